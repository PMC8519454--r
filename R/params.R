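#' @useDynLib vawinvar, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats pnorm qnorm dnorm plogis qlogis uniroot optimize nlminb
#'   rnorm runif glm.fit binomial pchisq quantile prcomp var sd cor cov
#'   median cov2cor setNames
#' @importFrom utils write.csv read.csv
NULL

#' The 15 WHO violence-against-women items
#'
#' Short labels for the 15 binary items ("Has any male ever done any of the
#' following things to you in the past 12 months?", yes = 1 / no = 0), in the
#' WHO instrument order: psychological/emotional violence (items 1-3),
#' physical violence (items 4-11) and sexual violence (items 12-15).
#'
#' @return Character vector of length 15.
#' @export
vaw_item_labels <- function() {
  c("humiliate you in front of others",
    "threaten to hurt you or someone close to you",
    "insult you or make you feel bad about yourself",
    "push you, shake you, or throw something at you",
    "slap you",
    "twist your arm or pull your hair",
    "punch you with his fist or something that could hurt you",
    "kick you, drag you, or beat you up",
    "try to choke you or burn you on purpose",
    "threaten to attack you with a knife or other weapon",
    "attack you with a weapon",
    "touch you in a sexual way when you did not want them to",
    "try to have sexual intercourse with you without success",
    "physically force you to have sexual intercourse",
    "force you to perform sexual acts when you did not want to")
}

#' WHO domain classification of the 15 items
#'
#' @return Character vector of length 15 with values `"psychological"`
#'   (items 1-3), `"physical"` (items 4-11), `"sexual"` (items 12-15).
#' @export
vaw_domain_map <- function() {
  rep(c("psychological", "physical", "sexual"), c(3L, 8L, 4L))
}

#' Major-factor index per item (1 = psychological, 2 = physical, 3 = sexual)
#' @return Integer vector of length 15.
#' @export
vaw_major_factor <- function() rep(1:3, c(3L, 8L, 4L))

#' Default categorical covariate specification
#'
#' Eleven categorical covariates with category labels, reference category and
#' marginal probabilities. Coding (labels and reference categories) follows
#' the DREAMS impact-evaluation survey conventions: site (ref Korogocho),
#' age group (ref 15-17), DREAMS invitation (ref not invited), marital status
#' (ref never married), in school (ref no), education (ref none/incomplete
#' primary), religion (ref Muslim), ethnicity (ref Somali), ever had sex
#' (ref no), slept hungry past 4 weeks (ref no), wealth tercile (ref poor).
#' Marginals reported for the DREAMS Nairobi cohort are used where available (site
#' 617:464, in school 625/1081, ever had sex 642/1081, never married
#' 843/1081, Christian 917/1081); the remainder are fixed plausible values
#' for an urban-slum AGYW cohort (see the methods vignette). Covariates are
#' drawn independently by default.
#'
#' @return Named list; each element has `levels`, `probs`, `ref`.
#' @export
vaw_covariate_spec <- function() {
  list(
    invited  = list(levels = c("not_invited", "invited"),
                    probs = c(0.45, 0.55), ref = "not_invited"),
    site     = list(levels = c("Korogocho", "Viwandani"),
                    probs = c(617, 464) / 1081, ref = "Korogocho"),
    agegrp   = list(levels = c("15-17", "18-22"),
                    probs = c(0.55, 0.45), ref = "15-17"),
    marital  = list(levels = c("never", "previously", "currently"),
                    probs = c(843 / 1081, 0.075, 1 - 843 / 1081 - 0.075),
                    ref = "never"),
    inschool = list(levels = c("no", "yes"),
                    probs = c(1 - 625 / 1081, 625 / 1081), ref = "no"),
    educ     = list(levels = c("none_incomplete_primary", "complete_primary",
                               "incomplete_secondary", "complete_secondary",
                               "tertiary"),
                    probs = c(0.18, 0.22, 0.33, 0.19, 0.08),
                    ref = "none_incomplete_primary"),
    religion = list(levels = c("Muslim", "Christian", "other"),
                    probs = c(0.09, 917 / 1081, 1 - 0.09 - 917 / 1081),
                    ref = "Muslim"),
    ethnicity = list(levels = c("Somali", "Kamba", "Kikuyu", "Kisii",
                                "Luhya", "Luo", "Other"),
                     probs = c(0.05, 0.17, 0.24, 0.08, 0.20, 0.20, 0.06),
                     ref = "Somali"),
    eversex  = list(levels = c("no", "yes"),
                    probs = c(1 - 642 / 1081, 642 / 1081), ref = "no"),
    hungry   = list(levels = c("no", "yes"),
                    probs = c(0.68, 0.32), ref = "no"),
    wealth   = list(levels = c("poor", "medium", "wealthy"),
                    probs = rep(1, 3) / 3, ref = "poor")
  )
}

#' Dummy-coding layout implied by a covariate specification
#'
#' For each categorical covariate with k categories, the k-1 non-reference
#' categories contribute one indicator column each, named `cov:level`.
#' Because covariates are drawn independently, the population covariance of
#' the dummy vector is block diagonal with multinomial blocks
#' (Var d_a = p_a (1 - p_a), Cov(d_a, d_b) = -p_a p_b within a covariate).
#'
#' @param spec covariate specification as from [vaw_covariate_spec()].
#' @return List with `colnames`, `mu` (marginal means), `Sigma` (p x p
#'   covariance), `R` (correlation), `sd`, and `index` mapping columns to
#'   covariates.
#' @export
covariate_design_info <- function(spec) {
  stopifnot(is.list(spec), length(spec) >= 1)
  cols <- character(0); mu <- numeric(0); index <- integer(0)
  blocks <- list()
  for (ci in seq_along(spec)) {
    cv <- spec[[ci]]
    stopifnot(length(cv$levels) == length(cv$probs),
              abs(sum(cv$probs) - 1) < 1e-8, cv$ref %in% cv$levels)
    keep <- cv$levels != cv$ref
    p <- cv$probs[keep]
    cols <- c(cols, paste0(names(spec)[ci], ":", cv$levels[keep]))
    mu <- c(mu, p)
    index <- c(index, rep(ci, sum(keep)))
    blocks[[ci]] <- diag(p, nrow = length(p)) - tcrossprod(p)
  }
  P <- length(cols)
  Sigma <- matrix(0, P, P, dimnames = list(cols, cols))
  at <- 1L
  for (b in blocks) {
    k <- nrow(b)
    if (k > 0) Sigma[at:(at + k - 1L), at:(at + k - 1L)] <- b
    at <- at + k
  }
  names(mu) <- cols
  list(colnames = cols, mu = mu, Sigma = Sigma, R = cov2cor(Sigma),
       sd = sqrt(diag(Sigma)), index = index)
}

#' Dummy-code a data frame of raw categorical covariates
#'
#' @param raw data.frame of character/factor columns named as in `spec`.
#' @param spec covariate specification.
#' @return Numeric matrix with one column per non-reference category.
#' @export
dummy_code <- function(raw, spec) {
  info <- covariate_design_info(spec)
  n <- nrow(raw)
  X <- matrix(0, n, length(info$colnames),
              dimnames = list(NULL, info$colnames))
  for (nm in names(spec)) {
    if (!nm %in% names(raw)) stop("missing covariate column: ", nm)
    v <- as.character(raw[[nm]])
    bad <- which(!v %in% spec[[nm]]$levels)
    if (length(bad) > 0)
      stop("unknown category '", v[bad[1]], "' for covariate '", nm,
           "' at row ", bad[1])
    for (lv in setdiff(spec[[nm]]$levels, spec[[nm]]$ref))
      X[, paste0(nm, ":", lv)] <- as.numeric(v == lv)
  }
  X
}

#' Construct and validate a MIMIC parameter set
#'
#' Houses the probit-scale parameters of the MIMIC measurement model
#' y*_ij = nu_j + lambda_j' eta_i + a_j' x_i + eps_ij, eps ~ N(0, 1),
#' eta_i = B x_i + zeta_i, zeta ~ N(0, Psi), with the binary response
#' y_ij = 1 exactly when y*_ij > 0.
#'
#' @param nu item intercepts (length J, probit scale).
#' @param Lambda J x m loading matrix (probit scale).
#' @param A J x p direct-effect matrix (rows mostly zero).
#' @param B m x p factor-regression matrix.
#' @param Psi m x m factor residual covariance (symmetric positive definite).
#' @param covariate_spec covariate specification; its dummy layout must match
#'   the columns of `A` and `B`.
#' @param major integer vector (length J) giving each item's designated major
#'   factor.
#' @return Object of class `mimic_parameters`.
#' @export
mimic_parameters <- function(nu, Lambda, A, B, Psi,
                             covariate_spec = vaw_covariate_spec(),
                             major = vaw_major_factor()) {
  Lambda <- as.matrix(Lambda); A <- as.matrix(A)
  B <- as.matrix(B); Psi <- as.matrix(Psi)
  J <- length(nu); m <- ncol(Lambda)
  info <- covariate_design_info(covariate_spec)
  p <- length(info$colnames)
  stopifnot(nrow(Lambda) == J, nrow(A) == J, ncol(A) == p,
            nrow(B) == m, ncol(B) == p, nrow(Psi) == m, ncol(Psi) == m,
            length(major) == J, all(major %in% seq_len(m)))
  if (max(abs(Psi - t(Psi))) > 1e-10)
    stop("Psi must be symmetric")
  ch <- tryCatch(chol(Psi), error = function(e) NULL)
  if (is.null(ch))
    stop("Psi is not positive definite")
  colnames(A) <- info$colnames
  colnames(B) <- info$colnames
  structure(list(nu = as.numeric(nu), Lambda = Lambda, A = A, B = B,
                 Psi = Psi, covariate_spec = covariate_spec,
                 major = as.integer(major)),
            class = "mimic_parameters")
}

#' @export
print.mimic_parameters <- function(x, ...) {
  cat("MIMIC parameter set:", length(x$nu), "items,",
      ncol(x$Lambda), "factors,", ncol(x$A), "covariate columns\n")
  cat("  direct effects (nonzero A entries):", sum(x$A != 0), "\n")
  invisible(x)
}

#' Closed-form marginal probability of a yes answer given covariates
#'
#' Integrating the factor residual zeta out of the probit measurement model
#' gives P(y_j = 1 | x) = Phi((nu_j + (lambda_j' B + a_j') x) /
#' sqrt(lambda_j' Psi lambda_j + 1)). Used as the analytic oracle for the
#' survey generator.
#'
#' @param params `mimic_parameters`.
#' @param x numeric dummy-coded covariate vector (length p), a matrix with
#'   p columns, or NULL for all-reference covariates.
#' @param item item index in 1..J.
#' @return Probability (vector if `x` is a matrix).
#' @export
marginal_item_probability <- function(params, x = NULL, item) {
  stopifnot(inherits(params, "mimic_parameters"),
            item >= 1, item <= length(params$nu))
  lam <- params$Lambda[item, ]
  s <- sqrt(drop(crossprod(lam, params$Psi %*% lam)) + 1)
  if (is.null(x)) x <- rep(0, ncol(params$A))
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  eff <- drop(crossprod(lam, params$B)) + params$A[item, ]
  drop(pnorm((params$nu[item] + x %*% eff) / s))
}

# Enumerate the joint covariate support (independent categorical draws):
# dummy-coded rows with product weights. Used for exact nu calibration and
# population prevalences.
covariate_grid <- function(spec) {
  lev <- lapply(spec, function(cv) seq_along(cv$levels))
  g <- expand.grid(lev, KEEP.OUT.ATTRS = FALSE)
  w <- rep(1, nrow(g))
  raw <- as.data.frame(lapply(names(spec), function(nm) {
    spec[[nm]]$levels[g[[nm]]]
  }), col.names = names(spec), stringsAsFactors = FALSE)
  for (nm in names(spec)) w <- w * spec[[nm]]$probs[g[[nm]]]
  list(X = dummy_code(raw, spec), w = w)
}

#' Population item prevalences under a parameter set
#'
#' Averages [marginal_item_probability()] exactly over the joint covariate
#' distribution (enumerated, since covariates are independent categoricals).
#'
#' @param params `mimic_parameters`.
#' @param grid optional precomputed covariate grid (internal use).
#' @return Numeric vector of length J of P(y_j = 1).
#' @export
population_item_prevalence <- function(params, grid = NULL) {
  if (is.null(grid)) grid <- covariate_grid(params$covariate_spec)
  vapply(seq_along(params$nu), function(j) {
    sum(grid$w * marginal_item_probability(params, grid$X, j))
  }, numeric(1))
}

#' Calibrate item intercepts to target prevalences
#'
#' Solves, per item, the population marginal-probability equation for nu_j so
#' that the model-implied prevalence equals the target, by root finding to
#' absolute tolerance 1e-8.
#'
#' @param params `mimic_parameters`.
#' @param target_prev numeric vector of target prevalences in (0,1).
#' @return `mimic_parameters` with calibrated `nu`.
#' @export
calibrate_nu <- function(params, target_prev) {
  stopifnot(length(target_prev) == length(params$nu),
            all(target_prev > 0), all(target_prev < 1))
  grid <- covariate_grid(params$covariate_spec)
  for (j in seq_along(params$nu)) {
    lam <- params$Lambda[j, ]
    s <- sqrt(drop(crossprod(lam, params$Psi %*% lam)) + 1)
    u <- drop(grid$X %*% (drop(crossprod(lam, params$B)) + params$A[j, ]))
    f <- function(nu) sum(grid$w * pnorm((nu + u) / s)) - target_prev[j]
    params$nu[j] <- uniroot(f, c(-15, 15), tol = 1e-10)$root
  }
  params
}

#' Standardize a MIMIC parameter set
#'
#' Maps the probit-scale parameters onto the standardized (STDYX) scale the
#' field reports: loadings lambda*_jk = lambda_jk SD(eta_k)/SD(y*_j), direct
#' effects a*_jc = a_jc SD(x_c)/SD(y*_j) and factor regressions
#' b*_kc = b_kc SD(x_c)/SD(eta_k), with SD(y*_j) from the model-implied
#' variance lambda' V(eta) lambda + a' S_x a + 2 lambda' B S_x a + 1 and
#' V(eta) = B S_x B' + Psi, S_x the analytic covariate covariance.
#'
#' @param params `mimic_parameters`.
#' @return List with `Lambda_std`, `A_std`, `B_std`, `factor_cor`
#'   (correlation of eta), `sd_eta`, `sd_ystar`, `sd_x`.
#' @export
standardize_parameters <- function(params) {
  info <- covariate_design_info(params$covariate_spec)
  Veta <- params$B %*% info$Sigma %*% t(params$B) + params$Psi
  sd_eta <- sqrt(diag(Veta))
  J <- length(params$nu)
  sd_y <- numeric(J)
  BSx <- params$B %*% info$Sigma
  for (j in seq_len(J)) {
    lam <- params$Lambda[j, ]; a <- params$A[j, ]
    sd_y[j] <- sqrt(drop(crossprod(lam, Veta %*% lam)) +
                    drop(crossprod(a, info$Sigma %*% a)) +
                    2 * drop(crossprod(lam, BSx %*% a)) + 1)
  }
  list(Lambda_std = params$Lambda * outer(1 / sd_y, sd_eta),
       A_std = params$A * outer(1 / sd_y, info$sd),
       B_std = params$B * outer(1 / sd_eta, info$sd),
       factor_cor = cov2cor(Veta),
       sd_eta = sd_eta, sd_ystar = sd_y, sd_x = info$sd)
}

#' Build probit-scale parameters from standardized inputs
#'
#' Inverse of [standardize_parameters()] under the convention SD(eta_k) = 1:
#' the factor-regression matrix is b_kc = b*_kc / SD(x_c), the residual
#' covariance is Psi = F - B S_x B' where F is the requested total factor
#' correlation matrix, and each item's scale follows in closed form from its
#' standardized communality: SD(y*_j) = 1/sqrt(1 - c_j) with
#' c_j = lambda*' F lambda* + a*' R_x a* + 2 lambda*' (B S_x D_x^-1) a*.
#' Item intercepts are then calibrated to the target prevalences.
#'
#' @param Lambda_std J x m standardized loadings.
#' @param B_std m x p standardized factor regressions.
#' @param A_std J x p standardized direct effects.
#' @param factor_cor m x m total factor correlation matrix.
#' @param target_prev length-J prevalence targets.
#' @param covariate_spec covariate specification.
#' @param major major-factor index per item.
#' @return `mimic_parameters`.
#' @export
parameters_from_standardized <- function(Lambda_std, B_std, A_std,
                                         factor_cor, target_prev,
                                         covariate_spec = vaw_covariate_spec(),
                                         major = vaw_major_factor()) {
  info <- covariate_design_info(covariate_spec)
  B <- B_std / rep(info$sd, each = nrow(B_std))
  Psi <- factor_cor - B %*% info$Sigma %*% t(B)
  BSxD <- B %*% info$Sigma %*% diag(1 / info$sd, length(info$sd))
  J <- nrow(Lambda_std)
  sd_y <- numeric(J)
  for (j in seq_len(J)) {
    lam <- Lambda_std[j, ]; a <- A_std[j, ]
    cj <- drop(crossprod(lam, factor_cor %*% lam)) +
      drop(crossprod(a, info$R %*% a)) +
      2 * drop(crossprod(lam, BSxD %*% a))
    if (cj >= 1)
      stop("standardized communality >= 1 for item ", j)
    sd_y[j] <- 1 / sqrt(1 - cj)
  }
  Lambda <- Lambda_std * sd_y
  A <- A_std * outer(sd_y, 1 / info$sd)
  params <- mimic_parameters(rep(0, J), Lambda, A, B, Psi,
                             covariate_spec, major)
  calibrate_nu(params, target_prev)
}

# Standardized loading pattern reported for the DREAMS AGYW cohort
# (15 items x psychological/physical/sexual).
dreams_loadings_std <- function() {
  matrix(c(
     0.886,  0.001, -0.048,
     0.543,  0.288,  0.092,
     0.755,  0.126,  0.041,
     0.352,  0.516, -0.021,
     0.086,  0.756, -0.038,
     0.044,  0.664,  0.133,
    -0.007,  0.943, -0.061,
     0.040,  0.934, -0.047,
    -0.047,  0.873,  0.004,
     0.183,  0.663,  0.019,
    -0.247,  0.816,  0.143,
     0.099,  0.228,  0.644,
    -0.037,  0.278,  0.752,
     0.020,  0.052,  0.917,
     0.167, -0.017,  0.896), ncol = 3, byrow = TRUE,
    dimnames = list(NULL, c("psychological", "physical", "sexual")))
}

# Standardized factor-regression coefficients (B) for the DREAMS cohort,
# 3 factors x 22 dummy columns in vaw_covariate_spec() order.
dreams_b_std <- function(info) {
  vals <- rbind(
    `invited:invited`             = c(-0.005, -0.021, -0.088),
    `site:Viwandani`              = c(-0.006, -0.207,  0.011),
    `agegrp:18-22`                = c( 0.011, -0.097, -0.133),
    `marital:previously`          = c( 0.090,  0.071, -0.067),
    `marital:currently`           = c(-0.184, -0.020, -0.096),
    `inschool:yes`                = c(-0.059, -0.090, -0.017),
    `educ:complete_primary`       = c(-0.103, -0.103, -0.133),
    `educ:incomplete_secondary`   = c( 0.022, -0.134, -0.076),
    `educ:complete_secondary`     = c(-0.044, -0.167, -0.036),
    `educ:tertiary`               = c(-0.045, -0.109,  0.032),
    `religion:Christian`          = c( 0.208,  0.196,  0.578),
    `religion:other`              = c( 0.096,  0.101,  0.250),
    `ethnicity:Kamba`             = c( 0.079, -0.137, -0.535),
    `ethnicity:Kikuyu`            = c( 0.050, -0.153, -0.590),
    `ethnicity:Kisii`             = c( 0.052, -0.029, -0.305),
    `ethnicity:Luhya`             = c( 0.021, -0.159, -0.481),
    `ethnicity:Luo`               = c( 0.062, -0.081, -0.458),
    `ethnicity:Other`             = c( 0.002, -0.049, -0.266),
    `eversex:yes`                 = c( 0.133,  0.090,  0.372),
    `hungry:yes`                  = c( 0.066,  0.052,  0.052),
    `wealth:medium`               = c(-0.010, -0.077, -0.103),
    `wealth:wealthy`              = c( 0.011,  0.002, -0.060))
  stopifnot(identical(rownames(vals), info$colnames))
  t(vals)
}

# The five noninvariant item-level direct effects (standardized A entries):
# items 1/2/15 x slept-hungry, item 5 x marital & education, item 10 x
# site & wealth.
dreams_a_std <- function(info) {
  A <- matrix(0, 15, length(info$colnames),
              dimnames = list(NULL, info$colnames))
  A[1,  "hungry:yes"] <- 0.090
  A[2,  "hungry:yes"] <- 0.100
  A[5,  "marital:currently"] <- 0.116
  A[5,  "educ:incomplete_secondary"] <- -0.135
  A[10, "site:Viwandani"] <- -0.244
  A[10, "wealth:medium"] <- -0.215
  A[15, "hungry:yes"] <- 0.139
  A
}

# Target item prevalences (percent / 100). Items 3 and 11 anchor the reported cohort
# extremes (26.5% and 1.6%); the rest are fixed plausible values declining
# within domain (methods vignette).
dreams_prevalence_targets <- function() {
  c(0.180, 0.120, 0.265,
    0.140, 0.160, 0.080, 0.065, 0.070, 0.030, 0.045, 0.016,
    0.125, 0.090, 0.060, 0.055)
}

#' Study-conditions parameter presets
#'
#' `"dreams"` mirrors the DREAMS AGYW survey conditions: the standardized
#' 3-factor loading pattern with major loadings 0.543-0.943 and small
#' cross-loadings, total factor correlations 0.575 / 0.446 / 0.467
#' (psychological-physical / psychological-sexual / physical-sexual),
#' covariate effects on the factors, five item-level noninvariant direct
#' effects (items 1, 2, 15 by slept-hungry; item 5 by marital status and
#' education; item 10 by site and wealth), and item intercepts calibrated so
#' population prevalences run from 1.6% to 26.5%. `"dreams_null"` is the
#' same preset with all direct effects zeroed (A = 0), for calibration
#' studies. `"null"` has no structure at all (Lambda = A = B = 0, nu = 0).
#'
#' `"dreams_nocov"` carries the measurement structure only (the reported
#' loading pattern and factor correlations with B = A = 0): under it the
#' latent responses are exactly multivariate normal, so the implied
#' correlation matrix is the population tetrachoric matrix — the right
#' preset for checking the tetrachoric and ESEM stages against their
#' closed forms. Under the full `"dreams"` preset the discrete covariates
#' make the marginal latent responses a normal mixture, and pairwise
#' tetrachorics deviate from the y* correlation by up to a few hundredths.
#'
#' @param name preset name.
#' @param covariate_spec covariate specification (defaults to the study
#'   marginals).
#' @return `mimic_parameters`.
#' @export
vaw_preset <- function(name = c("dreams", "dreams_null", "dreams_nocov",
                                "null"),
                       covariate_spec = vaw_covariate_spec()) {
  name <- match.arg(name)
  info <- covariate_design_info(covariate_spec)
  if (name == "null") {
    m <- 3
    return(mimic_parameters(rep(0, 15), matrix(0, 15, m),
                            matrix(0, 15, length(info$colnames)),
                            matrix(0, m, length(info$colnames)),
                            diag(m), covariate_spec))
  }
  F <- matrix(c(1, 0.575, 0.446,
                0.575, 1, 0.467,
                0.446, 0.467, 1), 3, 3)
  A_std <- dreams_a_std(info)
  if (name %in% c("dreams_null", "dreams_nocov")) A_std[] <- 0
  B_std <- dreams_b_std(info)
  if (name == "dreams_nocov") B_std[] <- 0
  parameters_from_standardized(
    Lambda_std = dreams_loadings_std(),
    B_std = B_std,
    A_std = A_std,
    factor_cor = F,
    target_prev = dreams_prevalence_targets(),
    covariate_spec = covariate_spec)
}
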