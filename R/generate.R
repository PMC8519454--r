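#' Draw raw categorical covariates from their marginal distributions
#'
#' Covariates are drawn independently from the marginal probabilities in the
#' specification (the joint dependence of the real survey covariates is not
#' modelled).
#'
#' @param spec covariate specification.
#' @param n number of respondents.
#' @return data.frame of character columns, one per covariate.
#' @export
generate_covariates <- function(spec, n) {
  as.data.frame(lapply(spec, function(cv) {
    sample(cv$levels, n, replace = TRUE, prob = cv$probs)
  }), stringsAsFactors = FALSE)
}

# Binary asset battery: q assets whose ownership probability increases in a
# latent standard-normal wealth score through a logistic link with slope 1.5
# and intercepts spreading baseline ownership from ~15% to ~85%.
generate_assets <- function(n, q = 12, slope = 1.5) {
  w <- rnorm(n)
  alpha <- qlogis(seq(0.15, 0.85, length.out = q))
  pr <- plogis(outer(w, rep(slope, q)) + rep(alpha, each = n))
  A <- matrix(as.integer(runif(n * q) < pr), n, q,
              dimnames = list(NULL, sprintf("asset%02d", seq_len(q))))
  attr(A, "latent_wealth") <- w
  A
}

#' Generate a synthetic violence-experience survey
#'
#' Samples respondents from the probit MIMIC model: covariates x from the
#' specification marginals, factors eta = B x + zeta with zeta ~ N(0, Psi),
#' latent responses y* = nu + Lambda eta + A x + eps with eps ~ N(0, 1), and
#' the observed binary item y = 1 exactly when y* > 0. Also draws a binary
#' asset battery for the wealth-index module.
#'
#' @param params `mimic_parameters` (e.g. [vaw_preset()]).
#' @param n number of respondents (>= 1).
#' @param seed integer seed; fixed seed reproduces the survey bit-for-bit.
#' @param n_assets number of asset indicators.
#' @return Object of class `synthetic_survey`: list with `responses` (n x J
#'   binary matrix, columns item01..itemJ), `covariates_raw` (data.frame),
#'   `X` (dummy-coded design matrix), `eta` (true factor scores), `assets`,
#'   `truth` (the generating `mimic_parameters`) and `seed`.
#' @export
generate_survey <- function(params, n, seed = 1L, n_assets = 12L) {
  stopifnot(inherits(params, "mimic_parameters"), n >= 1)
  set.seed(seed)
  info <- covariate_design_info(params$covariate_spec)
  raw <- generate_covariates(params$covariate_spec, n)
  X <- dummy_code(raw, params$covariate_spec)
  m <- ncol(params$Lambda); J <- length(params$nu)
  Lz <- chol(params$Psi)
  zeta <- matrix(rnorm(n * m), n, m) %*% Lz
  eta <- X %*% t(params$B) + zeta
  ystar <- rep(params$nu, each = n) + eta %*% t(params$Lambda) +
    X %*% t(params$A) + matrix(rnorm(n * J), n, J)
  Y <- matrix(as.integer(ystar > 0), n, J,
              dimnames = list(NULL, sprintf("item%02d", seq_len(J))))
  assets <- generate_assets(n, n_assets)
  structure(list(responses = Y, covariates_raw = raw, X = X, eta = eta,
                 assets = assets, truth = params, seed = as.integer(seed)),
            class = "synthetic_survey")
}

#' @export
print.synthetic_survey <- function(x, ...) {
  cat("Synthetic VAW survey:", nrow(x$responses), "respondents,",
      ncol(x$responses), "items,", ncol(x$X), "covariate columns, seed",
      x$seed, "\n")
  invisible(x)
}

#' Model-implied correlation of the latent responses of two items
#'
#' Closed form for the correlation of y*_j and y*_l marginal over factors
#' and covariates; this is the population tetrachoric correlation of the
#' generated item pair. With no covariate effects this reduces to
#' lambda_j' Psi lambda_l / sqrt((lambda_j' Psi lambda_j + 1)
#' (lambda_l' Psi lambda_l + 1)).
#'
#' @param params `mimic_parameters`.
#' @return J x J correlation matrix.
#' @export
implied_ystar_correlation <- function(params) {
  info <- covariate_design_info(params$covariate_spec)
  Veta <- params$B %*% info$Sigma %*% t(params$B) + params$Psi
  BSx <- params$B %*% info$Sigma
  # Cov(y*) = Lambda Veta Lambda' + A Sx A' + Lambda BSx A' + (Lambda BSx A')' + I
  C <- params$Lambda %*% Veta %*% t(params$Lambda) +
    params$A %*% info$Sigma %*% t(params$A) +
    params$Lambda %*% BSx %*% t(params$A) +
    t(params$Lambda %*% BSx %*% t(params$A)) +
    diag(length(params$nu))
  cov2cor(C)
}
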