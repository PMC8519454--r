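# Shared fixtures and independent oracles for the test suite.

# Small generic parameter set (not the study preset): 15 items, 3 factors,
# modest loadings, a couple of direct effects.
random_params <- function(seed = 1) {
  set.seed(seed)
  major <- vaw_major_factor()
  L <- matrix(0, 15, 3)
  L[cbind(1:15, major)] <- runif(15, 0.5, 1.2)
  L[cbind(1:15, 1 + (major %% 3))] <- rnorm(15, 0, 0.1)
  spec <- vaw_covariate_spec()
  info <- covariate_design_info(spec)
  p <- length(info$colnames)
  A <- matrix(0, 15, p)
  A[2, 3] <- 0.4; A[9, 10] <- -0.3
  B <- matrix(0, 3, p)
  B[1, 1] <- 0.3; B[2, 2] <- -0.4; B[3, 19] <- 0.5
  Psi <- matrix(c(1, .5, .3, .5, 1, .4, .3, .4, 1), 3, 3)
  mimic_parameters(nu = runif(15, -2, -0.5), Lambda = L, A = A, B = B,
                   Psi = Psi, covariate_spec = spec, major = major)
}

# covariate_design container from a synthetic survey
survey_design <- function(sv) {
  structure(list(X = sv$X, raw = sv$covariates_raw,
                 codebook = sv$truth$covariate_spec),
            class = "covariate_design")
}

# Direct-effect map: always-retained columns plus the truth's nonzero
# entries per item.
truth_direct_map <- function(sv) {
  X <- sv$X
  always <- colnames(X)[grep("^(invited|site|agegrp):", colnames(X))]
  lapply(seq_len(nrow(sv$truth$A)), function(j)
    union(always, colnames(X)[sv$truth$A[j, ] != 0]))
}

# Independent tetrachoric oracle: grid search over rho with the orthant
# probability from numeric quadrature of the bivariate normal density,
# reduced to one dimension: P(X > a, Y > b) =
# integral_a^inf phi(x) Phi((rho x - b)/sqrt(1-rho^2)) dx
# (no use of the package's pmvnorm-based path).
oracle_orthant <- function(tau1, tau2, rho) {
  f <- function(x) dnorm(x) * pnorm((rho * x - tau2) / sqrt(1 - rho^2))
  integrate(f, tau1, Inf, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

oracle_tetrachoric <- function(tb) {
  n <- sum(tb)
  tau1 <- qnorm(1 - (tb[1] + tb[2]) / n)
  tau2 <- qnorm(1 - (tb[1] + tb[3]) / n)
  ll <- function(rho) {
    p11 <- oracle_orthant(tau1, tau2, rho)
    p1 <- 1 - pnorm(tau1); p2 <- 1 - pnorm(tau2)
    p <- pmax(c(p11, p1 - p11, p2 - p11, 1 - p1 - p2 + p11), 1e-300)
    sum(tb * log(p))
  }
  # coarse grid then golden-section refinement
  grid <- seq(-0.995, 0.995, by = 0.01)
  vals <- vapply(grid, ll, numeric(1))
  g0 <- grid[which.max(vals)]
  optimize(ll, c(max(-0.999, g0 - 0.02), min(0.999, g0 + 0.02)),
           maximum = TRUE, tol = 1e-10)$maximum
}

# Independent Geomin criterion evaluation (plain loops).
oracle_geomin <- function(L, eps) {
  m <- ncol(L)
  total <- 0
  for (j in seq_len(nrow(L))) {
    prod <- 1
    for (k in seq_len(m)) prod <- prod * (L[j, k]^2 + eps)
    total <- total + prod^(1 / m)
  }
  total
}

# RMSEA confidence limit by plain bisection on the noncentral chi-square CDF.
oracle_rmsea_limit <- function(T, df, n, prob) {
  if (pchisq(T, df, ncp = 0) <= prob) return(0)
  lo <- 0; hi <- max(4 * T, 50)
  while (pchisq(T, df, ncp = hi) > prob) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (pchisq(T, df, ncp = mid) > prob) lo <- mid else hi <- mid
  }
  sqrt((lo + hi) / 2 / (df * n))
}
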