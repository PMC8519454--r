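# Rotate an initial loading matrix to echelon form (zeros above the
# "diagonal" of the first m rows), removing rotational indeterminacy for
# the unrotated extraction.
to_echelon <- function(L) {
  m <- ncol(L)
  if (m == 1) return(L)
  Q <- qr.Q(qr(t(L[seq_len(m), , drop = FALSE])))
  Le <- L %*% Q
  # fix signs so diagonal entries are positive
  s <- sign(diag(Le[seq_len(m), , drop = FALSE]))
  s[s == 0] <- 1
  Le %*% diag(s, m)
}

#' Unrotated factor extraction by diagonally-weighted least squares
#'
#' Minimizes the limited-information discrepancy
#' F = sum_{j<l} (s_jl - lambda_j' lambda_l)^2 / v_jl over an echelon-form
#' loading matrix (orthogonal factors), where s are the tetrachoric
#' correlations and v their asymptotic variances (the DWLS weights; unit
#' weights are used if none are supplied). Quasi-Newton minimization is run
#' to convergence with an analytic gradient.
#'
#' @param rho J x J correlation matrix or a `tetrachoric_result`.
#' @param n_factors number of factors m (admissible for J items).
#' @param weights optional J x J matrix of asymptotic variances v_jl.
#' @return List: `Lambda` (J x m, echelon), `F_min`, `communalities`,
#'   `heywood` (items clamped at uniqueness 0.001), `converged`,
#'   `gradient_norm`, `weights`.
#' @export
esem_extract <- function(rho, n_factors, weights = NULL) {
  if (inherits(rho, "tetrachoric_result")) {
    # DWLS weights on the asymptotic scale: Var(sqrt(n) s_r) = n * var(s_r),
    # so that T = n * F_min is the chi-square-scaled statistic
    if (is.null(weights)) weights <- rho$var_rho * rho$n
    rho <- rho$rho
  }
  S <- as.matrix(rho)
  J <- ncol(S); m <- n_factors
  stopifnot(m >= 1, J * m - m * (m - 1) / 2 <= J * (J - 1) / 2)
  W <- if (is.null(weights)) matrix(1, J, J) else 1 / weights
  diag(W) <- 0
  free <- which(!(col(matrix(0, J, m)) > row(matrix(0, J, m))))
  ev <- eigen(S, symmetric = TRUE)
  L0 <- ev$vectors[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(pmax(ev$values[seq_len(m)], 1e-4)), m)
  L0 <- to_echelon(L0)
  # tiny ridge breaks the tie among discrepancy-equivalent solutions
  # (e.g. disjoint-support loadings on an identity input) toward zero
  # loadings; the reported F_min is the unpenalized discrepancy
  ridge <- 1e-8
  obj <- function(par) {
    L <- matrix(0, J, m); L[free] <- par
    R <- S - tcrossprod(L); diag(R) <- 0
    sum(W * R^2) / 2 + ridge * sum(par^2)
  }
  grad <- function(par) {
    L <- matrix(0, J, m); L[free] <- par
    R <- S - tcrossprod(L); diag(R) <- 0
    G <- -2 * (W * R) %*% L
    G[free] + 2 * ridge * par
  }
  fval <- function(par) {
    L <- matrix(0, J, m); L[free] <- par
    R <- S - tcrossprod(L); diag(R) <- 0
    sum(W * R^2) / 2
  }
  fit <- nlminb(L0[free], obj, grad,
                control = list(iter.max = 2000, eval.max = 4000,
                               abs.tol = 0, rel.tol = 1e-14,
                               x.tol = 1e-12))
  L <- matrix(0, J, m); L[free] <- fit$par
  gn <- sqrt(sum(grad(fit$par)^2))
  h <- rowSums(L^2)
  heywood <- which(h > 0.999)
  if (length(heywood) > 0)
    L[heywood, ] <- L[heywood, ] * sqrt(0.999 / h[heywood])
  list(Lambda = L, F_min = fval(L[free]), # sum over j<l pairs
       communalities = rowSums(L^2), heywood = heywood,
       converged = fit$convergence == 0 || gn < 1e-6,
       gradient_norm = gn, weights = weights)
}

#' Geomin rotation criterion
#'
#' q(Lambda) = sum_j (prod_k (lambda_jk^2 + epsilon))^(1/m); epsilon is a
#' small smoothing constant improving the shape of the criterion.
#'
#' @param Lambda loading matrix.
#' @param epsilon smoothing constant (> 0), default 0.001.
#' @return Scalar criterion value.
#' @export
geomin_criterion <- function(Lambda, epsilon = 0.001) {
  stopifnot(epsilon > 0)
  L2 <- Lambda^2 + epsilon
  sum(exp(rowMeans(log(L2))))
}

# Criterion value and gradient for the gradient-projection rotation loop.
geomin_vg <- function(Lambda, epsilon = 0.001) {
  m <- ncol(Lambda)
  L2 <- Lambda^2 + epsilon
  pr <- exp(rowMeans(log(L2)))
  list(f = sum(pr), Gq = (2 / m) * (Lambda / L2) * pr)
}

# One oblique gradient-projection descent (Bernaards & Jennrich) from a
# given start Tmat (unit-length columns). L = A (T')^{-1}, Phi = T'T.
gpf_oblique <- function(A, Tmat, epsilon, maxit = 1000, tol = 1e-6) {
  al <- 1
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  vg <- geomin_vg(L, epsilon)
  f <- vg$f
  G <- -t(t(L) %*% vg$Gq %*% Ti)
  s <- Inf
  for (iter in seq_len(maxit)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), ncol(Tmat))
    s <- sqrt(sum(Gp^2))
    if (s < tol) break
    al <- 2 * al
    repeat {
      X <- Tmat - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), ncol(X))
      Ti2 <- tryCatch(solve(Tt), error = function(e) NULL)
      if (!is.null(Ti2)) {
        L2 <- A %*% t(Ti2)
        vg2 <- geomin_vg(L2, epsilon)
        if (vg2$f < f - 0.5 * s^2 * al) break
      }
      al <- al / 2
      if (al < 1e-12) break
    }
    if (al < 1e-12) break
    Tmat <- Tt; Ti <- Ti2; L <- L2; f <- vg2$f
    G <- -t(t(L) %*% vg2$Gq %*% Ti)
  }
  # the line search can exhaust machine precision with the gradient already
  # tiny; accept anything below 1e-4 as converged
  list(L = L, Phi = crossprod(Tmat), Tmat = Tmat, f = f,
       converged = s < max(tol, 1e-4), iterations = iter)
}

#' Oblique Geomin rotation with random starts
#'
#' Gradient-projection minimization of the Geomin criterion over oblique
#' transformations, from `n_starts` seeded random starts plus the identity;
#' the solution with the smallest criterion is kept (ties within 1e-8 broken
#' by lexicographic loading order). Columns are then aligned to the WHO
#' domain pattern (psychological, physical, sexual) by maximal absolute
#' congruence and signed so each column's largest-magnitude loading is
#' positive.
#'
#' @param Lambda unrotated J x m loading matrix (from [esem_extract()]).
#' @param epsilon Geomin smoothing constant, default 0.001.
#' @param n_starts number of random starts, default 30.
#' @param seed seed for the random starts.
#' @param align target major-factor index per item used for column
#'   alignment (NULL to skip).
#' @return List: `Lambda_rotated`, `Phi` (factor correlations), `criterion`,
#'   `n_converged`, `chosen_start`.
#' @export
rotate_geomin <- function(Lambda, epsilon = 0.001, n_starts = 30,
                          seed = 1L, align = vaw_major_factor()) {
  m <- ncol(Lambda)
  if (m == 1)
    return(list(Lambda_rotated = Lambda, Phi = matrix(1, 1, 1),
                criterion = geomin_criterion(Lambda, epsilon),
                n_converged = 1L, chosen_start = 0L))
  set.seed(seed)
  starts <- c(list(diag(m)), lapply(seq_len(n_starts), function(i) {
    X <- matrix(rnorm(m * m), m, m)
    X %*% diag(1 / sqrt(colSums(X^2)), m)
  }))
  best <- NULL; best_i <- NA_integer_; n_conv <- 0L
  for (i in seq_along(starts)) {
    res <- gpf_oblique(Lambda, starts[[i]], epsilon)
    if (res$converged) n_conv <- n_conv + 1L
    # ties within 1e-8 keep the earlier (deterministic) start
    if (is.null(best) || res$f < best$f - 1e-8) { best <- res; best_i <- i }
  }
  if (n_conv == 0L)
    stop("Geomin rotation: no start converged (", length(starts),
         " starts, epsilon = ", epsilon, ")")
  L <- best$L; Phi <- best$Phi
  if (!is.null(align) && length(align) == nrow(L)) {
    al <- align_factors(L, Phi, align)
    L <- al$Lambda; Phi <- al$Phi
  }
  list(Lambda_rotated = L, Phi = Phi, criterion = best$f,
       n_converged = n_conv, chosen_start = best_i - 1L)
}

# Permute and sign-flip rotated factors so column k carries the items whose
# designated major factor is k, by maximal absolute column congruence.
align_factors <- function(L, Phi, major) {
  m <- ncol(L)
  Tgt <- outer(major, seq_len(m), "==") * 1
  perms <- permutations_of(m)
  score <- vapply(perms, function(p) sum(Tgt * abs(L[, p, drop = FALSE])),
                  numeric(1))
  p <- perms[[which.max(score)]]
  L <- L[, p, drop = FALSE]
  Phi <- Phi[p, p, drop = FALSE]
  s <- vapply(seq_len(m), function(k) {
    v <- L[, k]; sign(v[which.max(abs(v))])
  }, numeric(1))
  s[s == 0] <- 1
  L <- L %*% diag(s, m)
  Phi <- diag(s, m) %*% Phi %*% diag(s, m)
  list(Lambda = L, Phi = Phi)
}

permutations_of <- function(m) {
  if (m == 1) return(list(1L))
  out <- list()
  for (i in seq_len(m)) {
    sub <- permutations_of(m - 1L)
    rest <- setdiff(seq_len(m), i)
    out <- c(out, lapply(sub, function(p) c(i, rest[p])))
  }
  out
}

#' Fit indices for the limited-information factor model
#'
#' CFI = 1 - max(T - df, 0)/max(T_B - df_B, 0);
#' TLI = ((T_B/df_B) - (T/df)) / ((T_B/df_B) - 1), clamped to [0, 1];
#' RMSEA = sqrt(max(T - df, 0)/(df n)) with the 90% CI obtained by
#' inverting the noncentral chi-square CDF in the noncentrality parameter;
#' WRMR = sqrt(sum_r (s_r - sigma_r)^2 / v_r / e) with e the number of
#' residual elements. The default `adjust = "mean"` rescales the raw DWLS
#' statistic T = n F_min by df/e so its null expectation matches its
#' degrees of freedom (an approximation to the proprietary mean-and-variance
#' adjusted statistic; `"none"` uses T unadjusted). RMSEA uses n in the
#' denominator (categorical-data convention); set `n_minus_1 = TRUE` for
#' the n-1 variant.
#'
#' @param T model chi-square statistic (already adjusted if desired, see
#'   `adjust`).
#' @param df model degrees of freedom (>= 1).
#' @param T_B baseline (independence-model) chi-square.
#' @param df_B baseline degrees of freedom (> df).
#' @param n sample size.
#' @param residuals vector of residual correlations s_r - sigma_r.
#' @param v vector of asymptotic variances of the s_r.
#' @param adjust `"mean"` (default) or `"none"`; applied to both T and T_B.
#' @param n_minus_1 use n - 1 in the RMSEA denominator.
#' @return List: `CFI`, `TLI`, `RMSEA`, `RMSEA_CI` (90%), `WRMR`,
#'   `T`, `df`, `T_B`, `df_B`.
#' @export
esem_fit_indices <- function(T, df, T_B, df_B, n, residuals, v,
                             adjust = c("mean", "none"),
                             n_minus_1 = FALSE) {
  adjust <- match.arg(adjust)
  stopifnot(df >= 1)
  if (df_B <= df) stop("baseline df must exceed model df")
  e <- length(residuals)
  if (adjust == "mean") {
    T <- T * df / e
    T_B <- T_B * df_B / e
  }
  nn <- if (n_minus_1) n - 1 else n
  CFI <- 1 - max(T - df, 0) / max(max(T_B - df_B, 0), max(T - df, 0))
  if (max(T_B - df_B, 0) == 0 && max(T - df, 0) == 0) CFI <- 1
  TLI <- if (T_B / df_B > 1)
    ((T_B / df_B) - (T / df)) / ((T_B / df_B) - 1) else 1
  TLI <- min(max(TLI, 0), 1)
  CFI <- min(max(CFI, 0), 1)
  RMSEA <- sqrt(max(T - df, 0) / (df * nn))
  ci <- rmsea_ci(T, df, nn, level = 0.90)
  WRMR <- sqrt(sum(residuals^2 / v) / e)
  list(CFI = CFI, TLI = TLI, RMSEA = RMSEA, RMSEA_CI = ci, WRMR = WRMR,
       T = T, df = df, T_B = T_B, df_B = df_B)
}

# Confidence interval for RMSEA by inverting the noncentral chi-square CDF
# in the noncentrality parameter.
rmsea_ci <- function(T, df, n, level = 0.90) {
  a <- (1 - level) / 2
  hi_p <- 1 - a   # lower limit: P(X_ncp <= T) = 1 - a
  lo_p <- a
  ncp_for <- function(p) {
    if (pchisq(T, df, ncp = 0) <= p) return(0)
    f <- function(l) pchisq(T, df, ncp = l) - p
    upper <- max(T * 2, df * 2, 10)
    while (f(upper) > 0) upper <- upper * 2
    uniroot(f, c(0, upper), tol = 1e-10)$root
  }
  l_lo <- ncp_for(hi_p)
  l_hi <- ncp_for(lo_p)
  c(lower = sqrt(l_lo / (df * n)), upper = sqrt(l_hi / (df * n)))
}

#' Exploratory structural equation model of the item battery
#'
#' The configural-invariance stage: estimates the tetrachoric correlation
#' matrix, extracts `n_factors` by DWLS, rotates with oblique Geomin
#' (epsilon = 0.001) and computes CFI/TLI/RMSEA (90% CI)/WRMR against the
#' independence baseline.
#'
#' @param responses n x J binary matrix, or a precomputed
#'   `tetrachoric_result`.
#' @param n_factors number of factors (default 3).
#' @param n sample size (required if `responses` is a correlation input).
#' @param epsilon Geomin constant.
#' @param n_starts rotation random starts.
#' @param seed seed for rotation starts.
#' @param adjust chi-square adjustment passed to [esem_fit_indices()].
#' @param align major-factor target for column alignment (NULL to skip).
#' @return Object of class `esem_solution`: `Lambda_rotated`, `Phi`,
#'   `Lambda_unrotated`, `communalities`, `F_min`, `fit`, `rotation`
#'   (diagnostics), `tetrachoric`, `n`.
#' @export
esem <- function(responses, n_factors = 3, n = NULL, epsilon = 0.001,
                 n_starts = 30, seed = 1L, adjust = "mean",
                 align = vaw_major_factor()) {
  tet <- if (inherits(responses, "tetrachoric_result")) responses
         else tetrachoric_matrix(responses)
  if (is.null(n)) n <- tet$n
  J <- ncol(tet$rho)
  ex <- esem_extract(tet, n_factors)
  up <- upper.tri(tet$rho)
  v <- tet$var_rho[up]            # finite-sample asymptotic variances
  resid <- (tet$rho - tcrossprod(ex$Lambda))[up]
  e <- J * (J - 1) / 2
  npar <- J * n_factors - n_factors * (n_factors - 1) / 2
  df <- e - npar
  Tstat <- n * ex$F_min           # = sum resid^2 / var(s_r)
  T_B <- sum(tet$rho[up]^2 / v)
  fit <- esem_fit_indices(Tstat, df, T_B, e, n, resid, v, adjust = adjust)
  alg <- if (!is.null(align) && length(align) == J) align else NULL
  rot <- rotate_geomin(ex$Lambda, epsilon, n_starts, seed, align = alg)
  structure(list(Lambda_rotated = rot$Lambda_rotated, Phi = rot$Phi,
                 Lambda_unrotated = ex$Lambda,
                 communalities = ex$communalities,
                 heywood = ex$heywood,
                 F_min = ex$F_min, fit = fit,
                 rotation = list(criterion = rot$criterion,
                                 n_starts = n_starts,
                                 n_converged = rot$n_converged,
                                 chosen_start = rot$chosen_start,
                                 epsilon = epsilon),
                 tetrachoric = tet, n = n),
            class = "esem_solution")
}

#' @export
print.esem_solution <- function(x, ...) {
  cat("ESEM solution:", nrow(x$Lambda_rotated), "items,",
      ncol(x$Lambda_rotated), "factors, n =", x$n, "\n")
  cat(sprintf("  CFI = %.3f, TLI = %.3f, RMSEA = %.3f (90%% CI %.3f-%.3f), WRMR = %.3f\n",
              x$fit$CFI, x$fit$TLI, x$fit$RMSEA,
              x$fit$RMSEA_CI[1], x$fit$RMSEA_CI[2], x$fit$WRMR))
  invisible(x)
}
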