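# Bivariate standard-normal CDF P(Z1 <= a, Z2 <= b) with correlation rho.
binorm_cdf <- function(a, b, rho) {
  if (!is.finite(a) || !is.finite(b)) {
    a <- min(a, 8); b <- min(b, 8)
  }
  mvtnorm::pmvnorm(lower = c(-Inf, -Inf), upper = c(a, b),
                   corr = matrix(c(1, rho, rho, 1), 2, 2),
                   algorithm = mvtnorm::TVPACK(abseps = 1e-12))[1]
}

# Bivariate standard-normal density at (a, b) with correlation rho.
binorm_pdf <- function(a, b, rho) {
  q <- (a^2 - 2 * rho * a * b + b^2) / (1 - rho^2)
  exp(-q / 2) / (2 * pi * sqrt(1 - rho^2))
}

# Orthant probabilities of the 2x2 table implied by thresholds (tau1, tau2)
# and latent correlation rho, under y = 1 iff y* > tau. Returns
# c(p11, p10, p01, p00), floored at a tiny positive value.
tetra_cell_probs <- function(tau1, tau2, rho) {
  p11 <- binorm_cdf(-tau1, -tau2, rho)   # P(Z1 > tau1, Z2 > tau2)
  p1_ <- pnorm(tau1, lower.tail = FALSE)
  p_1 <- pnorm(tau2, lower.tail = FALSE)
  p <- c(p11, p1_ - p11, p_1 - p11, 1 - p1_ - p_1 + p11)
  pmax(p, 1e-300)
}

#' Tetrachoric correlation of one item pair from its 2x2 table
#'
#' Maximum-likelihood tetrachoric estimate under bivariate normality of the
#' latent responses: thresholds from the table margins (for a 2x2 table the
#' margin quantiles are the joint MLE of the thresholds, so this two-step
#' estimator is the full MLE) and the correlation by maximizing the orthant
#' profile likelihood over (-0.999, 0.999).
#'
#' @param table 2x2 count table: `table[1,1]` = both yes, rows = item 1
#'   (yes, no), columns = item 2 (yes, no). A length-4 vector
#'   (n11, n10, n01, n00) is also accepted.
#' @param correct logical: add 0.5 to every cell if any cell is zero
#'   (continuity correction). Default FALSE; with a zero margin and
#'   `correct = FALSE` the estimate is not defined and an error advises
#'   enabling the correction.
#' @return List: `rho`, `tau` (two thresholds, probit scale, y = 1 iff
#'   y* > tau), `converged`, `boundary` (|rho| at the 0.999 cap or beyond
#'   0.998), `loglik`, `var_rho` (asymptotic variance of rho with
#'   thresholds fixed), `table` (the possibly corrected table).
#' @export
tetrachoric_pair <- function(table, correct = FALSE) {
  tb <- if (is.matrix(table)) c(table[1, 1], table[1, 2],
                                table[2, 1], table[2, 2])
        else as.numeric(table)
  stopifnot(length(tb) == 4, all(tb >= 0))
  if (correct && any(tb == 0)) tb <- tb + 0.5
  n11 <- tb[1]; n10 <- tb[2]; n01 <- tb[3]; n00 <- tb[4]
  n <- sum(tb)
  m1 <- n11 + n10; m2 <- n11 + n01
  if (m1 == 0 || m1 == n || m2 == 0 || m2 == n)
    stop("zero margin in 2x2 table; apply the continuity correction ",
         "(correct = TRUE)")
  tau1 <- qnorm(1 - m1 / n)
  tau2 <- qnorm(1 - m2 / n)
  nll <- function(rho) {
    p <- tetra_cell_probs(tau1, tau2, rho)
    -sum(tb * log(p))
  }
  # optimize over a slightly wider interval so that estimates pushed to the
  # boundary land exactly on the +/-0.999 cap
  opt <- optimize(nll, c(-0.9995, 0.9995), tol = 1e-9)
  rho <- max(-0.999, min(0.999, opt$minimum))
  boundary <- abs(rho) > 0.998
  p <- tetra_cell_probs(tau1, tau2, rho)
  phi2 <- binorm_pdf(tau1, tau2, rho)
  var_rho <- 1 / (n * phi2^2 * sum(1 / p))
  list(rho = rho, tau = c(tau1, tau2), converged = TRUE,
       boundary = boundary, loglik = -opt$objective, var_rho = var_rho,
       table = tb)
}

#' Tetrachoric correlation matrix of the item battery
#'
#' Pairwise ML tetrachoric estimates assembled into a correlation matrix,
#' with item thresholds tau_j = qnorm(1 - prevalence_j) (y = 1 iff
#' y* > tau). Pairs with an empty cell get the 0.5 continuity correction
#' when `correct = "auto"` (the default; low-prevalence items make empty
#' cells likely in subsamples). If the assembled matrix is not positive
#' semidefinite it is repaired by eigenvalue clipping at 1e-8 followed by
#' rescaling to unit diagonal, and flagged.
#'
#' @param responses n x J binary matrix.
#' @param correct `"auto"`, `"always"` or `"never"`.
#' @return List of class `tetrachoric_result`: `rho` (J x J), `tau`,
#'   `var_rho` (J x J asymptotic variances, used as DWLS weights),
#'   `corrected` / `boundary` (logical J x J), `psd_repaired`, `n`.
#' @export
tetrachoric_matrix <- function(responses, correct = c("auto", "always",
                                                      "never")) {
  correct <- match.arg(correct)
  Y <- unclass(responses)
  stopifnot(nrow(Y) >= 2)
  J <- ncol(Y)
  prev <- colMeans(Y)
  single <- prev == 0 | prev == 1
  if (any(single) && correct == "never")
    stop("item(s) with a single observed outcome: ",
         paste(which(single), collapse = ", "),
         "; enable the continuity correction")
  N11 <- crossprod(Y)
  ones <- colSums(Y)
  rho <- diag(J); var_rho <- matrix(NA_real_, J, J)
  corrected <- boundary <- matrix(FALSE, J, J)
  n <- nrow(Y)
  for (j in seq_len(J - 1)) for (l in (j + 1):J) {
    n11 <- N11[j, l]
    tb <- c(n11, ones[j] - n11, ones[l] - n11, n - ones[j] - ones[l] + n11)
    use_corr <- correct == "always" || (correct == "auto" && any(tb == 0))
    est <- tetrachoric_pair(tb, correct = use_corr)
    rho[j, l] <- rho[l, j] <- est$rho
    var_rho[j, l] <- var_rho[l, j] <- est$var_rho
    corrected[j, l] <- corrected[l, j] <- use_corr
    boundary[j, l] <- boundary[l, j] <- est$boundary
  }
  tau <- qnorm(1 - prev)
  ev <- eigen(rho, symmetric = TRUE)
  psd_repaired <- FALSE
  if (min(ev$values) < 0) {
    psd_repaired <- TRUE
    vals <- pmax(ev$values, 1e-8)
    rho <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    d <- sqrt(diag(rho))
    rho <- rho / tcrossprod(d)
    diag(rho) <- 1
  }
  structure(list(rho = rho, tau = tau, var_rho = var_rho,
                 corrected = corrected, boundary = boundary,
                 psd_repaired = psd_repaired, n = n),
            class = "tetrachoric_result")
}

#' @export
print.tetrachoric_result <- function(x, ...) {
  cat("Tetrachoric matrix:", ncol(x$rho), "items, n =", x$n)
  if (x$psd_repaired) cat(" (PSD-repaired)")
  cat("\n")
  invisible(x)
}
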