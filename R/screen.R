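#' Probit regression by maximum likelihood
#'
#' Fits P(y = 1 | X) = Phi(b0 + X b) by iteratively reweighted least
#' squares. Perfect or quasi-perfect separation (diverging coefficients or
#' degenerate fitted probabilities) is flagged and the fit is redone with a
#' small ridge penalty (1e-4) by a Newton iteration so that a finite
#' log-likelihood is always returned.
#'
#' @param y binary response vector.
#' @param X design matrix (no intercept column; one is added).
#' @return List: `coefficients` (intercept first), `loglik`, `converged`,
#'   `separation`, `fitted`.
#' @export
probit_fit <- function(y, X = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  X1 <- if (is.null(X) || ncol(as.matrix(X)) == 0) matrix(1, n, 1)
        else cbind(1, as.matrix(X))
  colnames(X1) <- c("(intercept)",
                    if (ncol(X1) > 1) colnames(as.matrix(X)))
  if (qr(X1)$rank < ncol(X1))
    stop("design matrix is rank deficient")
  fit <- suppressWarnings(
    glm.fit(X1, y, family = binomial(link = "probit"),
            control = list(maxit = 100)))
  beta <- fit$coefficients
  sep <- !fit$converged || any(abs(beta) > 8) ||
    any(fit$fitted.values < 1e-10) || any(fit$fitted.values > 1 - 1e-10)
  if (sep) {
    warning("probable separation in probit fit; using ridge fallback")
    beta <- probit_ridge(y, X1, lambda = 1e-4)
  }
  eta <- drop(X1 %*% beta)
  ll <- sum(y * pnorm(eta, log.p = TRUE) +
            (1 - y) * pnorm(-eta, log.p = TRUE))
  list(coefficients = setNames(beta, colnames(X1)), loglik = ll,
       converged = fit$converged || sep, separation = sep,
       fitted = pnorm(eta))
}

# Ridge-penalized probit Newton iteration (penalty on all coefficients).
probit_ridge <- function(y, X1, lambda = 1e-4, maxit = 200) {
  beta <- rep(0, ncol(X1))
  for (it in seq_len(maxit)) {
    eta <- pmin(pmax(drop(X1 %*% beta), -8), 8)
    phi <- dnorm(eta); P <- pnorm(eta)
    P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
    g <- drop(crossprod(X1, phi * (y - P) / (P * (1 - P)))) -
      2 * lambda * beta
    w <- phi^2 / (P * (1 - P))
    H <- crossprod(X1 * sqrt(w)) + diag(2 * lambda, ncol(X1))
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  beta
}

#' Likelihood-ratio test of nested probit models
#'
#' @param ll_full log-likelihood of the larger model.
#' @param ll_reduced log-likelihood of the nested model.
#' @param df_diff degrees-of-freedom difference (>= 1).
#' @return List: `statistic`, `df`, `p_value`.
#' @export
lrt <- function(ll_full, ll_reduced, df_diff) {
  stopifnot(df_diff >= 1)
  stat <- 2 * (ll_full - ll_reduced)
  if (stat < -1e-6)
    stop("negative LRT statistic (", signif(stat, 3),
         "); models are not nested or fits did not converge")
  stat <- max(stat, 0)
  list(statistic = stat, df = df_diff,
       p_value = pchisq(stat, df_diff, lower.tail = FALSE))
}

#' Two-stage per-item covariate screen for direct effects
#'
#' Stage 1 fits, for every item and every candidate covariate, a probit
#' model adjusted for DREAMS invitation, site and age, testing the
#' candidate's dummy block by a joint likelihood-ratio test (df = k - 1);
#' candidates with p <= `alpha1` enter stage 2. Stage 2 fits one
#' multivariable probit per item (adjustment set plus all stage-1
#' survivors) and keeps blocks significant at `alpha2` in a single backward
#' pass. Invitation, site and age are always retained in the final
#' direct-effect map for every item. Constant covariates are dropped with a
#' warning and never selected.
#'
#' @param responses n x 15 binary matrix.
#' @param covariates `covariate_design` (dummy matrix plus codebook).
#' @param alpha1 stage-1 threshold (default 0.10).
#' @param alpha2 stage-2 threshold (default 0.05).
#' @param always covariate names always retained (default invited, site,
#'   agegrp).
#' @return Object of class `screen_result`: `stage1_p` (items x candidate
#'   covariates), `stage2_p`, `direct_map` (per item: covariate names),
#'   `direct_columns` (per item: dummy column names), `always`, `dropped`.
#' @export
run_screen <- function(responses, covariates, alpha1 = 0.10,
                       alpha2 = 0.05,
                       always = c("invited", "site", "agegrp")) {
  Y <- unclass(responses)
  X <- covariates$X
  spec <- covariates$codebook
  stopifnot(all(always %in% names(spec)))
  blocks <- lapply(names(spec), function(nm)
    grep(paste0("^", nm, ":"), colnames(X), value = TRUE))
  names(blocks) <- names(spec)
  keep <- vapply(blocks, function(b)
    length(b) > 0 && any(apply(X[, b, drop = FALSE], 2, var) > 0),
    logical(1))
  dropped <- names(blocks)[!keep]
  if (length(dropped) > 0)
    warning("dropping constant covariate(s): ",
            paste(dropped, collapse = ", "))
  blocks <- blocks[keep]
  cand <- setdiff(names(blocks), always)
  adj_cols <- unlist(blocks[intersect(always, names(blocks))])
  J <- ncol(Y)
  stage1_p <- matrix(NA_real_, J, length(cand),
                     dimnames = list(sprintf("item%02d", seq_len(J)), cand))
  stage2_p <- stage1_p
  direct_map <- vector("list", J)
  for (j in seq_len(J)) {
    yj <- Y[, j]
    if (min(sum(yj), sum(1 - yj)) < 5)
      warning("item ", j, " has fewer than 5 responses in one outcome; ",
              "screen attempted anyway")
    base <- probit_fit(yj, X[, adj_cols, drop = FALSE])
    for (cv in cand) {
      b <- blocks[[cv]]
      full <- probit_fit(yj, X[, c(adj_cols, b), drop = FALSE])
      stage1_p[j, cv] <- lrt(full$loglik, base$loglik, length(b))$p_value
    }
    surv <- cand[stage1_p[j, ] <= alpha1]
    if (length(surv) > 0) {
      cols2 <- c(adj_cols, unlist(blocks[surv]))
      full2 <- probit_fit(yj, X[, cols2, drop = FALSE])
      for (cv in surv) {
        red_cols <- setdiff(cols2, blocks[[cv]])
        red <- probit_fit(yj, X[, red_cols, drop = FALSE])
        stage2_p[j, cv] <- lrt(full2$loglik, red$loglik,
                               length(blocks[[cv]]))$p_value
      }
      surv <- surv[stage2_p[j, surv] <= alpha2]
    }
    direct_map[[j]] <- c(intersect(always, names(blocks)), surv)
  }
  names(direct_map) <- sprintf("item%02d", seq_len(J))
  direct_columns <- lapply(direct_map, function(cvs) unlist(blocks[cvs],
                                                            use.names = FALSE))
  structure(list(stage1_p = stage1_p, stage2_p = stage2_p,
                 direct_map = direct_map, direct_columns = direct_columns,
                 always = always, dropped = dropped,
                 alpha1 = alpha1, alpha2 = alpha2),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  extra <- vapply(x$direct_map, function(m)
    length(setdiff(m, x$always)), integer(1))
  cat("Covariate screen:", sum(extra), "item-covariate direct effects",
      "beyond the always-retained set\n")
  for (j in which(extra > 0))
    cat("  ", names(x$direct_map)[j], "<-",
        paste(setdiff(x$direct_map[[j]], x$always), collapse = ", "), "\n")
  invisible(x)
}
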