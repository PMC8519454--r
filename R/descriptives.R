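#' Per-item prevalence of violence experience
#'
#' Percentage of respondents answering yes to each of the 15 items, overall
#' or stratified by a categorical covariate.
#'
#' @param responses n x 15 binary matrix (or `item_response_matrix`).
#' @param by optional factor/character vector of length n for stratification.
#' @return data.frame with columns `item`, `label`, `domain`, (`stratum`,)
#'   `n`, `n_yes`, `percent`.
#' @export
item_prevalence <- function(responses, by = NULL) {
  Y <- unclass(responses)
  if (is.null(dim(Y)) || nrow(Y) < 1) stop("empty response matrix")
  labels <- attr(responses, "item_labels")
  if (is.null(labels)) labels <- colnames(Y)
  domain <- attr(responses, "domain_map")
  if (is.null(domain)) domain <- rep(NA_character_, ncol(Y))
  one <- function(Ys, stratum = NULL) {
    out <- data.frame(item = seq_len(ncol(Ys)), label = labels,
                      domain = domain, n = nrow(Ys),
                      n_yes = colSums(Ys),
                      percent = 100 * colMeans(Ys),
                      stringsAsFactors = FALSE)
    if (!is.null(stratum)) out <- cbind(stratum = stratum, out)
    out
  }
  if (is.null(by)) return(one(Y))
  stopifnot(length(by) == nrow(Y))
  do.call(rbind, lapply(sort(unique(as.character(by))), function(s) {
    one(Y[as.character(by) == s, , drop = FALSE], s)
  }))
}

#' Distribution of the number of violence acts experienced
#'
#' Per-respondent count of yes answers and the cumulative table of
#' respondents experiencing at least k acts, k = 1..15, overall or
#' stratified. "At least half of the acts" is taken as >= 8 of 15.
#'
#' @param responses n x 15 binary matrix.
#' @param by optional stratification vector.
#' @return List of class `acts_distribution`: `acts` (per-respondent
#'   counts), `cumulative` (data.frame with `threshold`, (`stratum`,) `n`,
#'   `count`, `percent`), `n_at_least_one`, `n_at_least_half`.
#' @export
acts_distribution <- function(responses, by = NULL) {
  Y <- unclass(responses)
  if (is.null(dim(Y)) || nrow(Y) < 1) stop("empty response matrix")
  acts <- rowSums(Y)
  J <- ncol(Y)
  cum_one <- function(a, stratum = NULL) {
    out <- data.frame(threshold = seq_len(J), n = length(a),
                      count = vapply(seq_len(J),
                                     function(k) sum(a >= k), numeric(1)))
    out$percent <- 100 * out$count / out$n
    if (!is.null(stratum)) out <- cbind(stratum = stratum, out)
    out
  }
  cumulative <- if (is.null(by)) cum_one(acts) else {
    stopifnot(length(by) == nrow(Y))
    do.call(rbind, lapply(sort(unique(as.character(by))), function(s) {
      cum_one(acts[as.character(by) == s], s)
    }))
  }
  structure(list(acts = acts, cumulative = cumulative,
                 n_at_least_one = sum(acts >= 1),
                 n_at_least_half = sum(acts >= ceiling(J / 2)),
                 n = length(acts)),
            class = "acts_distribution")
}

#' @export
print.acts_distribution <- function(x, ...) {
  cat("Acts of violence among", x$n, "respondents:\n")
  cat("  >=1 act:", x$n_at_least_one,
      sprintf("(%.1f%%)", 100 * x$n_at_least_one / x$n), "\n")
  cat("  >=half (8) of the acts:", x$n_at_least_half,
      sprintf("(%.1f%%)", 100 * x$n_at_least_half / x$n), "\n")
  invisible(x)
}

#' PCA wealth index from a binary asset battery
#'
#' First principal component of the standardized (correlation-matrix) asset
#' indicators, following the Filmer-Pritchett convention; the component is
#' oriented so that a higher score correlates positively with the total
#' number of assets owned, then cut at the 33.33/66.67 percentiles into
#' poor/medium/wealthy terciles (ties kept in the lower group; for tied
#' scores the assignment is by this <=-percentile rule, hence stable in the
#' respondent order).
#'
#' @param assets n x q binary matrix, q >= 2.
#' @return List of class `wealth_index`: `score`, `tercile` (integer 1-3),
#'   `tercile_label`, `loadings` (first-component weights),
#'   `prop_variance`, `dropped` (zero-variance columns removed).
#' @export
wealth_index <- function(assets) {
  A <- as.matrix(assets)
  if (nrow(A) < 2) stop("need at least 2 respondents")
  v <- apply(A, 2, var)
  if (any(v == 0)) {
    labs <- if (is.null(colnames(A))) as.character(which(v == 0))
            else colnames(A)[v == 0]
    warning("dropping zero-variance asset column(s): ",
            paste(labs, collapse = ", "))
    dropped <- labs
    A <- A[, v > 0, drop = FALSE]
  } else dropped <- character(0)
  if (ncol(A) < 2) stop("fewer than 2 asset columns with nonzero variance")
  Z <- scale(A)
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  score <- pc$x[, 1]
  w <- pc$rotation[, 1]
  orient <- cor(score, rowSums(A))
  if (!is.na(orient) && orient < 0) { score <- -score; w <- -w }
  cuts <- quantile(score, c(1 / 3, 2 / 3), type = 7, names = FALSE)
  tercile <- 1L + (score > cuts[1]) + (score > cuts[2])
  structure(list(score = unname(score), tercile = unname(tercile),
                 tercile_label = c("poor", "medium", "wealthy")[tercile],
                 loadings = w,
                 prop_variance = pc$sdev[1]^2 / sum(pc$sdev^2),
                 dropped = dropped),
            class = "wealth_index")
}

#' Frequency table of the sample by covariate categories
#'
#' @param covariates a `covariate_design` (from [read_survey()] or built
#'   from a `synthetic_survey`) or a raw data.frame of categorical columns.
#' @return data.frame with `covariate`, `category`, `count`, `percent`.
#' @export
summarize_sample <- function(covariates) {
  raw <- if (inherits(covariates, "covariate_design")) covariates$raw
         else as.data.frame(covariates)
  do.call(rbind, lapply(names(raw), function(nm) {
    tb <- table(factor(raw[[nm]]))
    data.frame(covariate = nm, category = names(tb),
               count = as.integer(tb),
               percent = 100 * as.integer(tb) / nrow(raw),
               stringsAsFactors = FALSE)
  }))
}
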