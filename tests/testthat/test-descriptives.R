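toy_responses <- function(rows) {
  Y <- matrix(0L, length(rows), 15)
  for (i in seq_along(rows)) if (rows[i] > 0) Y[i, seq_len(rows[i])] <- 1L
  item_response_matrix(Y)
}

test_that("item prevalence is the column percentage", {
  Y <- item_response_matrix(matrix(0L, 10, 15))
  expect_true(all(item_prevalence(Y)$percent == 0))
  Y2 <- matrix(0L, 4, 15); Y2[, 1] <- c(1L, 1L, 0L, 0L)
  pv <- item_prevalence(item_response_matrix(Y2))
  expect_equal(pv$percent[1], 50)
  expect_equal(pv$n_yes[1], 2)
  expect_error(item_prevalence(matrix(0L, 0, 15)), "empty")
})

test_that("stratified prevalence splits by stratum and keeps denominators", {
  Y <- matrix(0L, 6, 15); Y[, 2] <- c(1L, 1L, 1L, 0L, 0L, 0L)
  by <- c("a", "a", "b", "b", "b", "b")
  pv <- item_prevalence(item_response_matrix(Y), by = by)
  expect_equal(nrow(pv), 30)
  expect_equal(pv$percent[pv$stratum == "a" & pv$item == 2], 100)
  expect_equal(pv$percent[pv$stratum == "b" & pv$item == 2], 25)
})

test_that("acts distribution counts thresholds and the at-least-half rule", {
  ad <- acts_distribution(toy_responses(c(0, 7, 15)))
  expect_equal(ad$cumulative$count[1], 2)    # >= 1 act
  expect_equal(ad$cumulative$count[8], 1)    # >= 8 acts ("at least half")
  expect_equal(ad$cumulative$count[15], 1)
  expect_equal(ad$n_at_least_half, 1)
  expect_true(all(diff(ad$cumulative$count) <= 0))
  ad0 <- acts_distribution(item_response_matrix(matrix(0L, 5, 15)))
  expect_true(all(ad0$cumulative$count == 0))
  expect_equal(ad0$n_at_least_one, 0)
})

test_that("stratified cumulative counts sum to the overall curve", {
  p <- random_params(3)
  sv <- generate_survey(p, 2000, seed = 11)
  Y <- item_response_matrix(sv$responses)
  by <- sv$covariates_raw$site
  tot <- acts_distribution(Y)$cumulative
  str <- acts_distribution(Y, by = by)$cumulative
  agg <- tapply(str$count, str$threshold, sum)
  agg <- agg[order(as.numeric(names(agg)))]
  expect_equal(as.numeric(agg), tot$count)
  # exact identity: n at >=1 equals n minus all-zero rows
  expect_equal(tot$count[1], sum(rowSums(sv$responses) > 0))
})

test_that("wealth index equals the eigendecomposition oracle up to sign", {
  set.seed(21)
  assets <- matrix(rbinom(400 * 8, 1, runif(8, 0.2, 0.8)), 400, 8,
                   byrow = TRUE)
  w <- wealth_index(assets)
  Z <- scale(assets)
  ev <- eigen(cor(assets), symmetric = TRUE)
  sc <- drop(Z %*% ev$vectors[, 1])
  if (cor(sc, rowSums(assets)) < 0) sc <- -sc
  expect_lt(max(abs(w$score - sc)), 1e-8)
  expect_equal(sort(unique(w$tercile)), 1:3)
  sizes <- table(w$tercile)
  expect_lt(max(sizes) - min(sizes), 1 + sum(duplicated(w$score)))
})

test_that("terciles are monotone in a strictly ordered asset battery", {
  n <- 30
  assets <- outer(seq_len(n), seq_len(12), ">=") * 1L  # respondent i owns first i
  assets <- assets[, colSums(assets) < n & colSums(assets) > 0]
  w <- wealth_index(assets)
  expect_true(all(diff(w$tercile) >= 0))
})

test_that("degenerate asset input is dropped or fatal", {
  assets <- cbind(a = rep(1L, 50), b = rbinom(50, 1, 0.5),
                  c = rbinom(50, 1, 0.5))
  expect_warning(w <- wealth_index(assets), "zero-variance")
  expect_equal(w$dropped, "a")
  expect_error(suppressWarnings(wealth_index(cbind(rep(1L, 10), rep(0L, 10)))),
               "nonzero variance")
})

test_that("sample summary reproduces generator marginals", {
  spec <- vaw_covariate_spec()
  set.seed(5)
  raw <- generate_covariates(spec, 50000)
  sm <- summarize_sample(raw)
  for (nm in c("site", "eversex")) {
    for (i in seq_along(spec[[nm]]$levels)) {
      lv <- spec[[nm]]$levels[i]; pr <- spec[[nm]]$probs[i]
      got <- sm$percent[sm$covariate == nm & sm$category == lv] / 100
      expect_lt(abs(got - pr), 3.5 * sqrt(pr * (1 - pr) / 50000))
    }
  }
  one <- summarize_sample(raw[1, , drop = FALSE])
  expect_true(all(one$percent %in% c(0, 100)))
})
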