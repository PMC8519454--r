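test_that("all-zero parameters give 50% prevalence on every item", {
  p <- vaw_preset("null")
  sv <- generate_survey(p, 10000, seed = 1)
  prev <- colMeans(sv$responses)
  expect_true(all(abs(prev - 0.5) < 3 * sqrt(0.25 / 10000) + 1e-9))
  expect_equal(marginal_item_probability(p, NULL, 1), 0.5)
})

test_that("an intercept-only item converges to the normal upper-tail probability", {
  p <- vaw_preset("null")
  p$nu[] <- -1.5
  sv <- generate_survey(p, 200000, seed = 2)
  target <- pnorm(-1.5)   # P(y* > 0) with y* ~ N(-1.5, 1)
  se <- sqrt(target * (1 - target) / 200000)
  expect_true(all(abs(colMeans(sv$responses) - target) < 3.5 * se))
})

test_that("a single loading leaves the marginal probability at one half", {
  p <- vaw_preset("null")
  p$Lambda[1, 1] <- 1
  expect_equal(marginal_item_probability(p, NULL, 1), 0.5)
})

test_that("pairwise tetrachoric converges to the implied closed form", {
  # two items on one factor, no covariates: rho = l1 l2 / sqrt((l1^2+1)(l2^2+1))
  p <- vaw_preset("null")
  l1 <- 0.8; l2 <- 1.1
  p$Lambda[1, 1] <- l1; p$Lambda[2, 1] <- l2
  p$nu[1:2] <- c(-0.5, -1)
  sv <- generate_survey(p, 100000, seed = 3)
  est <- tetrachoric_matrix(sv$responses[, 1:2, drop = FALSE])
  closed <- l1 * l2 / sqrt((l1^2 + 1) * (l2^2 + 1))
  expect_lt(abs(est$rho[1, 2] - closed), 0.012)
  expect_equal(implied_ystar_correlation(p)[1, 2], closed, tolerance = 1e-12)
})

test_that("marginal_item_probability matches empirical frequencies from the generator", {
  p <- random_params(4)
  sv <- generate_survey(p, 100000, seed = 5)
  prev_emp <- colMeans(sv$responses)
  prev_th <- population_item_prevalence(p)
  se <- sqrt(prev_th * (1 - prev_th) / 100000)
  expect_true(all(abs(prev_emp - prev_th) < 3.5 * se))
})

test_that("a fixed seed reproduces the survey bit for bit", {
  p <- random_params(6)
  a <- generate_survey(p, 500, seed = 42)
  b <- generate_survey(p, 500, seed = 42)
  expect_identical(a$responses, b$responses)
  expect_identical(a$covariates_raw, b$covariates_raw)
  expect_identical(a$assets, b$assets)
  d <- generate_survey(p, 500, seed = 43)
  expect_false(identical(a$responses, d$responses))
})

test_that("non positive definite Psi is rejected naming the matrix", {
  spec <- vaw_covariate_spec()
  info <- covariate_design_info(spec)
  Psi_bad <- matrix(c(1, 1.2, 0, 1.2, 1, 0, 0, 0, 1), 3, 3)
  expect_error(
    mimic_parameters(rep(0, 15), matrix(0, 15, 3),
                     matrix(0, 15, length(info$colnames)),
                     matrix(0, 3, length(info$colnames)), Psi_bad, spec),
    "Psi")
})

test_that("the study preset reproduces its published-scale values", {
  p <- vaw_preset("dreams")
  s <- standardize_parameters(p)
  expect_equal(unname(s$Lambda_std[7, 2]), 0.943, tolerance = 1e-10)
  expect_equal(s$factor_cor[2, 1], 0.575, tolerance = 1e-10)
  expect_equal(s$factor_cor[3, 1], 0.446, tolerance = 1e-10)
  expect_equal(s$factor_cor[3, 2], 0.467, tolerance = 1e-10)
  # intercepts calibrated to the target prevalences
  prev <- population_item_prevalence(p)
  expect_equal(prev[3], 0.265, tolerance = 1e-7)
  expect_equal(prev[11], 0.016, tolerance = 1e-7)
  # five noninvariant direct effects present with the reported signs
  expect_equal(sum(p$A != 0), 7)
  expect_lt(p$A[10, "site:Viwandani"], 0)
  expect_gt(p$A[15, "hungry:yes"], 0)
})

test_that("standardize/unstandardize round-trips to machine precision", {
  p <- vaw_preset("dreams")
  s <- standardize_parameters(p)
  prev <- population_item_prevalence(p)
  p2 <- parameters_from_standardized(s$Lambda_std, s$B_std, s$A_std,
                                     s$factor_cor, prev,
                                     p$covariate_spec, p$major)
  expect_equal(p2$Lambda, p$Lambda, tolerance = 1e-10)
  expect_equal(p2$B, p$B, tolerance = 1e-10)
  expect_equal(p2$Psi, p$Psi, tolerance = 1e-10)
  expect_equal(p2$nu, p$nu, tolerance = 1e-8)
})

test_that("dummy covariance matches empirical covariate draws", {
  spec <- vaw_covariate_spec()
  info <- covariate_design_info(spec)
  set.seed(9)
  raw <- generate_covariates(spec, 50000)
  X <- dummy_code(raw, spec)
  expect_lt(max(abs(colMeans(X) - info$mu)), 0.01)
  expect_lt(max(abs(cov(X) - info$Sigma)), 0.012)
})
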