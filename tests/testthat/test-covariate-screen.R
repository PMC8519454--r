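test_that("intercept-only probit recovers the probit of the mean", {
  set.seed(41)
  y <- rbinom(400, 1, 0.3)
  f <- probit_fit(y)
  expect_equal(unname(f$coefficients[1]), qnorm(mean(y)), tolerance = 1e-8)
})

test_that("probit log-likelihood matches an independent optimizer", {
  set.seed(42)
  X <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(200, 1, pnorm(-0.5 + X %*% c(0.8, -0.4, 0)))
  f <- probit_fit(y, X)
  nll <- function(b) {
    eta <- b[1] + X %*% b[-1]
    -sum(y * pnorm(eta, log.p = TRUE) + (1 - y) * pnorm(-eta, log.p = TRUE))
  }
  o <- optim(rep(0, 4), nll, method = "BFGS",
             control = list(maxit = 500, reltol = 1e-14))
  expect_lt(abs(f$loglik - (-o$value)), 1e-6)
})

test_that("separation is flagged and still yields a finite fit", {
  y <- c(rep(0, 20), rep(1, 20))
  X <- matrix(c(rep(0, 20), rep(1, 20)), ncol = 1,
              dimnames = list(NULL, "z"))
  expect_warning(f <- probit_fit(y, X), "separation")
  expect_true(f$separation)
  expect_true(is.finite(f$loglik))
})

test_that("the LRT matches the chi-square tail and rejects non-nesting", {
  expect_equal(lrt(-10, -10, 1)$statistic, 0)
  expect_equal(lrt(-10, -10, 1)$p_value, 1)
  expect_equal(lrt(-8.0795, -10, 1)$p_value, 0.05, tolerance = 1e-3)
  expect_equal(lrt(-5, -8, 2)$p_value, pchisq(6, 2, lower.tail = FALSE))
  expect_error(lrt(-10, -5, 1), "nested")
})

test_that("LRT rejection rate under the null is near nominal", {
  set.seed(43)
  rej <- replicate(400, {
    x <- rbinom(300, 1, 0.5)
    z <- rbinom(300, 1, 0.4)
    y <- rbinom(300, 1, pnorm(-0.8 + 0.3 * z))   # x truly inert
    full <- probit_fit(y, cbind(z = z, x = x))
    red <- probit_fit(y, cbind(z = z))
    lrt(full$loglik, red$loglik, 1)$p_value <= 0.05
  })
  p <- mean(rej)
  expect_true(p > 0.05 - 3 * sqrt(0.05 * 0.95 / 400) &
              p < 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("an injected direct effect is screened in and inert ones mostly out", {
  p <- vaw_preset("dreams_null")
  info <- covariate_design_info(p$covariate_spec)
  p$A[5, "educ:incomplete_secondary"] <- 0.5
  sv <- generate_survey(p, 5000, seed = 51)
  sc <- run_screen(item_response_matrix(sv$responses), survey_design(sv))
  expect_true("educ" %in% sc$direct_map[["item05"]])
  expect_true(all(c("invited", "site", "agegrp") %in% sc$direct_map[["item01"]]))
  # stage-2 survivors are a subset of stage-1 survivors
  for (j in 1:15) {
    extra <- setdiff(sc$direct_map[[sprintf("item%02d", j)]], sc$always)
    if (length(extra) > 0)
      expect_true(all(sc$stage1_p[j, extra] <= 0.10))
  }
})

test_that("tightening alpha1 never enlarges the candidate set", {
  p <- random_params(10)
  sv <- generate_survey(p, 1500, seed = 52)
  Y <- item_response_matrix(sv$responses)
  cd <- survey_design(sv)
  loose <- run_screen(Y, cd, alpha1 = 0.20)
  tight <- run_screen(Y, cd, alpha1 = 0.05)
  for (j in sprintf("item%02d", 1:15))
    expect_true(all(tight$direct_map[[j]] %in% loose$direct_map[[j]]))
})

test_that("a constant covariate is dropped with a warning and never selected", {
  p <- random_params(10)
  sv <- generate_survey(p, 500, seed = 53)
  cd <- survey_design(sv)
  cd$raw$religion <- "Muslim"
  cd$X <- dummy_code(cd$raw, cd$codebook)
  Y <- item_response_matrix(sv$responses)
  expect_warning(sc <- run_screen(Y, cd), "constant")
  expect_equal(sc$dropped, "religion")
  expect_false(any(vapply(sc$direct_map, function(m) "religion" %in% m,
                          logical(1))))
})
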