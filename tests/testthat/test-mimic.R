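# Small shared fit so several properties can be checked on one run.
small_fit <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      p <- vaw_preset("dreams")
      sv <- generate_survey(p, 600, seed = 61)
      val <<- list(
        sv = sv,
        fit = mimic_fit(sv$responses, survey_design(sv),
                        truth_direct_map(sv),
                        mimic_config(chains = 2, iter = 1200, burn = 600,
                                     thin = 2, ppp_every = 3), seed = 62))
    }
    val
  }
})

test_that("every retained draw satisfies the identification constraints", {
  fit <- small_fit()$fit
  for (ch in fit$chains) {
    Psi <- ch$Psi
    expect_true(all(abs(Psi[, c(1, 5, 9)] - 1) < 1e-12))
    # symmetric correlation entries within [-1, 1]
    expect_true(all(abs(Psi[, c(2, 3, 6)]) <= 1))
    expect_equal(Psi[, 2], Psi[, 4])
  }
})

test_that("the recorded discrepancy matches an R recomputation", {
  st <- small_fit()
  fit <- st$fit; sv <- st$sv
  ch <- fit$chains[[1]]
  ppe <- fit$config$ppp_every
  for (d in c(1, 11)) {   # discrepancies recorded every ppe-th retained draw
    k <- (d - 1) * ppe + 1
    D_r <- vawinvar:::mimic_discrepancy(
      nu = ch$nu[k, ], Lambda = matrix(ch$Lambda[k, ], 15, 3),
      A = matrix(ch$A[k, ], 15, ncol(fit$X)),
      B = matrix(ch$B[k, ], 3, ncol(fit$X)),
      Psi = matrix(ch$Psi[k, ], 3, 3), X = fit$X, Y = fit$Y)
    expect_equal(ch$D_obs[d], D_r, tolerance = 1e-8)
  }
})

test_that("summaries are invariant to chain relabeling", {
  fit <- small_fit()$fit
  fit2 <- fit
  fit2$chains <- rev(fit2$chains)
  s1 <- mimic_standardize(fit, force = TRUE)
  s2 <- mimic_standardize(fit2, force = TRUE)
  expect_equal(s1$loadings$mean, s2$loadings$mean)
  expect_equal(s1$factor_cor$mean, s2$factor_cor$mean)
  expect_equal(sort(s1$direct_effects$mean), sort(s2$direct_effects$mean))
})

test_that("standardized loadings follow the closed form in a null structure", {
  # no covariate effects, Psi = I: lambda* = lambda / sqrt(lambda'lambda + 1)
  p <- vaw_preset("null")
  p$Lambda[cbind(1:15, vaw_major_factor())] <- 0.9
  s <- standardize_parameters(p)
  expect_equal(s$Lambda_std[cbind(1:15, vaw_major_factor())],
               rep(0.9 / sqrt(0.9^2 + 1), 15), tolerance = 1e-12)
})

test_that("no direct effects means no noninvariance flags", {
  p <- vaw_preset("dreams_null")
  sv <- generate_survey(p, 400, seed = 63)
  fit <- mimic_fit(sv$responses, survey_design(sv), direct_map = NULL,
                   mimic_config(chains = 2, iter = 600, burn = 300,
                                thin = 1, ppp_every = 0), seed = 64)
  s <- mimic_standardize(fit, force = TRUE)
  expect_null(s$direct_effects)
  expect_equal(nrow(flag_noninvariance(s)), 0)
})

test_that("shrinking the loading prior drives loadings to zero monotonically", {
  p <- vaw_preset("dreams")
  sv <- generate_survey(p, 400, seed = 65)
  mag <- vapply(c(25, 0.05, 0.002), function(v) {
    fit <- mimic_fit(sv$responses, survey_design(sv), NULL,
                     mimic_config(chains = 1, iter = 400, burn = 200,
                                  thin = 1, v_major = v, v_cross = min(v, 0.04),
                                  ppp_every = 0), seed = 66)
    mean(abs(colMeans(fit$chains[[1]]$Lambda)[
      (1:15) + 15 * (vaw_major_factor() - 1)]))
  }, numeric(1))
  expect_true(mag[1] > mag[2] && mag[2] > mag[3])
  expect_lt(mag[3], mag[1] / 3)
})

test_that("compute_ppp requires enough recorded discrepancies", {
  fit <- small_fit()$fit
  expect_true(compute_ppp(fit) >= 0 && compute_ppp(fit) <= 1)
  trunc_fit <- fit
  for (i in seq_along(trunc_fit$chains))
    for (el in c("D_obs", "D_rep", "T_obs", "T_rep"))
      trunc_fit$chains[[i]][[el]] <- trunc_fit$chains[[i]][[el]][1:10]
  expect_error(compute_ppp(trunc_fit), "fewer than 100")
  expect_error(compute_ppp(trunc_fit, "deviance"), "fewer than 100")
})

test_that("an unknown direct-map column is rejected", {
  p <- vaw_preset("dreams_null")
  sv <- generate_survey(p, 100, seed = 67)
  dm <- rep(list("nope:column"), 15)
  expect_error(mimic_fit(sv$responses, survey_design(sv), dm,
                         mimic_config(chains = 1, iter = 10, burn = 5),
                         seed = 1),
               "unknown design column")
})
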