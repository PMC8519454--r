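test_that("geomin criterion: zero matrix, symmetry, and formula oracle", {
  Z <- matrix(0, 15, 3)
  expect_equal(geomin_criterion(Z, 0.001), 15 * 0.001)
  set.seed(31)
  L <- matrix(rnorm(8), 4, 2)
  expect_equal(geomin_criterion(L, 0.001), oracle_geomin(L, 0.001),
               tolerance = 1e-12)
  perm <- L[, c(2, 1)]
  flip <- L %*% diag(c(-1, 1))
  expect_equal(geomin_criterion(perm, 0.01), geomin_criterion(L, 0.01))
  expect_equal(geomin_criterion(flip, 0.01), geomin_criterion(L, 0.01))
})

test_that("extraction reproduces an exact orthogonal-factor structure", {
  set.seed(32)
  L0 <- matrix(0, 15, 3)
  L0[cbind(1:15, vaw_major_factor())] <- runif(15, 0.5, 0.9)
  L0[2, 2] <- 0.3; L0[12, 2] <- 0.25
  S <- tcrossprod(L0); diag(S) <- 1
  ex <- esem_extract(S, 3)
  expect_lt(ex$F_min, 1e-10)
  # recovered subspace spans L0: Procrustes residual tiny
  sv <- svd(t(ex$Lambda) %*% L0)
  Q <- sv$u %*% t(sv$v)
  expect_lt(max(abs(ex$Lambda %*% Q - L0)), 1e-5)
  # identity matrix: all loadings zero
  ex0 <- esem_extract(diag(15), 2)
  expect_lt(max(abs(ex0$Lambda)), 1e-6)
  expect_lt(ex0$F_min, 1e-12)
})

test_that("adding factors never increases the discrepancy", {
  p <- random_params(9)
  sv <- generate_survey(p, 5000, seed = 15)
  tet <- tetrachoric_matrix(sv$responses)
  f1 <- esem_extract(tet, 1)$F_min
  f2 <- esem_extract(tet, 2)$F_min
  f3 <- esem_extract(tet, 3)$F_min
  expect_lte(f2, f1 + 1e-10)
  expect_lte(f3, f2 + 1e-10)
  expect_lt(f3, f1)   # strictly better on 3-factor data
})

test_that("rotation preserves the model-implied correlation matrix", {
  set.seed(33)
  L0 <- matrix(0, 15, 3)
  L0[cbind(1:15, vaw_major_factor())] <- runif(15, 0.5, 0.9)
  S <- tcrossprod(L0); diag(S) <- 1
  ex <- esem_extract(S, 3)
  rot <- rotate_geomin(ex$Lambda, n_starts = 10, seed = 2)
  implied_before <- tcrossprod(ex$Lambda)
  implied_after <- rot$Lambda_rotated %*% rot$Phi %*% t(rot$Lambda_rotated)
  expect_lt(max(abs(implied_before - implied_after)), 1e-8)
  expect_equal(diag(rot$Phi), rep(1, 3))
  # majors aligned positive to the WHO pattern
  majors <- rot$Lambda_rotated[cbind(1:15, vaw_major_factor())]
  expect_true(all(majors > 0))
})

test_that("fit indices satisfy boundary identities and clamps", {
  resid <- rep(0.01, 105); v <- rep(1e-4, 105)
  f <- esem_fit_indices(T = 63, df = 63, T_B = 4000, df_B = 105, n = 1000,
                        residuals = resid, v = v, adjust = "none")
  expect_equal(f$RMSEA, 0)
  f2 <- esem_fit_indices(T = 0, df = 63, T_B = 4000, df_B = 105, n = 1000,
                         residuals = resid, v = v, adjust = "none")
  expect_equal(f2$CFI, 1)
  expect_true(f2$TLI >= 0 && f2$TLI <= 1)
  expect_equal(f$WRMR, sqrt(sum(resid^2 / v) / 105))
  expect_error(esem_fit_indices(10, 63, 50, 50, 100, resid, v), "baseline")
})

test_that("RMSEA interval matches a bisection oracle", {
  cases <- list(c(90, 63, 1081), c(200, 63, 5000), c(63.5, 63, 1000))
  for (cs in cases) {
    ci <- vawinvar:::rmsea_ci(cs[1], cs[2], cs[3], level = 0.90)
    expect_lt(abs(ci["lower"] -
                  oracle_rmsea_limit(cs[1], cs[2], cs[3], 0.95)), 1e-6)
    expect_lt(abs(ci["upper"] -
                  oracle_rmsea_limit(cs[1], cs[2], cs[3], 0.05)), 1e-6)
    point <- sqrt(max(cs[1] - cs[2], 0) / (cs[2] * cs[3]))
    expect_lte(ci["lower"], point + 1e-12)
    expect_gte(ci["upper"], point - 1e-12)
  }
})

test_that("the full ESEM stage recovers the generating pattern", {
  p <- vaw_preset("dreams")
  sv <- generate_survey(p, 20000, seed = 16)
  sol <- esem(sv$responses, 3, seed = 3)
  truth <- standardize_parameters(p)
  expect_lt(max(abs(sol$Lambda_rotated - truth$Lambda_std)), 0.1)
  expect_lt(max(abs(sol$Phi[lower.tri(sol$Phi)] -
                    truth$factor_cor[lower.tri(truth$factor_cor)])), 0.1)
  expect_gt(sol$fit$CFI, 0.95)
  expect_lt(sol$fit$RMSEA, 0.06)
  expect_lt(sol$fit$WRMR, 1.0)
  sol1 <- esem(sv$responses, 1, seed = 3, align = NULL)
  expect_lt(sol1$fit$CFI, sol$fit$CFI)
})
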