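test_that("expected covariance blocks follow the kinship weights", {
  # pure E: both groups identity
  ec <- expected_cov("ACE", list(a = 0, c = 0, e = 1))
  expect_equal(ec$sigma_mz, diag(2))
  expect_equal(ec$sigma_dz, diag(2))

  # AE with a2 = 0.39: cross-twin covariance 0.39 (MZ) and 0.195 (DZ)
  ec <- expected_cov("AE", list(a = sqrt(0.39), e = sqrt(0.61)))
  expect_equal(ec$sigma_mz[1, 2], 0.39, tolerance = 1e-12)
  expect_equal(ec$sigma_dz[1, 2], 0.195, tolerance = 1e-12)

  # ADE with a2 = d2 = 0.2: MZ cross 0.4, DZ cross 0.5*0.2 + 0.25*0.2
  ec <- expected_cov("ADE", list(a = sqrt(0.2), d = sqrt(0.2), e = sqrt(0.6)))
  expect_equal(ec$sigma_mz[1, 2], 0.4, tolerance = 1e-12)
  expect_equal(ec$sigma_dz[1, 2], 0.15, tolerance = 1e-12)

  # C and D together are not identifiable
  expect_error(twinstab:::check_components(c("A", "C", "D", "E")),
               "not jointly identifiable")
  expect_error(build_cholesky(1), "W >= 2")
  expect_error(build_common_pathway(2), "W >= 3")
  expect_error(build_correlated_factors(1), "V >= 2")
})

test_that("standardization arithmetic and rG structure are exact", {
  spec <- build_univariate("AE")
  s <- spec$summarize(c(0.66, 0.75, 0))
  expect_equal(unname(s["a2"]), 0.66^2 / (0.66^2 + 0.75^2), tolerance = 1e-9)
  expect_equal(unname(s["e2"]), 0.75^2 / (0.66^2 + 0.75^2), tolerance = 1e-9)
  expect_equal(sum(s), 1, tolerance = 1e-9)

  # diagonal A (angles at pi/2) gives rG = 0
  spec2 <- build_correlated_factors(2)
  th <- spec2$start
  th[grep("^angle_", names(th))] <- pi / 2
  s2 <- spec2$summarize(th)
  expect_equal(unname(s2["rG_21"]), 0, tolerance = 1e-9)

  # shares from Monte-Carlo component draws match the analytic shares
  sim <- simulate_twins(default_sim_config("cholesky", seed = 23,
                                           n_mz = 50000, n_dz = 50000))
  tm <- twin_matrices(sim$data)
  # empirical MZ cross-twin covariance estimates A + E*0 contributions:
  # total variance split checked against truth shares
  emp_tot <- diag(cov(rbind(tm$MZ[, 1:6], tm$MZ[, 7:12],
                            tm$DZ[, 1:6], tm$DZ[, 7:12])))
  emp_A <- diag((cov(tm$MZ)[1:6, 7:12] - cov(tm$DZ)[1:6, 7:12]) * 2)
  expect_lt(max(abs(emp_A / emp_tot - sim$truth$shares$A)), 0.03)
})

test_that("Cholesky share decomposition is complete and PSD by construction", {
  spec <- build_cholesky(3, c("A", "E"))
  set.seed(3)
  th <- rnorm(spec$n_par)
  s <- spec$summarize(th)
  for (w in 1:3) {
    tot <- sum(s[grep(sprintf("^[ae][0-9]_w%d$", w), names(s))])
    expect_equal(tot, 1, tolerance = 1e-6)
  }
  expect_true(all(s[grep("^[ae][0-9]_", names(s))] >= 0))
  # implied component matrices have nonnegative eigenvalues
  gm <- spec$builder(th)
  expect_true(all(eigen(gm$MZ$sigma, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))
})

test_that("common pathway with zero loadings degenerates to independent univariate AE", {
  sim <- simulate_twins(default_sim_config("common_pathway", seed = 25,
                                           n_mz = 300, n_dz = 500))
  d3 <- sim$data
  # fit univariate AE per wave (waves independent under lambda = 0)
  W <- 3
  unis <- lapply(1:W, function(w) fit_univariate(d3, wave = w, family = "AE",
                                                 n_starts = 1))
  # assemble the equivalent CPM parameter vector: lambda = 0, specifics and
  # means at the univariate solutions
  spec <- build_common_pathway(W, c("A", "E"))
  th <- spec$start
  th[sprintf("lambda_w%d", 1:W)] <- 0
  th[sprintf("a_s_w%d", 1:W)] <- vapply(unis, function(f) unname(f$par["a"]), 0)
  th[sprintf("e_s_w%d", 1:W)] <- vapply(unis, function(f) unname(f$par["e"]), 0)
  th[sprintf("mean_w%d", 1:W)] <- vapply(unis, function(f) unname(f$par["mean"]), 0)
  m2_cpm <- neg2_loglik(spec, th, twin_matrices(d3, waves = 1:W))
  m2_uni <- sum(vapply(unis, `[[`, 0, "minus2LL"))
  expect_equal(m2_cpm, m2_uni, tolerance = 1e-6)
})

test_that("correlated-factor and Cholesky coordinates reach the same optimum", {
  sim <- simulate_twins(default_sim_config("correlated_factors", seed = 27,
                                           n_mz = 400, n_dz = 700))
  chol_fit <- fit_cholesky(sim$data, n_starts = 3, seed = 2)
  cf_fit <- fit_correlated_factors(sim$data, n_starts = 3, seed = 2)
  expect_lt(abs(chol_fit$minus2LL - cf_fit$minus2LL), 1e-5)
  expect_identical(chol_fit$k, cf_fit$k)
})

test_that("unit rG and rE collapse the bivariate model to one common factor", {
  p <- list(sd_a = c(0.6, 0.6), sd_e = c(0.8, 0.8),
            R_a = matrix(1, 2, 2), R_e = matrix(1, 2, 2))
  sl <- twinstab:::sim_loadings(sim_config(10, 10, 2, "correlated_factors",
                                           params = p))
  comps <- twinstab:::implied_comps(sl$loadings)
  within <- Reduce(`+`, comps)
  expect_equal(within[1, 2], within[1, 1], tolerance = 1e-9)
})

test_that("nesting ladder: -2LL is monotone from E to AE to ACE/ADE", {
  d <- small_twin_data(400, 600, W = 1, seed = 29)
  fits <- lapply(setNames(c("E", "AE", "ACE", "ADE"),
                          c("E", "AE", "ACE", "ADE")),
                 function(f) fit_univariate(d, family = f, n_starts = 2))
  expect_gte(fits$E$minus2LL, fits$AE$minus2LL - 1e-6)
  expect_gte(fits$AE$minus2LL, fits$ACE$minus2LL - 1e-6)
  expect_gte(fits$AE$minus2LL, fits$ADE$minus2LL - 1e-6)
})
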