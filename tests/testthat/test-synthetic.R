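test_that("pure-A and pure-E limits give the expected cross-twin structure", {
  # a2 = 1: MZ co-twins are genetically identical copies
  sim <- simulate_twins(sim_config(500, 2000, 1, "univariate",
                                   params = list(a = 1, e = 0), seed = 1))
  mz <- sim$data[sim$data$zygosity == "MZ", ]
  expect_equal(mz$score_w1_t1, mz$score_w1_t2, tolerance = 1e-12)
  dz <- sim$data[sim$data$zygosity == "DZ", ]
  expect_lt(abs(cor(dz$score_w1_t1, dz$score_w1_t2) - 0.5), 0.06)

  # a2 = 0: co-twins independent in both groups
  sim0 <- simulate_twins(sim_config(3000, 3000, 1, "univariate",
                                    params = list(a = 0, e = 1), seed = 2))
  for (z in c("MZ", "DZ")) {
    d <- sim0$data[sim0$data$zygosity == z, ]
    expect_lt(abs(cov(d$score_w1_t1, d$score_w1_t2)), 0.06)
  }
})

test_that("fixed seed gives bit-identical simulated data", {
  cfg <- default_sim_config("cholesky", seed = 77, n_mz = 100, n_dz = 150,
                            missing_rate = 0.2)
  expect_identical(simulate_twins(cfg), simulate_twins(cfg))
})

test_that("every structure's empirical covariances match the implied ones", {
  # moderate n here; the n = 50,000 convergence check lives in the
  # acceptance suite
  for (s in c("cholesky", "common_pathway", "correlated_factors")) {
    sim <- simulate_twins(default_sim_config(s, seed = 31, n_mz = 20000,
                                             n_dz = 20000))
    tm <- twin_matrices(sim$data)
    expect_lt(max(abs(cov(tm$MZ) - sim$truth$sigma_mz)), 0.05)
    expect_lt(max(abs(cov(tm$DZ) - sim$truth$sigma_dz)), 0.05)
    # MZ cross-twin covariance dominates DZ entrywise for nonneg A, no C/D
    W <- ncol(tm$MZ) / 2
    cross_mz <- sim$truth$sigma_mz[1:W, W + 1:W]
    cross_dz <- sim$truth$sigma_dz[1:W, W + 1:W]
    expect_true(all(cross_mz - cross_dz >= -1e-12))
  }
})

test_that("truth record shares are standardized and sum to one", {
  for (s in c("univariate", "cholesky", "common_pathway",
              "correlated_factors")) {
    sim <- simulate_twins(default_sim_config(s, seed = 5, n_mz = 50,
                                             n_dz = 50))
    tot <- Reduce(`+`, sim$truth$shares)
    expect_equal(unname(tot), rep(1, length(tot)), tolerance = 1e-9)
  }
})

test_that("invalid truths are rejected with a diagnostic naming the block", {
  p <- default_sim_params("correlated_factors")
  p$R_a <- matrix(c(1, 1.2, 1.2, 1), 2)
  expect_error(simulate_twins(sim_config(10, 10, 2, "correlated_factors",
                                         params = p)),
               "R_a.*not positive semi-definite")
  cp <- default_sim_params("common_pathway")
  cp$latent <- c(a = 1, e = 1)
  expect_error(simulate_twins(sim_config(10, 10, 6, "common_pathway",
                                         params = cp)),
               "squares summing to 1")
})

test_that("MCAR missingness has the right rate, determinism and retention", {
  d <- small_twin_data(1250, 1250, W = 2, seed = 8)
  expect_identical(apply_missingness(d, 0), d)
  expect_error(apply_missingness(d, 1), "rate")

  m1 <- suppressMessages(apply_missingness(d, 0.3, seed = 3))
  m2 <- suppressMessages(apply_missingness(d, 0.3, seed = 3))
  expect_identical(m1, m2)

  cells <- as.matrix(m1[, grep("^score_", names(m1))])
  # 2500 pairs x 4 cells = 10,000 Bernoulli(0.3) draws; the handful of
  # dropped all-missing pairs (P = 0.3^4) shifts the retained fraction by
  # well under one SE, so a 3 SE binomial band still applies
  frac <- mean(is.na(cells))
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
  # retained pairs all have at least one observed cell
  expect_true(all(rowSums(!is.na(cells)) > 0))
})

test_that("item simulator reproduces the implied correlation structure", {
  cfg <- sim_config(5000, 5000, 1, "item_factors",
                    params = default_sim_params("item_factors"), seed = 12)
  sim <- simulate_items(cfg)
  it <- item_scores(sim$data, one_per_pair = FALSE)
  expect_true(all(it >= 0 & it <= 4))
  expect_true(all(rowSums(it) <= 40))
  # Pearson correlations of discretized items are attenuated relative to
  # the latent implied matrix; compare against the 2-factor structure shape
  R <- cor(it)
  imp <- sim$truth$implied_correlations
  # ordering of correlation magnitudes is preserved: within-factor pairs
  # correlate more strongly than cross-factor pairs
  within1 <- R[1:6, 1:6][lower.tri(matrix(0, 6, 6))]
  cross <- as.vector(R[1:6, 7:9])
  expect_gt(min(within1), max(cross))
  # attenuation is bounded: observed r within 0.2 of implied, same sign
  off <- lower.tri(R)
  expect_lt(max(abs(R[off] - imp[off])), 0.2)

  # zero loadings: items essentially uncorrelated
  p0 <- list(loadings = matrix(0, 6, 2), phi = diag(2))
  sim0 <- simulate_items(sim_config(2000, 2000, 1, "item_factors",
                                    params = p0, seed = 4))
  R0 <- cor(item_scores(sim0$data, one_per_pair = FALSE))
  expect_lt(max(abs(R0[lower.tri(R0)])), 0.05)
})

test_that("item simulator rejects impossible communalities, flags degenerate items", {
  bad <- list(loadings = matrix(0.8, 4, 2), phi = matrix(c(1, .9, .9, 1), 2))
  expect_error(simulate_items(sim_config(10, 10, 1, "item_factors",
                                         params = bad)),
               "communality > 1")
  degen <- list(loadings = matrix(0.5, 4, 1), phi = diag(1),
                thresholds = c(-50, -40, -30, -20))
  expect_warning(simulate_items(sim_config(20, 20, 1, "item_factors",
                                           params = degen, seed = 1)),
                 "degenerate constant item")
})

test_that("skew emulation round-trips through the square-root transform", {
  p <- default_sim_params("univariate")
  p$skew_shift <- 2
  sim <- simulate_twins(sim_config(2000, 2000, 1, "univariate", params = p,
                                   seed = 6))
  raw <- sim$data$score_w1_t1
  tr <- sqrt_transform(sim$data)$score_w1_t1
  expect_gt(twinstab:::sample_skewness(raw), 0.5)
  expect_lt(abs(twinstab:::sample_skewness(tr)),
            abs(twinstab:::sample_skewness(raw)))
})
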