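test_that("CSV round-trip preserves the dataset and validation rejects bad input", {
  d <- small_twin_data(30, 40, W = 2, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_twin_csv(d, path)
  d2 <- load_twin_csv(path)
  expect_equal(as.data.frame(d2), as.data.frame(d), tolerance = 1e-12)

  # an all-missing pair is dropped with a message
  d3 <- as.data.frame(d)
  d3[1, grep("^score_", names(d3))] <- NA
  write.csv(d3, path, row.names = FALSE, na = "")
  expect_message(d4 <- load_twin_csv(path), "1 pair")
  expect_equal(nrow(d4), nrow(d) - 1)

  # unknown zygosity names the row; duplicated pair_id rejected
  d5 <- as.data.frame(d)
  d5$zygosity[7] <- "XZ"
  write.csv(d5, path, row.names = FALSE, na = "")
  expect_error(load_twin_csv(path), "zygosity.*7")
  d6 <- as.data.frame(d)
  d6$pair_id[2] <- d6$pair_id[1]
  write.csv(d6, path, row.names = FALSE, na = "")
  expect_error(load_twin_csv(path), "duplicated pair_id")
})

test_that("square-root transform is exact, NA-preserving, and rejects negatives", {
  df <- data.frame(pair_id = c("a", "b"), zygosity = c("MZ", "DZ"),
                   score_w1_t1 = c(0, 36), score_w1_t2 = c(NA, 9))
  d <- twin_dataset(df)
  tr <- sqrt_transform(d)
  expect_identical(tr$score_w1_t1, c(0, 6))
  expect_identical(tr$score_w1_t2, c(NA, 3))
  df$score_w1_t1[1] <- -1
  expect_error(sqrt_transform(twin_dataset(df)), "negative")
})

test_that("correlation estimators agree with the textbook formula", {
  set.seed(99)
  for (rep in 1:5) {
    df <- data.frame(pair_id = sprintf("p%d", 1:50),
                     zygosity = sample(c("MZ", "DZ"), 50, TRUE),
                     score_w1_t1 = rnorm(50), score_w1_t2 = rnorm(50),
                     score_w2_t1 = rnorm(50), score_w2_t2 = rnorm(50))
    d <- twin_dataset(df)
    lc <- longitudinal_correlations(d, one_per_pair = FALSE)
    m <- rbind(as.matrix(df[, c(3, 5)]), as.matrix(df[, c(4, 6)]))
    expect_equal(lc$r[1], bf_cor(m[, 1], m[, 2]), tolerance = 1e-12)

    ct <- crosstwin_correlations(d)
    for (z in c("MZ", "DZ")) {
      s <- df[df$zygosity == z, ]
      x <- c(s$score_w1_t1, s$score_w1_t2)
      y <- c(s$score_w1_t2, s$score_w1_t1)
      expect_equal(ct$r[ct$zygosity == z & ct$wave == 1], bf_cor(x, y),
                   tolerance = 1e-12)
    }
  }
})

test_that("longitudinal correlation recovers a known stability and degenerate cases", {
  # identical columns give r = 1
  df <- data.frame(pair_id = sprintf("p%d", 1:20), zygosity = "MZ",
                   score_w1_t1 = 1:20, score_w1_t2 = 1:20,
                   score_w2_t1 = 1:20, score_w2_t2 = 1:20)
  lc <- longitudinal_correlations(twin_dataset(df), one_per_pair = FALSE)
  expect_equal(lc$r[1], 1, tolerance = 1e-12)
  expect_true(lc$ci_lo[1] <= lc$r[1] && lc$r[1] <= lc$ci_hi[1])

  # generating phenotypic correlation 0.76, one twin per pair
  sim <- simulate_twins(default_sim_config("stability", seed = 14,
                                           n_mz = 1700, n_dz = 3300))
  lc <- longitudinal_correlations(sim$data, one_per_pair = TRUE, seed = 2)
  se <- (1 - 0.76^2) / sqrt(5000)
  expect_lt(abs(lc$r[1] - 0.76), 3 * se)

  # fewer than 3 complete observations is flagged undefined
  df$score_w2_t1 <- df$score_w2_t2 <- NA_real_
  df$score_w2_t1[1:2] <- c(1, 2)
  lc2 <- longitudinal_correlations(twin_dataset(df), one_per_pair = FALSE)
  expect_true(lc2$undefined[1])
})

test_that("cross-twin correlations honour kinship under an AE truth", {
  sim <- simulate_twins(default_sim_config("univariate", seed = 10,
                                           n_mz = 50000, n_dz = 50000))
  ct <- crosstwin_correlations(sim$data)
  expect_lt(abs(ct$r[ct$zygosity == "MZ"] - 0.39), 0.015)
  expect_lt(abs(ct$r[ct$zygosity == "DZ"] - 0.195), 0.015)

  # double entry: swapping twin labels leaves r unchanged
  d <- small_twin_data(40, 40, W = 1, seed = 3)
  swapped <- as.data.frame(d)
  swapped[, c("score_w1_t1", "score_w1_t2")] <-
    swapped[, c("score_w1_t2", "score_w1_t1")]
  expect_equal(crosstwin_correlations(d)$r,
               crosstwin_correlations(twin_dataset(swapped))$r,
               tolerance = 1e-12)
})

test_that("Fisher confidence intervals narrow with n and cover the estimate", {
  widths <- vapply(c(10, 50, 200, 1000), function(n)
    diff(twinstab:::fisher_ci(0.5, n)), 0)
  expect_true(all(diff(widths) < 0))
})

test_that("Cronbach alpha matches the Spearman-Brown oracle and edge cases", {
  # parallel continuous items with loading L: inter-item r = L^2 and
  # alpha = k r / (1 + (k-1) r); L chosen so the oracle gives ~0.91
  k <- 10; L <- sqrt(0.5028)
  r <- L^2
  alpha_sb <- k * r / (1 + (k - 1) * r)
  set.seed(21)
  n <- 10000
  make_items <- function(n) {
    f <- rnorm(n)
    sapply(1:k, function(i) L * f + sqrt(1 - L^2) * rnorm(n))
  }
  df <- data.frame(pair_id = sprintf("p%d", 1:n), zygosity = "MZ")
  it1 <- make_items(n); it2 <- make_items(n)
  colnames(it1) <- sprintf("item_w1_i%d_t1", 1:k)
  colnames(it2) <- sprintf("item_w1_i%d_t2", 1:k)
  d <- twin_dataset(cbind(df, it1, it2))
  a <- cronbach_alpha(d)
  expect_lt(abs(a$alpha - alpha_sb), 0.01)

  # independent items: alpha near 0; two identical items: alpha = 1
  it0 <- matrix(rnorm(n * 4), n, 4)
  colnames(it0) <- sprintf("item_w1_i%d_t1", 1:4)
  it0b <- matrix(rnorm(n * 4), n, 4)
  colnames(it0b) <- sprintf("item_w1_i%d_t2", 1:4)
  a0 <- cronbach_alpha(twin_dataset(cbind(df, it0, it0b)))
  expect_lt(abs(a0$alpha), 0.05)

  x <- rnorm(50)
  did <- data.frame(pair_id = sprintf("p%d", 1:50), zygosity = "MZ",
                    item_w1_i1_t1 = x, item_w1_i2_t1 = x,
                    item_w1_i1_t2 = x, item_w1_i2_t2 = x)
  expect_equal(cronbach_alpha(twin_dataset(did))$alpha, 1, tolerance = 1e-12)
})
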