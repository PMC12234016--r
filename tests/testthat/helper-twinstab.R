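# Shared fixtures and independent oracles for the test suite.

# Textbook multivariate-normal -2 log likelihood, row by row over each
# observed subvector: the brute-force oracle for the FIML engine.
bf_m2ll <- function(Y, mu, sigma) {
  total <- 0
  for (i in seq_len(nrow(Y))) {
    obs <- which(!is.na(Y[i, ]))
    if (!length(obs)) next
    x <- Y[i, obs] - mu[obs]
    S <- sigma[obs, obs, drop = FALSE]
    total <- total + length(obs) * log(2 * pi) +
      determinant(S)$modulus[1] + drop(t(x) %*% solve(S) %*% x)
  }
  total
}

# Textbook Pearson correlation from raw sums.
bf_cor <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# A small complete twin dataset for I/O and engine tests.
small_twin_data <- function(n_mz = 150, n_dz = 250, W = 2, seed = 42) {
  params <- if (W == 1) list(a = sqrt(0.5), e = sqrt(0.5), mean = 3)
  else {
    XA <- diag(sqrt(0.5), W); XA[lower.tri(XA)] <- 0.3
    XE <- diag(sqrt(0.5), W)
    list(a = XA, e = XE, mean = rep(3, W))
  }
  simulate_twins(sim_config(n_mz, n_dz, W,
                            if (W == 1) "univariate" else "cholesky",
                            params = params, seed = seed))$data
}

# Master seed for the recovery suites (fixed once for the whole suite).
SUITE_SEED <- 20260928

# Memoised univariate AIC-selection replicates (6,000 pairs each): the first
# 20 serve the heritability-recovery check, all 50 the selection-consistency
# check.
.uni_cache <- new.env(parent = emptyenv())
uni_recovery <- function() {
  if (!is.null(.uni_cache$res)) return(.uni_cache$res)
  seeds <- twinstab:::derive_seeds(SUITE_SEED + 1, 50)
  res <- lapply(seeds, function(s) {
    sim <- simulate_twins(default_sim_config("univariate", seed = s,
                                             n_mz = 2000, n_dz = 4000))
    sel <- select_univariate(sim$data, families = c("ACE", "ADE", "AE"),
                             n_starts = 1, se = FALSE)
    est <- standardize(sel$best)
    list(best = attr(sel$comparison, "best"),
         genetic_share = sum(est$estimate[est$quantity %in% c("a2", "d2")]))
  })
  .uni_cache$res <- list(
    best = vapply(res, `[[`, "", "best"),
    genetic_share = vapply(res, `[[`, 0, "genetic_share"))
  .uni_cache$res
}

# Memoised study-scale common-pathway recovery replicates, shared by the
# latent-heritability and communality acceptance checks.
.cpm_cache <- new.env(parent = emptyenv())
cpm_recovery <- function(n_rep = 20, seed = SUITE_SEED) {
  key <- paste0("r", n_rep, "_", seed)
  if (!is.null(.cpm_cache[[key]])) return(.cpm_cache[[key]])
  seeds <- twinstab:::derive_seeds(seed, n_rep)
  res <- t(vapply(seeds, function(s) {
    sim <- simulate_twins(default_sim_config("common_pathway", seed = s))
    fit <- fit_common_pathway(sim$data, n_starts = 2, seed = s, se = FALSE)
    est <- standardize(fit)
    c(latent_a2 = est$estimate[est$quantity == "latent_a2"],
      communality_w2 = est$estimate[est$quantity == "communality_w2"])
  }, c(latent_a2 = 0, communality_w2 = 0)))
  .cpm_cache[[key]] <- res
  res
}
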