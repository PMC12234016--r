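## Synthetic twin-data generator. Latent biometric components are drawn as
## factor scores with the kinship correlation (A: 1/0.5, C: 1/1, D: 1/0.25,
## E: 0 across MZ/DZ co-twins) and mapped through the same per-component
## loading matrices the likelihood uses, so the empirical covariance of the
## generated data converges to the model-implied covariance by construction.

#' Simulation configuration
#'
#' @param n_mz,n_dz numbers of MZ and DZ pairs (>= 1).
#' @param n_waves number of repeated measures.
#' @param structure one of "univariate", "cholesky", "common_pathway",
#'   "correlated_factors", "item_factors".
#' @param params structure-specific truth values (see [simulate_twins()] and
#'   [simulate_items()]).
#' @param missing_rate probability in [0,1) that a twin-by-wave score cell is
#'   missing completely at random.
#' @param likert optional increasing numeric thresholds; scores are replaced
#'   by the count of thresholds below them (discrete 0..length(likert) scale).
#' @param seed integer RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_mz, n_dz, n_waves = 1, structure = "univariate",
                       params = list(), missing_rate = 0, likert = NULL,
                       seed = 1) {
  stopifnot(n_mz >= 1, n_dz >= 1, n_waves >= 1)
  structure <- match.arg(structure, c("univariate", "cholesky",
                                      "common_pathway", "correlated_factors",
                                      "item_factors"))
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  structure(list(n_mz = n_mz, n_dz = n_dz, n_waves = n_waves,
                 structure = structure, params = params,
                 missing_rate = missing_rate, likert = likert, seed = seed),
            class = "sim_config")
}

## Normalize user-facing truth parameters into component loading matrices.
sim_loadings <- function(config) {
  p <- config$params
  W <- config$n_waves
  if (config$structure == "univariate") {
    comps <- toupper(intersect(c("a", "c", "d", "e"), names(p)))
    comps <- check_components(comps)
    lp <- stats::setNames(lapply(tolower(comps), function(cc)
      matrix(p[[cc]], 1, 1)), comps)
    mean <- p$mean %||% 0
  } else if (config$structure == "cholesky") {
    comps <- toupper(intersect(c("a", "c", "d", "e"), names(p)))
    comps <- check_components(comps)
    lp <- stats::setNames(lapply(tolower(comps), function(cc) {
      X <- as.matrix(p[[cc]])
      if (!all(dim(X) == c(W, W))) stop("path matrix '", cc, "' must be ",
                                        W, "x", W)
      X
    }), comps)
    mean <- p$mean %||% rep(0, W)
  } else if (config$structure == "common_pathway") {
    comps <- check_components(toupper(names(p$latent)))
    if (abs(sum(p$latent^2) - 1) > 1e-6)
      stop("latent component paths must have squares summing to 1")
    if (length(p$lambda) != W) stop("lambda must have length n_waves")
    lp <- list()
    for (i in seq_along(comps)) {
      cc <- tolower(comps[i])
      sp <- p$specific[[cc]] %||% rep(0, W)
      lp[[comps[i]]] <- cbind(p$latent[[i]] * p$lambda, diag(sp, W))
    }
    mean <- p$mean %||% rep(0, W)
  } else if (config$structure == "correlated_factors") {
    comps <- check_components(toupper(sub("^sd_", "",
      grep("^sd_", names(p), value = TRUE))))
    lp <- list()
    for (cc in tolower(comps)) {
      s <- p[[paste0("sd_", cc)]]
      R <- as.matrix(p[[paste0("R_", cc)]])
      ch <- tryCatch(chol(R + diag(1e-12, nrow(R))), error = function(e) NULL)
      if (is.null(ch))
        stop("correlation matrix R_", cc, " is not positive semi-definite")
      lp[[toupper(cc)]] <- diag(s, length(s)) %*% t(ch)
    }
    mean <- p$mean %||% rep(0, nrow(lp[[1]]))
  } else stop("use simulate_items() for structure 'item_factors'")
  list(components = names(lp), loadings = lp, mean = mean)
}

## Factor scores for one component in one zygosity group: co-twins share
## sqrt(k) of a common draw, the rest is twin-unique, giving cross-twin
## correlation exactly k per factor.
draw_component <- function(n, X, kin) {
  q <- ncol(X)
  g <- matrix(stats::rnorm(n * q), n, q)
  u1 <- matrix(stats::rnorm(n * q), n, q)
  u2 <- matrix(stats::rnorm(n * q), n, q)
  f1 <- sqrt(kin) * g + sqrt(1 - kin) * u1
  f2 <- sqrt(kin) * g + sqrt(1 - kin) * u2
  list(t1 = f1 %*% t(X), t2 = f2 %*% t(X))
}

#' Simulate a twin dataset with known biometric structure
#'
#' Supported truths (`config$params`):
#' \describe{
#' \item{univariate}{`a`, `c`/`d`, `e` paths (scalars), `mean`.}
#' \item{cholesky}{lower-triangular W x W path matrices `a`, `c`/`d`, `e`,
#'   `mean` vector.}
#' \item{common_pathway}{`lambda` (W loadings), `latent` named path vector
#'   (e.g. `c(a = sqrt(0.6), e = sqrt(0.4))`, squares summing to 1),
#'   `specific` list of per-wave residual paths, `mean`.}
#' \item{correlated_factors}{`sd_a`, `sd_e`, ... standard-deviation vectors
#'   plus correlation matrices `R_a`, `R_e`, `mean`.}
#' }
#' Optional `params$skew_shift`: phenotypes are returned as
#' `(y + shift)^2`, a right-skewed score that the square-root transform maps
#' back to approximate normality. `config$likert` discretizes scores.
#'
#' @param config a [sim_config()].
#' @return list with `data` (a `twin_dataset`) and `truth` (generating
#'   parameters, per-wave standardized shares, implied covariance matrices).
#' @export
simulate_twins <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sl <- sim_loadings(config)
  W <- nrow(sl$loadings[[1]])
  n <- c(MZ = config$n_mz, DZ = config$n_dz)
  rows <- list()
  for (z in c("MZ", "DZ")) {
    y1 <- matrix(rep(sl$mean, each = n[[z]]), n[[z]], W)
    y2 <- y1
    for (comp in sl$components) {
      d <- draw_component(n[[z]], sl$loadings[[comp]], KINSHIP[[comp]][[z]])
      y1 <- y1 + d$t1
      y2 <- y2 + d$t2
    }
    if (!is.null(config$params$skew_shift)) {
      sh <- config$params$skew_shift
      y1 <- (y1 + sh)^2
      y2 <- (y2 + sh)^2
    }
    if (!is.null(config$likert)) {
      y1[] <- findInterval(y1, config$likert)
      y2[] <- findInterval(y2, config$likert)
    }
    df <- data.frame(zygosity = z, y1, y2)
    names(df) <- c("zygosity", sprintf("score_w%d_t1", 1:W),
                   sprintf("score_w%d_t2", 1:W))
    rows[[z]] <- df
  }
  out <- rbind(rows$MZ, rows$DZ)
  out <- cbind(pair_id = sprintf("P%05d", seq_len(nrow(out))), out)
  data <- twin_dataset(out)
  if (config$missing_rate > 0)
    data <- apply_missingness(data, config$missing_rate,
                              seed = derive_seeds(config$seed, 1))
  list(data = data, truth = sim_truth(config, sl))
}

## Ground-truth bookkeeping: standardized shares and implied covariances.
sim_truth <- function(config, sl) {
  comps <- implied_comps(sl$loadings)
  shares <- shares_from_comps(comps)
  tot <- Reduce(`+`, lapply(comps, diag))
  truth <- list(structure = config$structure, components = sl$components,
                params = config$params, shares = shares,
                total_variance = tot,
                sigma_mz = twin_pair_cov(comps, "MZ"),
                sigma_dz = twin_pair_cov(comps, "DZ"),
                mu = rep(sl$mean, 2))
  if (config$structure == "common_pathway") {
    truth$latent_shares <- stats::setNames(config$params$latent^2,
                                           paste0("latent_",
                                                  tolower(names(config$params$latent)), "2"))
    truth$communalities <- config$params$lambda^2 / tot
  }
  if (config$structure == "correlated_factors") {
    for (cc in tolower(sl$components))
      truth[[paste0("R_", cc)]] <- config$params[[paste0("R_", cc)]]
  }
  truth
}

#' Apply missing-completely-at-random wave-level missingness
#'
#' Each twin-by-wave score cell is set missing independently with the given
#' probability; a pair is retained as long as at least one twin has at least
#' one observed wave.
#'
#' @param data a `twin_dataset`.
#' @param rate missingness probability in [0, 1).
#' @param seed RNG seed (same seed, same mask).
#' @return the masked `twin_dataset`.
#' @export
apply_missingness <- function(data, rate, seed = 1) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(data)
  set.seed(seed)
  cols <- grep("^score_w[0-9]+_t[12]$", names(data), value = TRUE)
  m <- as.matrix(data[, cols, drop = FALSE])
  mask <- matrix(stats::runif(length(m)) < rate, nrow(m), ncol(m))
  m[mask] <- NA
  data[, cols] <- m
  keep <- rowSums(!is.na(m)) > 0
  if (any(!keep))
    message(sum(!keep), " pair(s) with no observed wave dropped")
  twin_dataset(as.data.frame(data)[keep, , drop = FALSE])
}

#' Simulate item-level Likert responses from a two-level factor model
#'
#' Continuous item responses follow `x = Lambda f + sqrt(psi) eps` with
#' correlated factors, then are discretized to 0..4 by thresholds. Per-wave
#' sum scores (`score_w*` columns) are added. Factors are drawn
#' independently per individual and per wave unless `params$factor_a2 > 0`,
#' in which case that share of each factor's variance is additive-genetic
#' (kinship-correlated across co-twins).
#'
#' `config$params`: `loadings` (K x m matrix), `phi` (m x m factor
#' correlation), `thresholds` (increasing, default `c(0.25, 1, 1.75, 2.5)`,
#' a right-skewed response distribution), optional `factor_a2`.
#'
#' @param config a [sim_config()] with `structure = "item_factors"`.
#' @return list with `data` (a `twin_dataset` carrying item and sum-score
#'   columns) and `truth` (loadings, phi, implied item correlations).
#' @export
simulate_items <- function(config) {
  stopifnot(inherits(config, "sim_config"),
            config$structure == "item_factors")
  set.seed(config$seed)
  p <- config$params
  L <- as.matrix(p$loadings)
  K <- nrow(L); m <- ncol(L)
  Phi <- p$phi %||% diag(m)
  thr <- p$thresholds %||% c(0.25, 1, 1.75, 2.5)
  a2 <- p$factor_a2 %||% 0
  comm <- diag(L %*% Phi %*% t(L))
  if (any(comm > 1))
    stop("communality > 1 for item(s): ",
         paste(which(comm > 1), collapse = ", "))
  psi <- 1 - comm
  ch <- t(chol(Phi))
  n <- c(MZ = config$n_mz, DZ = config$n_dz)
  W <- config$n_waves
  implied_R <- L %*% Phi %*% t(L) + diag(psi, K)
  rows <- list()
  for (z in c("MZ", "DZ")) {
    kin <- KINSHIP$A[[z]]
    df <- data.frame(zygosity = rep(z, n[[z]]))
    for (w in seq_len(W)) {
      g <- matrix(stats::rnorm(n[[z]] * m), n[[z]], m) %*% t(ch)
      xs <- list()
      for (t in 1:2) {
        ## factor = sqrt(a2)*(genetic, sharing sqrt(kin) with the co-twin)
        ##        + sqrt(1-a2)*(individual-unique)
        u <- matrix(stats::rnorm(n[[z]] * m), n[[z]], m) %*% t(ch)
        ug <- matrix(stats::rnorm(n[[z]] * m), n[[z]], m) %*% t(ch)
        f <- sqrt(a2) * (sqrt(kin) * g + sqrt(1 - kin) * ug) +
          sqrt(1 - a2) * u
        eps <- matrix(stats::rnorm(n[[z]] * K), n[[z]], K)
        xc <- f %*% t(L) + eps %*% diag(sqrt(psi), K)
        xd <- matrix(findInterval(xc, thr), n[[z]], K)
        colnames(xd) <- sprintf("item_w%d_i%d_t%d", w, 1:K, t)
        xs[[t]] <- xd
        df[sprintf("score_w%d_t%d", w, t)] <- rowSums(xd)
      }
      df <- cbind(df, xs[[1]], xs[[2]])
    }
    rows[[z]] <- df
  }
  out <- rbind(rows$MZ, rows$DZ)
  out <- cbind(pair_id = sprintf("P%05d", seq_len(nrow(out))), out)
  const <- vapply(grep("^item_", names(out), value = TRUE), function(cc)
    stats::var(out[[cc]]) == 0, TRUE)
  if (any(const))
    warning("degenerate constant item column(s): ",
            paste(names(const)[const], collapse = ", "))
  list(data = twin_dataset(out),
       truth = list(loadings = L, phi = Phi, psi = psi,
                    thresholds = thr, implied_correlations = implied_R))
}
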