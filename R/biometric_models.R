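## Model builders for the four biometric families: univariate variance
## decomposition, multivariate Cholesky, common pathway (latent stability)
## and correlated factors. All free parameters are paths, squared inside the
## builders, so every component covariance matrix is positive semi-definite
## by construction; squared (standardized) quantities are what gets reported.

## Per-component factor-loading matrices for each structure. The simulator
## and the likelihood share these, so the model-implied covariance and the
## generating process agree by construction: component covariance = X X'.
component_loadings <- function(structure, params, components) {
  out <- list()
  if (structure == "univariate") {
    for (comp in components)
      out[[comp]] <- matrix(params[[tolower(comp)]], 1, 1)
  } else if (structure == "cholesky") {
    for (comp in components)
      out[[comp]] <- as.matrix(params[[tolower(comp)]])
  } else if (structure == "common_pathway") {
    lam <- params$lambda
    W <- length(lam)
    for (i in seq_along(components)) {
      comp <- components[i]
      lat <- params$latent_paths[i]
      spec_p <- params$specific[[tolower(comp)]]
      out[[comp]] <- cbind(lat * lam, diag(spec_p, W))
    }
  } else if (structure == "correlated_factors") {
    for (comp in components) {
      s <- params[[paste0("sd_", tolower(comp))]]
      R <- params[[paste0("R_", tolower(comp))]]
      out[[comp]] <- diag(s, length(s)) %*% t(chol(R))
    }
  } else stop("unknown structure: ", structure)
  out
}

implied_comps <- function(loadings) lapply(loadings, tcrossprod)

## Pooled (both groups) phenotype means and within-twin covariance from
## FIML sufficient statistics; used for data-driven starting values.
pooled_moments <- function(st) {
  p <- st[[1]]$p
  q <- p / 2
  s_sum <- rep(0, p); cnt <- rep(0, p)
  for (g in names(st)) for (pt in st[[g]]$patterns) {
    s_sum[pt$cols] <- s_sum[pt$cols] + pt$sx
    cnt[pt$cols] <- cnt[pt$cols] + pt$n
  }
  mu <- ifelse(cnt > 0, s_sum / pmax(cnt, 1), 0)
  S <- matrix(0, p, p)
  for (g in names(st)) S <- S + sat_start_cov(st[[g]], mu)
  S <- S / length(st)
  within <- (S[1:q, 1:q, drop = FALSE] +
               S[(q + 1):p, (q + 1):p, drop = FALSE]) / 2
  list(mu = (mu[1:q] + mu[(q + 1):p]) / 2, within = within)
}

comp_start_fracs <- function(components) {
  switch(paste(sort(components), collapse = ""),
         "AE" = c(A = 0.4, E = 0.6),
         "ACE" = c(A = 0.35, C = 0.2, E = 0.45),
         "ADE" = c(A = 0.3, D = 0.15, E = 0.55),
         "CE" = c(C = 0.4, E = 0.6),
         "E" = c(E = 1))[components]
}

#' Univariate variance-components model
#'
#' One phenotype per twin; free parameters are the component paths and the
#' (twin- and zygosity-constrained) mean. Reported quantities are the
#' standardized shares a2/c2/d2/e2.
#'
#' @param family one of "ACE", "ADE", "AE", "CE", "E".
#' @param start_var,start_mean data-driven starting values (total phenotypic
#'   variance and mean).
#' @return a `model_spec`.
#' @export
build_univariate <- function(family = c("ACE", "ADE", "AE", "CE", "E"),
                             start_var = 1, start_mean = 0) {
  family <- match.arg(family)
  comps <- check_components(FAMILY_COMPONENTS[[family]])
  fr <- comp_start_fracs(comps)
  par_names <- c(tolower(comps), "mean")
  start <- c(sqrt(fr * start_var), start_mean)
  builder <- function(theta) {
    th <- as.list(stats::setNames(theta[seq_along(comps)], tolower(comps)))
    th$mean <- theta[length(theta)]
    ec <- expected_cov(family, th, W = 1, V = 1)
    list(MZ = list(mu = ec$mu, sigma = ec$sigma_mz),
         DZ = list(mu = ec$mu, sigma = ec$sigma_dz))
  }
  summarize <- function(theta) {
    v <- theta[seq_along(comps)]^2
    stats::setNames(v / sum(v), paste0(tolower(comps), "2"))
  }
  model_spec(paste0(family, " (univariate)"), par_names, start, builder,
             summarize,
             meta = list(structure = "univariate", family = family,
                         components = comps, W = 1))
}

#' Multivariate Cholesky decomposition
#'
#' Each component's covariance across the W waves is parameterized as
#' \eqn{X X'} with `X` lower triangular: factor k loads on waves k..W, so its
#' off-diagonal paths quantify continuity and the diagonal quantifies
#' innovation. Reported quantities are the per-factor standardized variance
#' shares at each wave (e.g. `a1_w3` = share of wave-3 variance due to the
#' first genetic factor).
#'
#' @param W number of waves (>= 2).
#' @param components subset of A, C, D, E containing E (C and D exclusive).
#' @param start_cov,start_mean data-driven starts: within-twin covariance
#'   (W x W) and mean vector.
#' @return a `model_spec`.
#' @export
build_cholesky <- function(W, components = c("A", "E"),
                           start_cov = diag(W), start_mean = rep(0, W)) {
  if (W < 2) stop("Cholesky decomposition needs W >= 2 waves")
  comps <- check_components(components)
  fr <- comp_start_fracs(comps)
  nlt <- W * (W + 1) / 2
  li <- lt_index(W)
  rc <- arrayInd(li, c(W, W))
  par_names <- c(unlist(lapply(tolower(comps), function(cc)
    sprintf("%s_%d%d", cc, rc[, 1], rc[, 2]))), sprintf("mean_w%d", 1:W))
  start <- c(unlist(lapply(comps, function(cc)
    lt_mat2vec(t(chol(fr[[cc]] * start_cov + diag(1e-6, W)))))), start_mean)
  nc <- length(comps)
  params_of <- function(theta) {
    pl <- list()
    for (i in seq_len(nc))
      pl[[tolower(comps[i])]] <- lt_vec2mat(theta[(i - 1) * nlt + seq_len(nlt)], W)
    pl
  }
  builder <- function(theta) {
    mu1 <- theta[nc * nlt + seq_len(W)]
    cl <- implied_comps(component_loadings("cholesky", params_of(theta), comps))
    list(MZ = list(mu = rep(mu1, 2), sigma = twin_pair_cov(cl, "MZ")),
         DZ = list(mu = rep(mu1, 2), sigma = twin_pair_cov(cl, "DZ")))
  }
  summarize <- function(theta) {
    pl <- params_of(theta)
    cl <- implied_comps(component_loadings("cholesky", pl, comps))
    tot <- Reduce(`+`, lapply(cl, diag))
    out <- c()
    for (cc in comps) {
      X <- pl[[tolower(cc)]]
      for (w in 1:W) for (k in 1:w)
        out[sprintf("%s%d_w%d", tolower(cc), k, w)] <- X[w, k]^2 / tot[w]
      for (w in 1:W)
        out[sprintf("%s_total_w%d", tolower(cc), w)] <- cl[[cc]][w, w] / tot[w]
    }
    out
  }
  model_spec(paste0(paste(comps, collapse = ""), " Cholesky"), par_names,
             start, builder, summarize,
             meta = list(structure = "cholesky", components = comps, W = W))
}

## Latent-component paths with unit total variance via spherical angles in
## (0, pi/2): all paths positive, squares sum to 1.
latent_paths_from_angles <- function(ang) {
  n <- length(ang) + 1
  p <- numeric(n)
  s <- 1
  for (j in seq_along(ang)) {
    p[j] <- s * cos(ang[j])
    s <- s * sin(ang[j])
  }
  p[n] <- s
  p
}

#' Common pathway (latent stability) model
#'
#' All waves load on one latent factor whose variance is fixed to 1 and
#' decomposed into the biometric components (shares summing to 1); each wave
#' additionally has component-specific residual paths. Reported quantities:
#' the latent splits (`latent_a2`, ...), per-wave communalities
#' (`communality_w`), and standardized specific shares.
#'
#' @param W number of waves (>= 3 for identification).
#' @param components subset of A, C, D, E containing E.
#' @param start_cov,start_mean data-driven starts.
#' @return a `model_spec`.
#' @export
build_common_pathway <- function(W, components = c("A", "E"),
                                 start_cov = diag(W), start_mean = rep(0, W)) {
  if (W < 3) stop("common pathway model needs W >= 3 waves for identification")
  comps <- check_components(components)
  nc <- length(comps)
  ## factor-analytic starting values for the loadings
  off <- start_cov; diag(off) <- NA
  lam0 <- sqrt(pmax(rowMeans(abs(off), na.rm = TRUE), 0.05))
  res0 <- pmax(diag(start_cov) - lam0^2, 0.05)
  fr <- comp_start_fracs(comps)
  ang0 <- rep(pi / 4, nc - 1)
  par_names <- c(sprintf("lambda_w%d", 1:W),
                 if (nc > 1) sprintf("latent_angle%d", seq_len(nc - 1)),
                 unlist(lapply(tolower(comps), function(cc)
                   sprintf("%s_s_w%d", cc, 1:W))),
                 sprintf("mean_w%d", 1:W))
  start <- c(lam0, ang0, unlist(lapply(comps, function(cc) sqrt(fr[[cc]] * res0))),
             start_mean)
  k <- length(par_names)
  lower <- rep(-Inf, k); upper <- rep(Inf, k)
  if (nc > 1) {
    ai <- W + seq_len(nc - 1)
    lower[ai] <- 1e-4; upper[ai] <- pi / 2 - 1e-4
  }
  params_of <- function(theta) {
    lam <- theta[1:W]
    ang <- if (nc > 1) theta[W + seq_len(nc - 1)] else numeric(0)
    lat <- latent_paths_from_angles(ang)
    sp <- list()
    for (i in seq_len(nc))
      sp[[tolower(comps[i])]] <-
        theta[W + (nc - 1) + (i - 1) * W + seq_len(W)]
    list(lambda = lam, latent_paths = lat, specific = sp)
  }
  builder <- function(theta) {
    mu1 <- theta[(k - W + 1):k]
    cl <- implied_comps(component_loadings("common_pathway", params_of(theta), comps))
    list(MZ = list(mu = rep(mu1, 2), sigma = twin_pair_cov(cl, "MZ")),
         DZ = list(mu = rep(mu1, 2), sigma = twin_pair_cov(cl, "DZ")))
  }
  summarize <- function(theta) {
    pl <- params_of(theta)
    cl <- implied_comps(component_loadings("common_pathway", pl, comps))
    tot <- Reduce(`+`, lapply(cl, diag))
    out <- stats::setNames(pl$latent_paths^2, paste0("latent_", tolower(comps), "2"))
    for (w in 1:W) out[sprintf("communality_w%d", w)] <- pl$lambda[w]^2 / tot[w]
    for (i in seq_len(nc)) for (w in 1:W)
      out[sprintf("specific_%s2_w%d", tolower(comps[i]), w)] <-
        pl$specific[[tolower(comps[i])]][w]^2 / tot[w]
    out
  }
  model_spec(paste0(paste(comps, collapse = ""), " common pathway"),
             par_names, start, builder, summarize, lower = lower, upper = upper,
             meta = list(structure = "common_pathway", components = comps, W = W))
}

#' Correlated-factor model
#'
#' Each of V variables has its own component standard-deviation paths; the
#' etiological overlap between variables is carried by component correlation
#' matrices (genetic correlations rG in R_A, environmental rE in R_E),
#' parameterized through spherical angles so each matrix has unit diagonal
#' and is positive semi-definite throughout optimization. Reported
#' quantities: standardized per-variable shares and the rG/rE entries.
#'
#' @param V number of variables (>= 2).
#' @param components subset of A, C, D, E containing E.
#' @param start_cov,start_mean data-driven starts (V x V within-twin
#'   covariance and mean vector).
#' @return a `model_spec`.
#' @export
build_correlated_factors <- function(V, components = c("A", "E"),
                                     start_cov = diag(V),
                                     start_mean = rep(0, V)) {
  if (V < 2) stop("correlated-factor model needs V >= 2 variables")
  comps <- check_components(components)
  nc <- length(comps)
  nang <- V * (V - 1) / 2
  fr <- comp_start_fracs(comps)
  R0 <- stats::cov2cor(start_cov + diag(1e-6, V))
  ang0 <- angles_from_corr(0.5 * R0 + 0.5 * diag(V))
  rc <- which(lower.tri(matrix(0, V, V)), arr.ind = TRUE)
  par_names <- c(
    unlist(lapply(tolower(comps), function(cc) c(
      sprintf("sd_%s_v%d", cc, 1:V),
      sprintf("angle_%s_%d%d", cc, rc[, 1], rc[, 2])))),
    sprintf("mean_v%d", 1:V))
  start <- c(unlist(lapply(comps, function(cc)
    c(sqrt(fr[[cc]] * diag(start_cov)), ang0))), start_mean)
  k <- length(par_names)
  lower <- rep(-Inf, k); upper <- rep(Inf, k)
  ang_pos <- grep("^angle_", par_names)
  lower[ang_pos] <- 1e-3; upper[ang_pos] <- pi - 1e-3
  params_of <- function(theta) {
    pl <- list()
    for (i in seq_len(nc)) {
      o <- (i - 1) * (V + nang)
      cc <- tolower(comps[i])
      pl[[paste0("sd_", cc)]] <- theta[o + seq_len(V)]
      pl[[paste0("R_", cc)]] <- corr_from_angles(theta[o + V + seq_len(nang)], V)
    }
    pl
  }
  builder <- function(theta) {
    mu1 <- theta[(k - V + 1):k]
    cl <- implied_comps(component_loadings("correlated_factors",
                                           params_of(theta), comps))
    list(MZ = list(mu = rep(mu1, 2), sigma = twin_pair_cov(cl, "MZ")),
         DZ = list(mu = rep(mu1, 2), sigma = twin_pair_cov(cl, "DZ")))
  }
  summarize <- function(theta) {
    pl <- params_of(theta)
    cl <- implied_comps(component_loadings("correlated_factors", pl, comps))
    tot <- Reduce(`+`, lapply(cl, diag))
    out <- c()
    for (cc in comps) {
      sd2 <- pl[[paste0("sd_", tolower(cc))]]^2
      for (v in 1:V)
        out[sprintf("%s2_v%d", tolower(cc), v)] <- sd2[v] / tot[v]
      R <- pl[[paste0("R_", tolower(cc))]]
      lab <- if (cc == "A") "rG" else if (cc == "E") "rE" else paste0("r", cc)
      for (idx in seq_len(nrow(rc)))
        out[sprintf("%s_%d%d", lab, rc[idx, 1], rc[idx, 2])] <-
          R[rc[idx, 1], rc[idx, 2]]
    }
    out
  }
  model_spec(paste0(paste(comps, collapse = ""), " correlated factors"),
             par_names, start, builder, summarize, lower = lower, upper = upper,
             meta = list(structure = "correlated_factors", components = comps,
                         V = V))
}
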