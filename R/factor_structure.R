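## Item-level factor structure: exploration/confirmation split, exploratory
## factor analysis (minimum-residual extraction, oblique promax rotation,
## parallel analysis for the factor count), the item-assignment rule, and
## confirmatory factor analysis fitted by the package's FIML engine.

#' Split individuals into exploration and confirmation subsets
#'
#' Disjoint, exhaustive random split (by row), reproducible under the seed.
#' Intended for data with one randomly selected twin per pair, so rows are
#' independent.
#'
#' @param x data.frame or matrix of individuals.
#' @param fraction exploration fraction in (0, 1).
#' @param seed RNG seed.
#' @return list with `explore` and `confirm` subsets and the index vectors.
#' @export
split_sample <- function(x, fraction = 0.7, seed = 1) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n <- nrow(x)
  set.seed(seed)
  idx <- sample.int(n, round(fraction * n))
  list(explore = x[idx, , drop = FALSE],
       confirm = x[-idx, , drop = FALSE],
       explore_idx = sort(idx), confirm_idx = setdiff(seq_len(n), sort(idx)))
}

#' Item-score matrix for one wave, one individual per pair
#'
#' @param data a `twin_dataset` with item columns.
#' @param wave wave to extract.
#' @param one_per_pair randomly keep one co-twin per pair (default TRUE).
#' @param seed RNG seed for the co-twin selection.
#' @return numeric matrix individuals x items.
#' @export
item_scores <- function(data, wave = 1, one_per_pair = TRUE, seed = 1) {
  K <- attr(data, "n_items")
  if (K < 1) stop("dataset has no item columns")
  m <- lapply(1:2, function(t)
    as.matrix(data[, sprintf("item_w%d_i%d_t%d", wave, 1:K, t), drop = FALSE]))
  if (one_per_pair) {
    set.seed(seed)
    pick <- stats::runif(nrow(data)) < 0.5
    out <- m[[1]]
    out[pick, ] <- m[[2]][pick, ]
  } else out <- rbind(m[[1]], m[[2]])
  colnames(out) <- sprintf("item%d", 1:K)
  out
}

## Pairwise-complete Pearson correlations and the median pairwise n.
pairwise_corr <- function(items) {
  R <- suppressWarnings(stats::cor(items, use = "pairwise.complete.obs"))
  if (anyNA(R)) stop("undefined item correlations (constant or empty items)")
  nobs <- crossprod(!is.na(items))
  list(R = R, n = stats::median(nobs[lower.tri(nobs)]))
}

#' Parallel analysis for the number of factors
#'
#' Compares the eigenvalues of the observed correlation matrix with the mean
#' eigenvalues of correlation matrices of independent normal data of the
#' same dimensions; the retained count is the number of observed eigenvalues
#' exceeding their simulated counterpart.
#'
#' @param R observed correlation matrix.
#' @param n number of observations behind R.
#' @param n_sim simulated datasets.
#' @param seed RNG seed.
#' @return list with `n_factors`, `eigen_obs`, `eigen_sim`.
#' @export
parallel_analysis <- function(R, n, n_sim = 20, seed = 1) {
  p <- ncol(R)
  ev_obs <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  set.seed(seed)
  sims <- replicate(n_sim, {
    X <- matrix(stats::rnorm(n * p), n, p)
    eigen(stats::cor(X), symmetric = TRUE, only.values = TRUE)$values
  })
  ev_sim <- rowMeans(sims)
  list(n_factors = sum(ev_obs > ev_sim), eigen_obs = ev_obs, eigen_sim = ev_sim)
}

## Minimum-residual (unweighted least squares) extraction: optimize the
## uniquenesses, with loadings given by the leading eigenvectors of the
## reduced correlation matrix.
minres_fa <- function(R, m) {
  p <- ncol(R)
  smc <- 1 - 1 / diag(solve(R + diag(1e-8, p)))
  loadings_of <- function(psi) {
    Rr <- R
    diag(Rr) <- 1 - psi
    e <- eigen(Rr, symmetric = TRUE)
    L <- e$vectors[, seq_len(m), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(m)], 0)), m)
    L
  }
  obj <- function(psi) {
    L <- loadings_of(psi)
    Rr <- R
    diag(Rr) <- 1 - psi
    res <- Rr - tcrossprod(L)
    sum(res^2)
  }
  opt <- stats::optim(pmin(pmax(1 - smc, 0.05), 0.95), obj,
                      method = "L-BFGS-B", lower = 0.001, upper = 0.999,
                      control = list(maxit = 500))
  L <- loadings_of(opt$par)
  res <- R - tcrossprod(L)
  diag(res) <- 0
  list(loadings = L, uniquenesses = opt$par,
       rmsr = sqrt(mean(res[lower.tri(res)]^2)),
       converged = opt$convergence == 0)
}

#' Exploratory factor analysis of item scores
#'
#' Pearson correlations on pairwise-complete observations;
#' minimum-residual extraction; the factor count is chosen by parallel
#' analysis (clipped to `range`) and corroborated by the residual fit of
#' every candidate count, which is returned alongside. With more than one
#' factor, loadings are obliquely rotated (promax by default); a rotation
#' failure falls back to the unrotated solution with a flag. Items are then
#' assigned to the factor on which they load above the cutoff and strictly
#' higher than on any other factor; unassigned items (including exact ties)
#' are flagged.
#'
#' @param items individuals x items matrix.
#' @param range candidate factor counts.
#' @param cutoff assignment loading threshold (default 0.3).
#' @param rotate "promax" or "none".
#' @param n_sim,seed parallel-analysis settings.
#' @return object of class `efa_fit`: loadings, factor correlation `phi`,
#'   `n_factors`, `assignment` (NA = unassigned), parallel-analysis and
#'   per-count fit tables.
#' @export
efa <- function(items, range = 1:3, cutoff = 0.3, rotate = "promax",
                n_sim = 20, seed = 1) {
  pc <- pairwise_corr(items)
  pa <- parallel_analysis(pc$R, pc$n, n_sim = n_sim, seed = seed)
  fits <- lapply(range, function(m) minres_fa(pc$R, m))
  fit_tab <- data.frame(n_factors = range,
                        rmsr = vapply(fits, `[[`, 0, "rmsr"),
                        converged = vapply(fits, `[[`, 0, "converged"))
  m <- min(max(pa$n_factors, min(range)), max(range))
  fm <- fits[[match(m, range)]]
  L <- fm$loadings
  phi <- diag(m)
  rotated <- FALSE
  rotation_failed <- FALSE
  if (m > 1 && rotate == "promax") {
    pr <- tryCatch(stats::promax(L), error = function(e) NULL)
    if (is.null(pr)) {
      rotation_failed <- TRUE
    } else {
      L <- unclass(pr$loadings)
      phi <- stats::cov2cor(solve(crossprod(pr$rotmat)))
      rotated <- TRUE
    }
  }
  flip <- sign(colSums(L))
  flip[flip == 0] <- 1
  L <- sweep(L, 2, flip, `*`)
  phi <- diag(flip, m) %*% phi %*% diag(flip, m)
  rownames(L) <- colnames(items) %||% sprintf("item%d", seq_len(nrow(L)))
  colnames(L) <- colnames(phi) <- rownames(phi) <- sprintf("F%d", 1:m)
  structure(list(loadings = L, phi = phi, n_factors = m,
                 assignment = assign_items(L, cutoff),
                 uniquenesses = fm$uniquenesses, rmsr = fm$rmsr,
                 parallel = pa, fit_by_count = fit_tab,
                 rotated = rotated, rotation_failed = rotation_failed),
            class = "efa_fit")
}

#' Item-to-factor assignment rule
#'
#' An item is assigned to a factor when its loading there exceeds the cutoff
#' and is strictly greater than its loading on every other factor; exact
#' ties and sub-threshold items stay unassigned (NA).
#'
#' @param loadings items x factors matrix.
#' @param cutoff loading threshold.
#' @return integer vector of factor indices with NA for unassigned.
#' @export
assign_items <- function(loadings, cutoff = 0.3) {
  apply(loadings, 1, function(l) {
    b <- which.max(l)
    if (l[b] > cutoff && all(l[-b] < l[b])) b else NA_integer_
  })
}

#' @export
print.efa_fit <- function(x, digits = 2, ...) {
  cat(sprintf("EFA: %d factor(s) retained (parallel analysis: %d)%s\n",
              x$n_factors, x$parallel$n_factors,
              if (x$rotation_failed) " [rotation failed, unrotated]" else ""))
  print(round(x$loadings, digits))
  if (x$n_factors > 1) {
    cat("factor correlations:\n")
    print(round(x$phi, digits))
  }
  cat("assignment:", paste(ifelse(is.na(x$assignment), "-", x$assignment),
                           collapse = " "), "\n")
  invisible(x)
}

## Exact FIML -2LL of the independence (diagonal) baseline: columns are
## independent, so the likelihood factorizes over observed cells.
independence_m2ll <- function(Y) {
  m2ll <- 0; k <- 0
  for (j in seq_len(ncol(Y))) {
    x <- Y[!is.na(Y[, j]), j]
    n <- length(x)
    s2 <- mean((x - mean(x))^2)
    m2ll <- m2ll + n * (LOG2PI + log(s2) + 1)
    k <- k + 2
  }
  list(minus2LL = m2ll, k = k)
}

#' Confirmatory factor analysis via the FIML engine
#'
#' Single-group factor model with factor variances fixed to 1, free oblique
#' factor correlations, and free means; only items assigned in `pattern` are
#' modeled. Fit indices are computed against the saturated model (closed
#' form on complete data, optimized otherwise) and the independence
#' baseline.
#'
#' @param items individuals x items matrix (missing allowed).
#' @param pattern integer vector (length = ncol(items)) of factor indices,
#'   NA for items excluded from the model.
#' @param ... passed to [fit_model()].
#' @return object of class `cfa_fit` with `fit` (a `twin_fit`), `loadings`,
#'   `phi`, and `indices` (chisq, df, CFI, TLI, RMSEA, SRMR, AIC).
#' @export
cfa <- function(items, pattern, ...) {
  stopifnot(length(pattern) == ncol(items))
  keep <- which(!is.na(pattern))
  pat <- pattern[keep]
  m <- max(pat)
  if (m > 1 && any(tabulate(pat, m) < 2))
    stop("empirically underidentified pattern: a factor has < 2 items")
  Y <- as.matrix(items[, keep, drop = FALSE])
  Y <- Y[rowSums(!is.na(Y)) > 0, , drop = FALSE]
  p <- ncol(Y)
  nang <- m * (m - 1) / 2
  mu0 <- colMeans(Y, na.rm = TRUE)
  sd0 <- apply(Y, 2, stats::sd, na.rm = TRUE)
  par_names <- c(sprintf("lambda%d", 1:p), sprintf("u%d", 1:p),
                 if (nang > 0) sprintf("phi_angle%d", seq_len(nang)),
                 sprintf("mean%d", 1:p))
  start <- c(0.7 * sd0, 0.6 * sd0, rep(pi / 3, nang), mu0)
  lower <- rep(-Inf, length(start)); upper <- rep(Inf, length(start))
  if (nang > 0) {
    ai <- 2 * p + seq_len(nang)
    lower[ai] <- 1e-3; upper[ai] <- pi - 1e-3
  }
  builder <- function(theta) {
    lam <- theta[1:p]
    u <- theta[p + 1:p]
    Phi <- if (nang > 0) corr_from_angles(theta[2 * p + seq_len(nang)], m)
           else diag(m)
    mu <- theta[2 * p + nang + 1:p]
    Lam <- matrix(0, p, m)
    Lam[cbind(1:p, pat)] <- lam
    list(all = list(mu = mu, sigma = Lam %*% Phi %*% t(Lam) + diag(u^2, p)))
  }
  summarize <- function(theta) {
    out <- stats::setNames(theta[1:p], sprintf("lambda%d", 1:p))
    if (nang > 0) {
      Phi <- corr_from_angles(theta[2 * p + seq_len(nang)], m)
      rc <- which(lower.tri(Phi), arr.ind = TRUE)
      for (i in seq_len(nrow(rc)))
        out[sprintf("phi_%d%d", rc[i, 1], rc[i, 2])] <- Phi[rc[i, 1], rc[i, 2]]
    }
    out
  }
  spec <- model_spec(sprintf("CFA (%d factors)", m), par_names, start,
                     builder, summarize, lower = lower, upper = upper,
                     meta = list(structure = "cfa", m = m, pattern = pat))
  fit <- fit_model(spec, list(all = Y), ...)
  sat <- saturated_fit(list(all = Y), n_starts = 1)
  ind <- independence_m2ll(Y)
  n <- nrow(Y)
  Tm <- max(fit$minus2LL - sat$minus2LL, 0)
  dfm <- sat$k - fit$k
  Tb <- max(ind$minus2LL - sat$minus2LL, 0)
  dfb <- sat$k - ind$k
  cfi <- 1 - max(Tm - dfm, 0) / max(Tb - dfb, Tm - dfm, .Machine$double.eps)
  tli <- ((Tb / dfb) - (Tm / dfm)) / max((Tb / dfb) - 1, .Machine$double.eps)
  rmsea <- sqrt(max((Tm - dfm) / (dfm * n), 0))
  gm <- spec$builder(fit$par)$all
  S <- stats::cov(Y, use = "pairwise.complete.obs") * (n - 1) / n
  S[is.na(S)] <- gm$sigma[is.na(S)]
  sdS <- sqrt(diag(S))
  resid <- S / tcrossprod(sdS) - gm$sigma / tcrossprod(sqrt(diag(gm$sigma)))
  srmr <- sqrt(mean(c(resid[lower.tri(resid)],
                      (diag(S) - diag(gm$sigma)) / diag(S))^2))
  th <- fit$par
  Lam <- matrix(0, p, m, dimnames = list(colnames(Y), sprintf("F%d", 1:m)))
  Lam[cbind(1:p, pat)] <- th[1:p]
  phi <- if (nang > 0) corr_from_angles(th[2 * p + seq_len(nang)], m)
         else diag(m)
  structure(list(fit = fit, loadings = Lam, phi = phi,
                 indices = data.frame(chisq = Tm, df = dfm, CFI = cfi,
                                      TLI = tli, RMSEA = rmsea, SRMR = srmr,
                                      AIC = fit$AIC, n = n)),
            class = "cfa_fit")
}

#' @export
print.cfa_fit <- function(x, digits = 3, ...) {
  cat(x$fit$name, "\n")
  print(round(x$indices, digits), row.names = FALSE)
  invisible(x)
}
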