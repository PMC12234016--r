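## Internal numerical helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

## Lower-triangular packing (column-major over the lower triangle, the
## convention used for all Cholesky path matrices in this package).
lt_index <- function(W) which(lower.tri(matrix(0, W, W), diag = TRUE))

lt_vec2mat <- function(x, W) {
  M <- matrix(0, W, W)
  M[lt_index(W)] <- x
  M
}

lt_mat2vec <- function(M) M[lt_index(nrow(M))]

## Correlation matrix from spherical angles: lower-triangular factor L with
## unit-norm rows, R = L L'.  Angles in (0, pi); V(V-1)/2 of them, row-major
## over rows 2..V.  Guarantees unit diagonal and positive semi-definiteness.
corr_from_angles <- function(theta, V) {
  stopifnot(length(theta) == V * (V - 1) / 2)
  L <- diag(V)
  pos <- 1L
  if (V >= 2) {
    for (i in 2:V) {
      ang <- theta[pos:(pos + i - 2L)]
      pos <- pos + i - 1L
      s <- 1
      for (j in seq_len(i - 1L)) {
        L[i, j] <- s * cos(ang[j])
        s <- s * sin(ang[j])
      }
      L[i, i] <- s
    }
  }
  tcrossprod(L)
}

## Inverse map for starting values: angles reproducing a given correlation
## matrix (via its Cholesky factor with positive diagonal, rows unit norm).
angles_from_corr <- function(R) {
  V <- nrow(R)
  if (V < 2) return(numeric(0))
  L <- t(chol(R))
  out <- numeric(0)
  for (i in 2:V) {
    s <- 1
    ang <- numeric(i - 1L)
    for (j in seq_len(i - 1L)) {
      cosang <- L[i, j] / s
      cosang <- min(1, max(-1, cosang))
      ang[j] <- acos(cosang)
      s <- s * sin(ang[j])
      if (s < 1e-12) s <- 1e-12
    }
    out <- c(out, ang)
  }
  out
}

## Fisher-z confidence interval for a Pearson correlation.
fisher_ci <- function(r, n, level = 0.95) {
  if (is.na(r) || n < 4) return(c(NA_real_, NA_real_))
  rc <- min(1 - 1e-12, max(-1 + 1e-12, r))
  z <- atanh(rc)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  ci <- tanh(c(z - q * se, z + q * se))
  # clipping at |r| = 1 can push an endpoint inside the point estimate by
  # machine precision; force containment
  c(min(ci[1], r), max(ci[2], r))
}

## Central-difference Jacobian of a vector-valued function.
num_jacobian <- function(f, x, eps = 1e-5) {
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  rownames(J) <- names(f0)
  J
}

## Sample skewness (moment estimator), NA-tolerant.
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  mean((x - m)^3) / s2^1.5
}

## Derive a stream of distinct 31-bit seeds from one master seed.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  (as.integer(seed) + 104729L * seq_len(n)) %% 2147483629L
}
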