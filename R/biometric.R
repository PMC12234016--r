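## Biometric covariance algebra: expected twin-pair covariance matrices for
## the classical variance components A (additive genetic), C (shared
## environment), D (dominance) and E (non-shared environment).
##
## Cross-twin weights: MZ pairs share all segregating genes, DZ pairs on
## average half of them; dominance deviations correlate 0.25 in DZ pairs;
## the shared environment correlates 1 in both; E is uncorrelated.

KINSHIP <- list(
  A = c(MZ = 1.0, DZ = 0.5),
  C = c(MZ = 1.0, DZ = 1.0),
  D = c(MZ = 1.0, DZ = 0.25),
  E = c(MZ = 0.0, DZ = 0.0)
)

FAMILY_COMPONENTS <- list(
  ACE = c("A", "C", "E"), ADE = c("A", "D", "E"), AE = c("A", "E"),
  CE = c("C", "E"), E = "E"
)

check_components <- function(components) {
  components <- match.arg(components, c("A", "C", "D", "E"), several.ok = TRUE)
  if (!"E" %in% components) stop("E (non-shared environment) must be included")
  if (all(c("C", "D") %in% components))
    stop("C and D are not jointly identifiable in a twins-reared-together design")
  components
}

## Assemble a 2p x 2p twin-pair covariance from p x p component covariance
## matrices: within-twin block = sum of components, cross-twin block =
## kinship-weighted sum.
twin_pair_cov <- function(comps, zyg) {
  p <- nrow(comps[[1]])
  within <- Reduce(`+`, comps)
  cross <- matrix(0, p, p)
  for (nm in names(comps))
    cross <- cross + KINSHIP[[nm]][[zyg]] * comps[[nm]]
  rbind(cbind(within, cross), cbind(t(cross), within))
}

as_path_matrix <- function(x, p, what) {
  if (is.null(x)) return(NULL)
  if (length(x) == 1 && p == 1) x <- matrix(x, 1, 1)
  x <- as.matrix(x)
  if (!all(dim(x) == c(p, p)))
    stop(what, " path matrix must be ", p, "x", p)
  x
}

#' Expected twin-pair mean and covariance structure
#'
#' Builds the model-implied mean vector and MZ/DZ covariance matrices for a
#' variance-components family, from per-component path matrices. Each
#' component's covariance contribution is \eqn{X X'} where `X` is the
#' (typically lower-triangular) path matrix supplied in `theta`. The
#' within-twin block is the sum of all component covariances; the cross-twin
#' block weights A, C and D by their MZ/DZ kinship coefficients
#' (1/0.5, 1/1, 1/0.25) and drops E. Means are constrained equal across
#' twins and zygosity groups.
#'
#' @param family one of "ACE", "ADE", "AE", "CE", "E".
#' @param theta named list with path matrices `a`, `c`, `d`, `e` (those the
#'   family uses; p x p for p = W*V phenotypes, scalars allowed when p = 1)
#'   and optionally `mean` (length-p vector, default 0).
#' @param W number of waves; @param V number of variables per wave.
#' @return list with `sigma_mz`, `sigma_dz` (2p x 2p) and `mu` (length 2p).
#' @export
expected_cov <- function(family = c("ACE", "ADE", "AE", "CE", "E"), theta,
                         W = 1, V = 1) {
  family <- match.arg(family)
  p <- W * V
  comps <- list()
  for (comp in FAMILY_COMPONENTS[[family]]) {
    X <- as_path_matrix(theta[[tolower(comp)]], p, comp)
    if (is.null(X)) stop("theta$", tolower(comp), " missing for family ", family)
    comps[[comp]] <- tcrossprod(X)
  }
  mu1 <- theta$mean %||% rep(0, p)
  if (length(mu1) != p) stop("theta$mean must have length ", p)
  list(sigma_mz = twin_pair_cov(comps, "MZ"),
       sigma_dz = twin_pair_cov(comps, "DZ"),
       mu = rep(mu1, 2))
}

## Standardized per-phenotype variance shares from component covariances.
shares_from_comps <- function(comps) {
  tot <- Reduce(`+`, lapply(comps, diag))
  out <- lapply(comps, function(S) diag(S) / tot)
  stats::setNames(out, names(comps))
}
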