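## User-facing fitting wrappers: compute data-driven starting values from the
## observed moments, build the spec, and hand off to the FIML engine.

start_moments <- function(st) pooled_moments(st)

#' Fit a univariate twin model at one wave
#'
#' @param data a `twin_dataset`.
#' @param wave wave to analyse.
#' @param family "ACE", "ADE", "AE", "CE" or "E".
#' @param ... passed to [fit_model()].
#' @return a `twin_fit`.
#' @export
fit_univariate <- function(data, wave = 1, family = "AE", ...) {
  st <- as_group_stats(twin_matrices(data, waves = wave))
  mom <- start_moments(st)
  spec <- build_univariate(family, start_var = mom$within[1, 1],
                           start_mean = mom$mu[1])
  fit_model(spec, st, ...)
}

#' Fit and compare univariate families at one wave, selecting by AIC
#'
#' Fits each requested family to the same wave and returns the comparison
#' table plus the best-fitting model (minimal AIC, ties toward fewer
#' parameters).
#'
#' @inheritParams fit_univariate
#' @param families families to fit.
#' @return list with `fits`, `comparison` and `best` (a `twin_fit`).
#' @export
select_univariate <- function(data, wave = 1,
                              families = c("ACE", "ADE", "AE"), ...) {
  fits <- lapply(stats::setNames(families, families), function(f)
    fit_univariate(data, wave, f, ...))
  nesting <- c(AE = "ACE", CE = "ACE", E = "AE")
  nesting <- nesting[names(nesting) %in% families &
                       nesting %in% families]
  cmp <- compare_fits(fits, nesting = nesting)
  list(fits = fits, comparison = cmp, best = fits[[attr(cmp, "best")]])
}

#' Fit a multivariate Cholesky decomposition
#'
#' @param data a `twin_dataset` with W >= 2 waves.
#' @param components biometric components, e.g. `c("A","E")`.
#' @param waves waves to include (default all).
#' @param ... passed to [fit_model()].
#' @return a `twin_fit`.
#' @export
fit_cholesky <- function(data, components = c("A", "E"), waves = NULL, ...) {
  st <- as_group_stats(twin_matrices(data, waves = waves))
  mom <- start_moments(st)
  spec <- build_cholesky(nrow(mom$within), components,
                         start_cov = mom$within, start_mean = mom$mu)
  fit_model(spec, st, ...)
}

#' Fit a common pathway (latent stability) model
#'
#' @inheritParams fit_cholesky
#' @return a `twin_fit`.
#' @export
fit_common_pathway <- function(data, components = c("A", "E"), waves = NULL,
                               ...) {
  st <- as_group_stats(twin_matrices(data, waves = waves))
  mom <- start_moments(st)
  spec <- build_common_pathway(nrow(mom$within), components,
                               start_cov = mom$within, start_mean = mom$mu)
  fit_model(spec, st, ...)
}

#' Fit a correlated-factor model
#'
#' The selected wave columns are treated as the V correlated variables (for
#' the classic bivariate case, pass the two dimension scores as two waves of
#' the dataset).
#'
#' @inheritParams fit_cholesky
#' @return a `twin_fit`.
#' @export
fit_correlated_factors <- function(data, components = c("A", "E"),
                                   waves = NULL, ...) {
  st <- as_group_stats(twin_matrices(data, waves = waves))
  mom <- start_moments(st)
  spec <- build_correlated_factors(nrow(mom$within), components,
                                   start_cov = mom$within, start_mean = mom$mu)
  fit_model(spec, st, ...)
}
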