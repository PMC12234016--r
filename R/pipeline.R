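## End-to-end study driver: descriptives -> univariate fits per wave ->
## Cholesky -> common pathway -> optional item-level EFA/CFA, with every
## random step seeded and the whole bundle serialized to JSON/CSV.

#' Run the full longitudinal twin analysis sequence
#'
#' Executes, on a canonical twin dataset (loaded from CSV or simulated from
#' a supplied truth): descriptive statistics (longitudinal and cross-twin
#' correlations, internal consistency when items are present), per-wave
#' univariate model selection, multivariate Cholesky and common pathway
#' fits with AIC comparison, and, when item columns exist, the EFA/CFA
#' stage. Any stage failure is caught and reported in the bundle rather
#' than aborting the run.
#'
#' @param config list with elements:
#'   \describe{
#'   \item{input}{path to a canonical wide CSV, or}
#'   \item{sim}{a [sim_config()] to simulate from;}
#'   \item{sqrt_transform}{apply the square-root transform (default TRUE);}
#'   \item{families}{multivariate families to compare (default
#'     `c("ACE","ADE","AE")`);}
#'   \item{univariate_families}{families for the per-wave stage;}
#'   \item{efa_waves}{waves at which to run the item-level stage (default
#'     none);}
#'   \item{seed}{master seed (default 1);}
#'   \item{out_dir}{optional output directory for CSV/JSON reports;}
#'   \item{n_starts}{optimizer starts per fit (default 5).}
#'   }
#' @return a named list (report bundle) with per-stage results; written to
#'   `out_dir/report.json` (and CSV tables) when `out_dir` is given.
#' @export
run_study <- function(config) {
  seed <- config$seed %||% 1
  n_starts <- config$n_starts %||% 5
  families <- config$families %||% c("ACE", "ADE", "AE")
  uni_families <- config$univariate_families %||% families
  bundle <- list(config = config[setdiff(names(config), c("sim", "out_dir"))],
                 errors = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      bundle$errors[[name]] <<- conditionMessage(e)
      NULL
    })
    bundle[[name]] <<- res
    res
  }
  ## data
  truth <- NULL
  if (!is.null(config$input)) {
    data <- load_twin_csv(config$input)
  } else if (!is.null(config$sim)) {
    sim <- simulate_twins(config$sim)
    data <- sim$data
    truth <- sim$truth
  } else stop("config needs 'input' or 'sim'")
  if (isTRUE(config$sqrt_transform %||% TRUE)) data <- sqrt_transform(data)
  W <- attr(data, "n_waves")
  bundle$n_pairs <- c(MZ = sum(data$zygosity == "MZ"),
                      DZ = sum(data$zygosity == "DZ"))
  bundle$n_waves <- W
  ## descriptives
  stage("longitudinal_correlations",
        if (W >= 2) longitudinal_correlations(data, seed = seed))
  stage("crosstwin_correlations", crosstwin_correlations(data))
  if (attr(data, "n_items") > 0) stage("cronbach_alpha", cronbach_alpha(data))
  ## univariate per wave
  stage("univariate", {
    out <- lapply(seq_len(W), function(w) {
      sel <- select_univariate(data, wave = w, families = uni_families,
                               n_starts = n_starts, seed = seed)
      list(wave = w, comparison = sel$comparison,
           best = attr(sel$comparison, "best"),
           shares = standardize(sel$best))
    })
    names(out) <- sprintf("wave%d", seq_len(W))
    out
  })
  ## multivariate
  if (W >= 2) stage("cholesky", {
    fits <- lapply(stats::setNames(families, families), function(f)
      fit_cholesky(data, FAMILY_COMPONENTS[[f]], n_starts = n_starts,
                   seed = seed))
    cmp <- compare_fits(fits, nesting = c(AE = "ACE"))
    best <- fits[[attr(cmp, "best")]]
    list(comparison = cmp, best = attr(cmp, "best"),
         estimates = standardize(best))
  })
  if (W >= 3) stage("common_pathway", {
    fits <- lapply(stats::setNames(families, families), function(f)
      fit_common_pathway(data, FAMILY_COMPONENTS[[f]], n_starts = n_starts,
                         seed = seed))
    cmp <- compare_fits(fits, nesting = c(AE = "ACE"))
    best <- fits[[attr(cmp, "best")]]
    list(comparison = cmp, best = attr(cmp, "best"),
         estimates = standardize(best))
  })
  ## item stage
  for (w in config$efa_waves %||% integer(0)) {
    stage(sprintf("factor_structure_w%d", w), {
      it <- item_scores(data, wave = w, one_per_pair = TRUE, seed = seed)
      sp <- split_sample(it, 0.7, seed = seed)
      ef <- efa(sp$explore, seed = seed)
      cf <- if (!all(is.na(ef$assignment)))
        cfa(sp$confirm, ef$assignment, n_starts = 1)
      list(efa = list(n_factors = ef$n_factors, loadings = ef$loadings,
                      phi = ef$phi, assignment = ef$assignment),
           cfa_indices = if (!is.null(cf)) cf$indices)
    })
  }
  if (!is.null(truth)) bundle$truth <- truth
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  invisible(bundle)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("longitudinal_correlations", "crosstwin_correlations",
               "cronbach_alpha")) {
    if (!is.null(bundle[[nm]]))
      utils::write.csv(bundle[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  for (nm in c("cholesky", "common_pathway")) {
    if (!is.null(bundle[[nm]])) {
      utils::write.csv(bundle[[nm]]$comparison,
                       file.path(out_dir, paste0(nm, "_comparison.csv")),
                       row.names = FALSE)
      utils::write.csv(bundle[[nm]]$estimates,
                       file.path(out_dir, paste0(nm, "_estimates.csv")),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(strip_for_json(bundle),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       force = TRUE, na = "null")
  invisible(out_dir)
}

## Drop heavyweight matrix members before serialization.
strip_for_json <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x)))
      x <- x[setdiff(names(x), c("sigma_mz", "sigma_dz", "spec"))]
    lapply(x, strip_for_json)
  } else x
}
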