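## Fit comparison: AIC ranking plus likelihood-ratio tests along declared
## nestings, mirroring the usual twin-model fit table (-2LL, df, AIC).

#' Compare fitted models and select the best by AIC
#'
#' All fits must come from the same data (checked via a fingerprint of group
#' sizes, observed-cell counts and data sums). The comparison table reports
#' -2LL, df, k, AIC and delta-AIC versus the best model; for declared
#' nestings a chi-square likelihood-ratio test of the restricted model
#' against its parent is added. Note that when the truth lies on a boundary
#' of the parameter space (a variance component equal to zero), the naive
#' chi-square reference makes these p-values conservative; they are reported
#' as-is.
#'
#' @param fits named list of `twin_fit` objects.
#' @param nesting named character vector: `c(child = "parent")`, parent the
#'   more general model.
#' @return data.frame (one row per model, AIC-ranked input order preserved)
#'   with attribute `best` naming the minimal-AIC model (ties broken toward
#'   fewer parameters, then input order).
#' @export
compare_fits <- function(fits, nesting = NULL) {
  stopifnot(is.list(fits), length(fits) >= 1)
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- vapply(fits, `[[`, "", "name")
  fp <- lapply(fits, `[[`, "fingerprint")
  for (i in seq_along(fp)[-1]) {
    same <- identical(fp[[1]]$n, fp[[i]]$n) &&
      identical(fp[[1]]$cells, fp[[i]]$cells) &&
      all(abs(fp[[1]]$sum - fp[[i]]$sum) < 1e-6 * (1 + abs(fp[[1]]$sum)))
    if (!same)
      stop("fits '", names(fits)[1], "' and '", names(fits)[i],
           "' were not computed on identical data")
  }
  tab <- data.frame(
    model = names(fits),
    minus2LL = vapply(fits, `[[`, 0, "minus2LL"),
    df = vapply(fits, `[[`, 0, "df"),
    k = vapply(fits, `[[`, 0, "k"),
    AIC = vapply(fits, `[[`, 0, "AIC"),
    row.names = NULL)
  ord <- order(tab$AIC, tab$k)
  best <- tab$model[ord[1]]
  tab$dAIC <- tab$AIC - min(tab$AIC)
  tab$parent <- NA_character_
  tab$lrt_chisq <- tab$lrt_p <- NA_real_
  tab$lrt_df <- NA_integer_
  for (child in names(nesting)) {
    parent <- nesting[[child]]
    if (!child %in% tab$model || !parent %in% tab$model) next
    i <- match(child, tab$model); jp <- match(parent, tab$model)
    chisq <- tab$minus2LL[i] - tab$minus2LL[jp]
    dfd <- tab$k[jp] - tab$k[i]
    if (dfd <= 0) stop("nesting '", child, "' in '", parent,
                       "' has no parameter difference")
    tab$parent[i] <- parent
    tab$lrt_chisq[i] <- chisq
    tab$lrt_df[i] <- dfd
    tab$lrt_p[i] <- stats::pchisq(max(chisq, 0), dfd, lower.tail = FALSE)
  }
  attr(tab, "best") <- best
  tab
}
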