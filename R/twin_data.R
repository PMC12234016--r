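## Data model and descriptive stage: canonical wide per-pair table, CSV I/O,
## square-root transform, longitudinal and cross-twin correlations, alpha.

#' Construct a twin dataset
#'
#' A twin dataset is a wide data.frame with one row per twin pair. Required
#' columns are `pair_id` (unique) and `zygosity` (`"MZ"` or `"DZ"`).
#' Phenotype scores live in columns `score_w<w>_t<j>` for wave `w` and twin
#' `j` in 1:2; optional item-level responses in `item_w<w>_i<i>_t<j>`.
#' Optional covariates `sex` and `age` are carried through untouched.
#'
#' @param df data.frame in the wide per-pair layout.
#' @return The validated data.frame with class `twin_dataset` and attributes
#'   `n_waves` and `n_items`.
#' @export
twin_dataset <- function(df) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df)
  if (!all(c("pair_id", "zygosity") %in% names(df)))
    stop("twin dataset needs 'pair_id' and 'zygosity' columns")
  if (anyDuplicated(df$pair_id)) {
    dup <- which(duplicated(df$pair_id))
    stop("duplicated pair_id at row(s): ", paste(dup, collapse = ", "))
  }
  bad <- which(!df$zygosity %in% c("MZ", "DZ"))
  if (length(bad))
    stop("unknown zygosity code at row(s): ", paste(bad, collapse = ", "),
         " (value(s): ", paste(unique(df$zygosity[bad]), collapse = ", "), ")")
  sw <- grep("^score_w[0-9]+_t[12]$", names(df), value = TRUE)
  iw <- grep("^item_w[0-9]+_i[0-9]+_t[12]$", names(df), value = TRUE)
  n_waves <- if (length(sw)) {
    max(as.integer(sub("^score_w([0-9]+)_t[12]$", "\\1", sw)))
  } else if (length(iw)) {
    max(as.integer(sub("^item_w([0-9]+)_i[0-9]+_t[12]$", "\\1", iw)))
  } else stop("no score_w*_t* or item_w*_i*_t* columns found")
  n_items <- if (length(iw))
    max(as.integer(sub("^item_w[0-9]+_i([0-9]+)_t[12]$", "\\1", iw))) else 0L
  structure(df, class = c("twin_dataset", "data.frame"),
            n_waves = n_waves, n_items = n_items)
}

#' @export
print.twin_dataset <- function(x, ...) {
  cat(sprintf("twin_dataset: %d pairs (%d MZ, %d DZ), %d wave(s)%s\n",
              nrow(x), sum(x$zygosity == "MZ"), sum(x$zygosity == "DZ"),
              attr(x, "n_waves"),
              if (attr(x, "n_items") > 0)
                sprintf(", %d items", attr(x, "n_items")) else ""))
  invisible(x)
}

score_cols <- function(data, waves = NULL, twin = NULL) {
  W <- attr(data, "n_waves")
  waves <- waves %||% seq_len(W)
  twin <- twin %||% 1:2
  unlist(lapply(twin, function(t)
    sprintf("score_w%d_t%d", waves, t)))
}

#' Extract per-group score matrices for model fitting
#'
#' Returns numeric matrices (pairs x 2W; twin 1's waves then twin 2's) for
#' each zygosity group, the column order assumed by all model builders.
#'
#' @param data a `twin_dataset`.
#' @param waves integer vector of waves to keep (default all).
#' @return list with elements `MZ` and `DZ`.
#' @export
twin_matrices <- function(data, waves = NULL) {
  cols <- score_cols(data, waves)
  stopifnot(all(cols %in% names(data)))
  lapply(stats::setNames(c("MZ", "DZ"), c("MZ", "DZ")), function(z)
    as.matrix(data[data$zygosity == z, cols, drop = FALSE]))
}

#' Write a twin dataset to the canonical wide CSV
#' @param data a `twin_dataset`.
#' @param path output file path.
#' @export
write_twin_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Load a twin dataset from the canonical wide CSV
#'
#' Rows where neither twin has any observed score are dropped with a message.
#' Unknown zygosity codes and duplicated pair ids are rejected with row
#' numbers.
#'
#' @param path CSV file path.
#' @param col_map optional named character vector mapping file columns to
#'   canonical names (`c(canonical = "file_name")`).
#' @return a `twin_dataset`.
#' @export
load_twin_csv <- function(path, col_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      j <- match(col_map[[canon]], names(df))
      if (is.na(j)) stop("mapped column not found: ", col_map[[canon]])
      names(df)[j] <- canon
    }
  }
  d <- twin_dataset(df)
  sc <- grep("^(score|item)_", names(d), value = TRUE)
  all_missing <- apply(d[, sc, drop = FALSE], 1, function(r) all(is.na(r)))
  if (any(all_missing)) {
    message(sum(all_missing), " pair(s) with no observed data dropped")
    d <- twin_dataset(as.data.frame(d)[!all_missing, , drop = FALSE])
  }
  d
}

#' Square-root transform of all phenotype scores
#'
#' Right-skewed sum scores are square-root transformed before twin modelling;
#' missing values are preserved and negative scores rejected.
#'
#' @param data a `twin_dataset`.
#' @return the dataset with every `score_*` column replaced by its square root.
#' @export
sqrt_transform <- function(data) {
  cols <- grep("^score_w[0-9]+_t[12]$", names(data), value = TRUE)
  vals <- as.matrix(data[, cols, drop = FALSE])
  if (any(vals < 0, na.rm = TRUE)) stop("negative scores cannot be sqrt-transformed")
  data[, cols] <- sqrt(vals)
  data
}

## One individual-level score matrix (rows = persons). With one_per_pair a
## random co-twin is dropped from every pair; otherwise twins are stacked.
individual_scores <- function(data, one_per_pair = FALSE, seed = 1) {
  W <- attr(data, "n_waves")
  m1 <- as.matrix(data[, score_cols(data, twin = 1), drop = FALSE])
  m2 <- as.matrix(data[, score_cols(data, twin = 2), drop = FALSE])
  colnames(m1) <- colnames(m2) <- sprintf("wave%d", seq_len(W))
  if (one_per_pair) {
    set.seed(seed)
    pick <- stats::runif(nrow(data)) < 0.5
    out <- m1
    out[pick, ] <- m2[pick, ]
    out
  } else rbind(m1, m2)
}

#' Longitudinal (cross-wave) correlations
#'
#' Pearson correlations between waves on pairwise-complete observations, with
#' Fisher-z 95\% confidence intervals. By default one co-twin per pair is
#' selected at random so that observations are independent.
#'
#' @param data a `twin_dataset` with at least two waves.
#' @param one_per_pair keep one randomly chosen twin per pair (default TRUE).
#' @param seed RNG seed for the co-twin selection.
#' @param level confidence level.
#' @return data.frame with columns wave_i, wave_j, n, r, ci_lo, ci_hi.
#' @export
longitudinal_correlations <- function(data, one_per_pair = TRUE, seed = 1,
                                      level = 0.95) {
  W <- attr(data, "n_waves")
  if (W < 2) stop("need at least two waves")
  m <- individual_scores(data, one_per_pair = one_per_pair, seed = seed)
  out <- NULL
  for (i in 1:(W - 1)) for (j in (i + 1):W) {
    ok <- stats::complete.cases(m[, c(i, j)])
    n <- sum(ok)
    r <- if (n >= 3) stats::cor(m[ok, i], m[ok, j]) else NA_real_
    ci <- fisher_ci(r, n, level)
    out <- rbind(out, data.frame(wave_i = i, wave_j = j, n = n, r = r,
                                 ci_lo = ci[1], ci_hi = ci[2]))
  }
  out$undefined <- is.na(out$r)
  out
}

#' Cross-twin correlations per zygosity group and wave
#'
#' Double-entered Pearson correlations between co-twins' scores: each pair
#' contributes both orderings, so the statistic is invariant to twin
#' labelling. Groups with fewer than 3 complete pairs are flagged undefined.
#'
#' @param data a `twin_dataset`.
#' @return data.frame with columns zygosity, wave, n_pairs, r, undefined.
#' @export
crosstwin_correlations <- function(data) {
  W <- attr(data, "n_waves")
  out <- NULL
  for (z in c("MZ", "DZ")) {
    d <- data[data$zygosity == z, , drop = FALSE]
    for (w in seq_len(W)) {
      x <- d[[sprintf("score_w%d_t1", w)]]
      y <- d[[sprintf("score_w%d_t2", w)]]
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      r <- if (n >= 3) stats::cor(c(x[ok], y[ok]), c(y[ok], x[ok])) else NA_real_
      out <- rbind(out, data.frame(zygosity = z, wave = w, n_pairs = n,
                                   r = r, undefined = is.na(r)))
    }
  }
  out
}

#' Cronbach's alpha per wave from item-level data
#'
#' Computed on complete cases over stacked individuals for each wave:
#' alpha = k/(k-1) * (1 - sum(item variances)/variance of the sum score).
#'
#' @param data a `twin_dataset` carrying `item_w*_i*_t*` columns.
#' @return data.frame with columns wave, k_items, n, alpha, undefined.
#' @export
cronbach_alpha <- function(data) {
  W <- attr(data, "n_waves")
  K <- attr(data, "n_items")
  if (K < 2) stop("need at least two items")
  out <- NULL
  for (w in seq_len(W)) {
    m <- do.call(rbind, lapply(1:2, function(t) {
      cols <- sprintf("item_w%d_i%d_t%d", w, seq_len(K), t)
      as.matrix(data[, cols, drop = FALSE])
    }))
    m <- m[stats::complete.cases(m), , drop = FALSE]
    n <- nrow(m)
    a <- NA_real_
    if (n >= 3) {
      vt <- stats::var(rowSums(m))
      if (vt > 0) a <- (K / (K - 1)) * (1 - sum(apply(m, 2, stats::var)) / vt)
    }
    out <- rbind(out, data.frame(wave = w, k_items = K, n = n, alpha = a,
                                 undefined = is.na(a)))
  }
  out
}
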