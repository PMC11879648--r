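#' Tukey median polish of a two-way table
#'
#' Robust additive decomposition of a feature-by-channel matrix of log2
#' intensities into an overall effect, row (feature) effects, column
#' (channel) effects and residuals, by iteratively sweeping out row and
#' column medians. Missing entries are ignored by the medians; rows or
#' columns with no finite entry are excluded (with a warning) and their
#' effects reported as `NA`.
#'
#' @param mat Numeric matrix, possibly with `NA` entries.
#' @param tol Convergence tolerance on the relative change of the sum of
#'   absolute residuals between sweeps.
#' @param max_sweeps Maximum number of row+column sweeps.
#' @return A list with elements `overall` (scalar), `row` (length
#'   `nrow(mat)`), `col` (length `ncol(mat)`), `residuals` (same shape as
#'   `mat`) and `converged` (logical). For observed cells,
#'   `mat = overall + row + col + residuals` up to numerical precision.
#' @examples
#' median_polish(rbind(c(1, 2), c(3, 4)))
#' @export
median_polish <- function(mat, tol = 1e-10, max_sweeps = 100L) {
  if (!is.matrix(mat)) {
    mat <- as.matrix(mat)
  }
  storage.mode(mat) <- "double"
  live_rows <- rowSums(is.finite(mat)) > 0
  live_cols <- colSums(is.finite(mat)) > 0
  if (!all(live_rows) || !all(live_cols)) {
    warn(sprintf(
      "median_polish: excluding %d all-missing row(s) and %d all-missing column(s).",
      sum(!live_rows), sum(!live_cols)
    ))
  }
  row_eff <- rep(NA_real_, nrow(mat))
  col_eff <- rep(NA_real_, ncol(mat))
  residuals <- matrix(NA_real_, nrow(mat), ncol(mat),
    dimnames = dimnames(mat)
  )
  z <- mat[live_rows, live_cols, drop = FALSE]
  if (nrow(z) == 0L || ncol(z) == 0L) {
    return(list(
      overall = NA_real_, row = row_eff, col = col_eff,
      residuals = residuals, converged = FALSE
    ))
  }

  # classical Tukey sweep: rows first, then columns, re-absorbing the
  # median of the opposite effects into the overall term each half-sweep
  t_eff <- 0
  r_eff <- rep(0, nrow(z))
  c_eff <- rep(0, ncol(z))
  oldsum <- 0
  converged <- FALSE
  for (iter in seq_len(max_sweeps)) {
    rdelta <- apply(z, 1L, median, na.rm = TRUE)
    z <- z - rdelta
    r_eff <- r_eff + rdelta
    delta <- median(c_eff)
    c_eff <- c_eff - delta
    t_eff <- t_eff + delta

    cdelta <- apply(z, 2L, median, na.rm = TRUE)
    z <- sweep(z, 2L, cdelta)
    c_eff <- c_eff + cdelta
    delta <- median(r_eff)
    r_eff <- r_eff - delta
    t_eff <- t_eff + delta

    newsum <- sum(abs(z), na.rm = TRUE)
    if (newsum == 0 || abs(newsum - oldsum) < tol * newsum) {
      converged <- TRUE
      break
    }
    oldsum <- newsum
  }

  row_eff[live_rows] <- r_eff
  col_eff[live_cols] <- c_eff
  residuals[live_rows, live_cols] <- z
  list(
    overall = t_eff, row = row_eff, col = col_eff,
    residuals = residuals, converged = converged
  )
}

#' Baseline per-protein channel summaries by median polish
#'
#' The single-protein summarization baseline: features of one protein in
#' one mixture are arranged as a feature-by-channel matrix of log2
#' intensities and decomposed by [median_polish()]; the per-channel
#' abundance summary is the overall effect plus the channel effect.
#'
#' @param features Feature tibble (see [read_feature_table()]) restricted
#'   to the features of one protein and one mixture. The `protein` column
#'   is not consulted; all rows are used.
#' @param ... Passed on to [median_polish()].
#' @return A tibble with columns `channel` and `abundance`; channels with
#'   no observed intensity get `NA` abundance.
#' @export
tmp_summarize <- function(features, ...) {
  assert_feature_table(features)
  if (nrow(features) == 0L) {
    abort("tmp_summarize: no features to summarize.")
  }
  mat <- feature_matrix(features)
  fit <- median_polish(mat, ...)
  tibble::tibble(
    channel = colnames(mat),
    abundance = fit$overall + fit$col
  )
}

# internal: feature-by-channel matrix of log2 intensities for one mixture.
# channel order: natural sort of unique channel labels unless `channels`
# is supplied.
feature_matrix <- function(features, channels = NULL) {
  fid <- unique(features$feature_id)
  ch <- channels %||% sort_channels(unique(features$channel))
  mat <- matrix(NA_real_, length(fid), length(ch), dimnames = list(fid, ch))
  idx <- cbind(
    match(features$feature_id, fid),
    match(as.character(features$channel), ch)
  )
  mat[idx] <- features$log2_intensity
  mat
}

# natural ordering of channel labels (numeric if possible)
sort_channels <- function(x) {
  x <- as.character(x)
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) x[order(num)] else sort(x)
}
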