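#' Fit the per-protein linear model on channel summaries
#'
#' Models the protein-level summaries of one protein as condition (or
#' condition-time cell) means plus, for multi-mixture designs, an
#' additive mixture effect. The mixture term is fitted as a fixed
#' blocking effect; in the balanced designs targeted here this leaves
#' condition contrasts unchanged relative to a random-intercept
#' formulation while avoiding variance-component estimation.
#' Single-mixture designs reduce to a one-way layout.
#'
#' @param summaries Summary tibble for one protein: columns `abundance`,
#'   `condition`, `mixture` (and optionally `time`, combined with
#'   `condition` into cells when `design = "condition-time"`).
#' @param design `"group"` (condition means) or `"condition-time"`
#'   (cell means of condition x time).
#' @return A `protein_fit` object: estimable condition means, their
#'   covariance, residual degrees of freedom and variance.
#' @export
fit_protein_model <- function(summaries, design = c("group", "condition-time")) {
  design <- match.arg(design)
  dat <- summaries |>
    dplyr::filter(is.finite(.data$abundance))
  if (design == "condition-time") {
    if (!"time" %in% names(dat)) {
      abort("design 'condition-time' requires a `time` column.")
    }
    dat$condition <- paste(dat$condition, dat$time, sep = ":")
  }
  dat$condition <- factor(dat$condition)
  if (nlevels(dat$condition) < 2L) {
    abort("fit_protein_model: need at least two conditions with data.")
  }
  multi_mixture <- dplyr::n_distinct(dat$mixture) > 1L
  formula <- if (multi_mixture) {
    abundance ~ 0 + condition + factor(mixture)
  } else {
    abundance ~ 0 + condition
  }
  fit <- stats::lm(formula, data = dat)
  cf <- coef(fit)
  cond_idx <- grep("^condition", names(cf))
  cond_means <- cf[cond_idx]
  names(cond_means) <- sub("^condition", "", names(cond_means))
  V <- matrix(NA_real_, length(cond_idx), length(cond_idx),
    dimnames = list(names(cond_means), names(cond_means))
  )
  ok <- !is.na(cond_means)
  if (any(ok)) {
    # vcov() of the full fit drops aliased coefficients
    vc <- stats::vcov(fit)
    keep <- intersect(rownames(vc), paste0("condition", names(cond_means)[ok]))
    V[sub("^condition", "", keep), sub("^condition", "", keep)] <-
      vc[keep, keep]
  }
  structure(
    list(
      condition_means = cond_means,
      vcov = V,
      df = fit$df.residual,
      sigma2 = sum(fit$residuals^2) / max(fit$df.residual, 1L),
      design = design,
      protein = if ("protein" %in% names(dat)) dat$protein[[1L]] else NA_character_
    ),
    class = "protein_fit"
  )
}

#' Test a contrast of condition means
#'
#' The log2 fold change is the contrast applied to the estimated
#' condition means; its standard error comes from the fit's covariance;
#' the two-sided p-value from a t distribution with the fit's residual
#' degrees of freedom.
#'
#' @param fit A `protein_fit` from [fit_protein_model()].
#' @param contrast Named numeric vector of coefficients over condition
#'   levels, summing to zero. Conditions absent from the vector get
#'   coefficient zero.
#' @param label Contrast label for the result row; defaults to
#'   `"pos-vs-neg"` built from the signs of the coefficients.
#' @return One-row tibble (`protein`, `contrast`, `log2fc`, `se`, `df`,
#'   `t`, `p_value`, `degenerate`), or a zero-row tibble when the
#'   contrast is not estimable (some involved condition has no data).
#' @export
test_contrast <- function(fit, contrast, label = NULL) {
  if (!inherits(fit, "protein_fit")) abort("`fit` must be a protein_fit.")
  if (abs(sum(contrast)) > 1e-8) {
    abort("contrast coefficients must sum to zero.")
  }
  label <- label %||% default_contrast_label(contrast)
  used <- names(contrast)[contrast != 0]
  means <- fit$condition_means
  if (!all(used %in% names(means)) || anyNA(means[used])) {
    return(empty_result())
  }
  L <- setNames(rep(0, length(means)), names(means))
  L[used] <- contrast[used]
  est <- sum(L * means)
  Vok <- fit$vcov[used, used, drop = FALSE]
  if (anyNA(Vok)) {
    return(empty_result())
  }
  se <- sqrt(drop(t(contrast[used]) %*% Vok %*% contrast[used]))
  degenerate <- FALSE
  # an (essentially) zero standard error cannot support a t statistic;
  # threshold absorbs floating-point residue of exact fits
  if (se < 1e-10 || fit$df < 1L) {
    degenerate <- TRUE
    p <- if (abs(est) > 1e-10) 0 else 1
    tstat <- if (abs(est) > 1e-10) Inf * sign(est) else 0
  } else {
    tstat <- est / se
    p <- 2 * pt(-abs(tstat), df = fit$df)
  }
  tibble::tibble(
    protein = fit$protein,
    contrast = label,
    log2fc = est,
    se = se,
    df = fit$df,
    t = tstat,
    p_value = p,
    degenerate = degenerate
  )
}

empty_result <- function() {
  tibble::tibble(
    protein = character(0), contrast = character(0),
    log2fc = numeric(0), se = numeric(0), df = numeric(0),
    t = numeric(0), p_value = numeric(0), degenerate = logical(0)
  )
}

default_contrast_label <- function(contrast) {
  pos <- names(contrast)[contrast > 0]
  neg <- names(contrast)[contrast < 0]
  sprintf("%s vs %s", paste(pos, collapse = "+"), paste(neg, collapse = "+"))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of raw p-values.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone, `>=` raw, `<= 1`).
#' @export
adjust_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Pairwise contrasts against a reference condition
#'
#' @param conditions Character vector of condition levels.
#' @param reference The reference level; default the first.
#' @return Named list of contrast vectors (`condition - reference`).
#' @export
ref_contrasts <- function(conditions, reference = conditions[[1L]]) {
  conditions <- unique(as.character(conditions))
  others <- setdiff(conditions, reference)
  out <- lapply(others, function(g) {
    setNames(c(1, -1), c(g, reference))
  })
  names(out) <- paste0(others, " vs ", reference)
  out
}

#' Differential abundance testing over all proteins
#'
#' Fits the per-protein linear model on the channel summaries and tests
#' each contrast, then adjusts p-values across proteins within each
#' contrast by Benjamini-Hochberg. Not-estimable (protein, contrast)
#' pairs are absent from the result rather than reported as `NA`.
#'
#' @param summaries A `protein_summaries` object or its summary tibble.
#' @param contrasts A named list of contrast vectors over condition
#'   levels (see [ref_contrasts()]), or a single named vector.
#' @param design Passed to [fit_protein_model()].
#' @return A tibble of class `differential_results` with one row per
#'   estimable (protein, contrast): `log2fc`, `se`, `df`, `t`,
#'   `p_value`, `adj_p_value`.
#' @export
test_differential <- function(summaries, contrasts,
                              design = c("group", "condition-time")) {
  design <- match.arg(design)
  tab <- if (inherits(summaries, "protein_summaries")) {
    summaries$summaries
  } else {
    summaries
  }
  if (is.numeric(contrasts)) contrasts <- list(contrast = contrasts)
  if (length(contrasts) == 0L) {
    out <- empty_result()
    out$adj_p_value <- numeric(0)
    class(out) <- c("differential_results", class(out))
    return(out)
  }
  results <- tab |>
    dplyr::group_by(.data$protein) |>
    dplyr::group_split() |>
    purrr::map_dfr(function(prot_tab) {
      fit <- tryCatch(
        fit_protein_model(dplyr::mutate(prot_tab, protein = prot_tab$protein[[1L]]),
          design = design
        ),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        return(empty_result())
      }
      purrr::imap_dfr(contrasts, function(ctr, lbl) {
        test_contrast(fit, ctr, label = lbl)
      })
    })
  if (nrow(results) > 0L) {
    results <- results |>
      dplyr::group_by(.data$contrast) |>
      dplyr::mutate(adj_p_value = adjust_fdr(.data$p_value)) |>
      dplyr::ungroup()
  } else {
    results$adj_p_value <- numeric(0)
  }
  class(results) <- c("differential_results", class(results))
  results
}

#' @describeIn test_differential Volcano plot of the test results.
#' @param object A `differential_results` tibble.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.differential_results <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = .data$log2fc, y = -log10(pmax(.data$p_value, 1e-300)),
      colour = .data$adj_p_value < 0.05
    )
  ) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~contrast) +
    ggplot2::labs(
      x = "log2 fold change", y = "-log10 p-value",
      colour = "adj. p < 0.05"
    ) +
    ggplot2::theme_minimal()
}

#' Compare summarization methods on the same data
#'
#' Runs the weighted, unique-only and all-peptides summarizations on the
#' same feature table, applies identical downstream modeling and
#' testing, and returns the side-by-side results. Proteins for which a
#' method is infeasible (e.g. no unique peptides for the unique-only
#' method) are simply absent from that method's rows.
#'
#' @inheritParams summarize_proteins
#' @inheritParams test_differential
#' @param methods Methods to compare.
#' @return A `differential_results` tibble with an extra `method`
#'   column.
#' @export
compare_summarization_methods <- function(features, contrasts,
                                          config = huber_config(),
                                          design = c("group", "condition-time"),
                                          methods = c("weighted", "unique", "all"),
                                          keep_subset = FALSE) {
  design <- match.arg(design)
  out <- purrr::map_dfr(methods, function(m) {
    summ <- summarize_proteins(features,
      method = m, config = config,
      keep_subset = keep_subset
    )
    res <- test_differential(summ, contrasts, design = design)
    dplyr::mutate(res, method = m)
  })
  class(out) <- c("differential_results", class(tibble::tibble()))
  out
}
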