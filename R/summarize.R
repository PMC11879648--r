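#' Restrict features to a cluster assignment
#'
#' Joins a feature table with a (possibly merged and filtered)
#' `cluster_assignment`: features absent from the assignment are dropped,
#' the `protein` list column is replaced by the retained membership sets,
#' and a `cluster` column is added.
#'
#' @param features Canonical feature tibble.
#' @param clusters A `cluster_assignment` (see [find_clusters()]).
#' @return The filtered feature tibble with updated membership.
#' @export
apply_cluster_assignment <- function(features, clusters) {
  assert_feature_table(features)
  assert_cluster_assignment(clusters)
  mem <- clusters |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(
      cluster = .data$cluster[[1L]],
      protein = list(sort(unique(.data$protein))),
      .groups = "drop"
    )
  features |>
    dplyr::select(-"protein") |>
    dplyr::inner_join(mem, by = "feature_id") |>
    dplyr::relocate("protein")
}

#' Summarize feature intensities to protein-level abundances
#'
#' End-to-end summarization: builds the peptide-protein graph, partitions
#' it into clusters, optionally merges indistinguishable proteins and
#' removes subset proteins, and then summarizes each cluster and mixture
#' with the requested method:
#'
#' * `"weighted"`: the weighted cluster model fitted by alternating
#'   convex search under the configured robust loss
#'   ([fit_weighted_model()]). Trivial single-protein clusters use the
#'   median-polish baseline.
#' * `"unique"`: per-protein median polish on unique features only
#'   (exclusion); proteins without unique features yield no summary.
#' * `"all"`: per-protein median polish on all matching features as if
#'   they were unique (naive inclusion).
#'
#' @param features Canonical feature tibble (see [read_feature_table()]).
#' @param method Summarization method, see above.
#' @param config A [huber_config()] (weighted method only).
#' @param keep_subset Retain proteins identified by shared peptides only
#'   (see [filter_shared_only()]).
#' @param merge Merge proteins identified by identical peptide sets
#'   (see [merge_indistinguishable()]).
#' @param update_weights Weighted method only: if `FALSE`, hold weights
#'   at the uniform inclusion values.
#' @return A `protein_summaries` object: list with `summaries` (tibble
#'   of protein, mixture, channel, condition, bio_replicate, cluster,
#'   abundance), `weights` (tibble of estimated peptide-protein weights,
#'   weighted method only), `convergence` (one row per cluster and
#'   mixture) and `method`.
#' @export
summarize_proteins <- function(features,
                               method = c("weighted", "unique", "all"),
                               config = huber_config(),
                               keep_subset = FALSE,
                               merge = TRUE,
                               update_weights = TRUE) {
  method <- match.arg(method)
  assert_feature_table(features)
  clusters <- find_clusters(build_graph(features))
  if (merge) clusters <- merge_indistinguishable(clusters)
  clusters <- filter_shared_only(clusters, keep_subset = keep_subset)
  if (nrow(clusters) == 0L) {
    abort("summarize_proteins: no quantifiable protein after filtering.")
  }
  dat <- apply_cluster_assignment(features, clusters)
  summarize_assigned(dat, method, config, update_weights)
}

# summarization over an already cluster-assigned feature table
summarize_assigned <- function(dat, method, config = huber_config(),
                               update_weights = TRUE) {
  pieces <- dat |>
    dplyr::group_by(.data$cluster, .data$mixture) |>
    dplyr::group_split()
  fits <- purrr::map(pieces, function(piece) {
    summarize_one(piece, method, config, update_weights)
  })
  out <- structure(
    list(
      summaries = purrr::map_dfr(fits, "summaries"),
      weights = purrr::map_dfr(fits, "weights"),
      convergence = purrr::map_dfr(fits, "convergence"),
      method = method
    ),
    class = "protein_summaries"
  )
  out
}

summarize_one <- function(piece, method, config, update_weights) {
  cluster_id <- piece$cluster[[1L]]
  mixture_id <- piece$mixture[[1L]]
  meta <- piece |>
    dplyr::distinct(.data$channel, .data$condition, .data$bio_replicate)
  proteins <- sort(unique(unlist(piece$protein)))
  n_prot <- length(proteins)

  if (method == "weighted" && n_prot > 1L) {
    fit <- fit_weighted_model(piece, config, update_weights = update_weights)
    summaries <- extract_summaries(fit) |>
      dplyr::mutate(cluster = cluster_id)
    weights <- tidy(fit) |>
      dplyr::mutate(cluster = cluster_id, mixture = mixture_id)
    convergence <- glance(fit) |>
      dplyr::mutate(cluster = cluster_id, mixture = mixture_id)
    return(list(summaries = summaries, weights = weights, convergence = convergence))
  }

  per_protein <- purrr::map_dfr(proteins, function(p) {
    rows <- switch(method,
      weighted = , # trivial cluster: baseline on all (necessarily unique) rows
      all = piece[purrr::map_lgl(piece$protein, ~ p %in% .x), , drop = FALSE],
      unique = piece[purrr::map_lgl(piece$protein, ~ identical(.x, p)), ,
        drop = FALSE
      ]
    )
    if (nrow(rows) == 0L || all(is.na(rows$log2_intensity))) {
      return(tibble::tibble())
    }
    tmp_summarize(rows) |>
      dplyr::mutate(protein = p, .before = 1L)
  })
  if (nrow(per_protein) == 0L) {
    return(list(
      summaries = tibble::tibble(), weights = tibble::tibble(),
      convergence = tibble::tibble()
    ))
  }
  summaries <- per_protein |>
    dplyr::mutate(mixture = mixture_id, cluster = cluster_id) |>
    dplyr::left_join(meta, by = "channel")
  list(
    summaries = summaries,
    weights = tibble::tibble(),
    convergence = tibble::tibble(
      n_proteins = n_prot,
      n_features = dplyr::n_distinct(piece$feature_id),
      converged = TRUE, n_iter = 1L, final_weight_change = 0,
      residual_scale = NA_real_, objective = NA_real_,
      unidentifiable = FALSE,
      cluster = cluster_id, mixture = mixture_id
    )
  )
}

#' @export
print.protein_summaries <- function(x, ...) {
  cat(sprintf(
    "<protein_summaries> method '%s': %d protein(s), %d mixture(s), %d summary rows\n",
    x$method,
    dplyr::n_distinct(x$summaries$protein),
    dplyr::n_distinct(x$summaries$mixture),
    nrow(x$summaries)
  ))
  invisible(x)
}

#' @describeIn summarize_proteins Summary tibble accessor.
#' @param x A `protein_summaries` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.protein_summaries <- function(x, ...) {
  x$summaries
}

#' @describeIn summarize_proteins Per-cluster convergence records.
#' @exportS3Method generics::glance
glance.protein_summaries <- function(x, ...) {
  x$convergence
}

#' @describeIn summarize_proteins Profile plot of the per-protein channel
#'   summaries (one line per protein, faceted by mixture).
#' @param object A `protein_summaries` object.
#' @exportS3Method ggplot2::autoplot
autoplot.protein_summaries <- function(object, ...) {
  dat <- object$summaries |>
    dplyr::mutate(channel = factor(.data$channel, levels = sort_channels(unique(.data$channel))))
  ggplot2::ggplot(
    dat,
    ggplot2::aes(
      x = .data$channel, y = .data$abundance,
      colour = .data$protein, group = .data$protein
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~mixture) +
    ggplot2::labs(
      x = "channel", y = "log2 abundance",
      title = sprintf("Protein summaries (%s)", object$method)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn extract_summaries Weight profile plot: estimated
#'   peptide-protein weights of the shared features.
#' @param object A `cluster_fit`.
#' @exportS3Method ggplot2::autoplot
autoplot.cluster_fit <- function(object, ...) {
  w <- tidy(object) |>
    dplyr::filter(!.data$is_unique)
  ggplot2::ggplot(
    w,
    ggplot2::aes(x = .data$protein, y = .data$feature_id, fill = .data$weight)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue", limits = c(0, 1)) +
    ggplot2::labs(
      x = "protein", y = "shared feature",
      title = "Estimated peptide-protein weights"
    ) +
    ggplot2::theme_minimal()
}
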