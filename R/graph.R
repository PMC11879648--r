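#' Build the peptide-protein bipartite graph
#'
#' One node per distinct feature (peptide ion) and per protein accession,
#' with an edge wherever the feature's sequence matches the protein.
#' Duplicate rows of the same feature (different channels or mixtures)
#' contribute a single feature node.
#'
#' @param features Canonical feature tibble (see [read_feature_table()]).
#' @return A `peptide_protein_graph` object: a list with `edges` (tibble
#'   of `feature_id`, `protein`), `proteins` and `features` (character
#'   vectors of node labels).
#' @export
build_graph <- function(features) {
  assert_feature_table(features)
  if (nrow(features) == 0L) {
    abort("build_graph: empty feature table.")
  }
  edges <- features |>
    dplyr::distinct(.data$feature_id, .data$protein) |>
    tidyr::unnest_longer("protein") |>
    dplyr::distinct(.data$feature_id, .data$protein) |>
    dplyr::arrange(.data$feature_id, .data$protein)
  structure(
    list(
      edges = edges,
      proteins = sort(unique(edges$protein)),
      features = sort(unique(edges$feature_id))
    ),
    class = "peptide_protein_graph"
  )
}

#' @export
print.peptide_protein_graph <- function(x, ...) {
  cat(sprintf(
    "<peptide_protein_graph> %d proteins, %d features, %d edges\n",
    length(x$proteins), length(x$features), nrow(x$edges)
  ))
  invisible(x)
}

#' Partition the peptide-protein graph into protein clusters
#'
#' Protein clusters are the connected components of the bipartite graph:
#' groups of proteins linked (possibly transitively) by shared peptides,
#' together with all their features. Proteins that share no peptide with
#' any other protein form trivial single-protein clusters.
#'
#' @param graph A `peptide_protein_graph` from [build_graph()].
#' @return A `cluster_assignment` tibble with one row per
#'   (feature, protein) edge and columns `cluster` (integer id, ordered
#'   by the lexicographically first protein of the cluster), `feature_id`,
#'   `protein`, and `is_unique` (does the feature match exactly one
#'   protein?).
#' @export
find_clusters <- function(graph) {
  if (!inherits(graph, "peptide_protein_graph")) {
    abort("`graph` must be a peptide_protein_graph (see build_graph()).")
  }
  g <- igraph::graph_from_data_frame(
    graph$edges |>
      dplyr::transmute(
        from = paste0("f:", .data$feature_id),
        to = paste0("p:", .data$protein)
      ),
    directed = FALSE
  )
  comp <- igraph::components(g)$membership
  edges <- graph$edges
  edges$cluster <- unname(comp[paste0("p:", edges$protein)])
  # deterministic cluster ids: order components by their first protein
  first_protein <- edges |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(p0 = min(.data$protein), .groups = "drop") |>
    dplyr::arrange(.data$p0)
  edges$cluster <- match(edges$cluster, first_protein$cluster)
  as_cluster_assignment(edges)
}

# recompute is_unique flags and row order; tag the class
as_cluster_assignment <- function(edges) {
  out <- edges |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::mutate(is_unique = dplyr::n() == 1L) |>
    dplyr::ungroup() |>
    dplyr::select("cluster", "feature_id", "protein", "is_unique") |>
    dplyr::arrange(.data$cluster, .data$protein, .data$feature_id)
  class(out) <- c("cluster_assignment", class(tibble::tibble()))
  out
}

#' Merge proteins identified by the same set of peptides
#'
#' Proteins within a cluster whose incident feature sets are identical
#' cannot be distinguished by the data; they are replaced by a single
#' merged protein whose label is the `";"`-joined sorted accessions.
#' Feature-cluster assignments are unchanged.
#'
#' @param clusters A `cluster_assignment` from [find_clusters()].
#' @return A `cluster_assignment` with merged protein labels.
#' @export
merge_indistinguishable <- function(clusters) {
  assert_cluster_assignment(clusters)
  merged <- clusters |>
    dplyr::group_by(.data$cluster, .data$protein) |>
    dplyr::summarise(
      fset = paste(sort(.data$feature_id), collapse = "\r"),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$cluster, .data$fset) |>
    dplyr::mutate(merged_label = paste(sort(.data$protein), collapse = ";")) |>
    dplyr::ungroup() |>
    dplyr::select("cluster", "protein", "merged_label")
  n_merged <- sum(merged$protein != merged$merged_label)
  if (n_merged > 0L) {
    inform(sprintf(
      "merge_indistinguishable: merged %d protein label(s) into %d group label(s).",
      n_merged, length(unique(merged$merged_label[merged$protein != merged$merged_label]))
    ))
  }
  clusters |>
    dplyr::left_join(merged, by = c("cluster", "protein")) |>
    dplyr::mutate(protein = .data$merged_label) |>
    dplyr::select(-"merged_label") |>
    dplyr::distinct(.data$cluster, .data$feature_id, .data$protein) |>
    as_cluster_assignment()
}

#' Remove proteins identified by shared peptides only
#'
#' Subset proteins -- proteins with no unique feature -- cannot be
#' quantified on their own evidence. With `keep_subset = FALSE` they are
#' removed and feature membership is recomputed; because removing a
#' protein can turn a shared feature into a unique one (and thereby
#' change another protein's status), the removal iterates to a fixed
#' point. Features losing all their proteins are dropped. At the fixed
#' point every remaining protein has at least one unique feature.
#'
#' @param clusters A `cluster_assignment` from [find_clusters()].
#' @param keep_subset If `TRUE`, return the input unchanged (retain
#'   subset proteins, as appropriate for designs where most clusters are
#'   heavily shared).
#' @param min_unique Optional stricter filter: in addition to the
#'   shared-only rule, drop proteins whose total feature count is below
#'   this value. Default 0 (off). This is a separate, explicit filter and
#'   is not applied iteratively.
#' @return A filtered `cluster_assignment`.
#' @export
filter_shared_only <- function(clusters, keep_subset = FALSE, min_unique = 0L) {
  assert_cluster_assignment(clusters)
  if (keep_subset) {
    return(clusters)
  }
  current <- clusters
  removed <- character(0)
  repeat {
    status <- current |>
      dplyr::group_by(.data$cluster, .data$protein) |>
      dplyr::summarise(has_unique = any(.data$is_unique), .groups = "drop")
    bad <- status$protein[!status$has_unique]
    if (length(bad) == 0L) {
      break
    }
    removed <- c(removed, bad)
    current <- current |>
      dplyr::filter(!.data$protein %in% bad) |>
      as_cluster_assignment()
    if (nrow(current) == 0L) {
      break
    }
  }
  if (length(removed) > 0L) {
    inform(sprintf(
      "filter_shared_only: removed %d subset protein(s): %s.",
      length(removed), paste(sort(removed), collapse = ", ")
    ))
  }
  if (min_unique > 0L && nrow(current) > 0L) {
    counts <- current |>
      dplyr::count(.data$protein, name = "n_feat")
    weak <- counts$protein[counts$n_feat < min_unique]
    if (length(weak) > 0L) {
      inform(sprintf(
        "filter_shared_only: removed %d protein(s) with fewer than %d feature(s).",
        length(weak), min_unique
      ))
      current <- current |>
        dplyr::filter(!.data$protein %in% weak) |>
        as_cluster_assignment()
    }
  }
  current
}

#' Per-cluster size report
#'
#' @param clusters A `cluster_assignment`.
#' @return Tibble with one row per cluster: number of proteins
#'   (`n_proteins`), features (`n_features`) and shared features
#'   (`n_shared`).
#' @export
cluster_report <- function(clusters) {
  assert_cluster_assignment(clusters)
  clusters |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n_proteins = dplyr::n_distinct(.data$protein),
      n_features = dplyr::n_distinct(.data$feature_id),
      n_shared = dplyr::n_distinct(.data$feature_id[!.data$is_unique]),
      .groups = "drop"
    )
}

assert_cluster_assignment <- function(x) {
  if (!inherits(x, "cluster_assignment")) {
    abort("expected a cluster_assignment (see find_clusters()).")
  }
  invisible(x)
}
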