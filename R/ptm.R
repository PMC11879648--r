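#' Expand PTM site annotations into a site-level feature table
#'
#' Maps modified peptides to PTM sites so that the weighted cluster
#' model can be reused with sites in the role of proteins: a
#' singly-modified peptide is a unique feature of its site, and a
#' peptide carrying several modification sites is a shared feature of
#' all of them. No concatenated multi-site labels are created. Site
#' units are labeled `"<protein>/<site>"` (e.g. `"Q99999/S236"`), which
#' keeps site clusters within one protein by construction.
#'
#' @param features Canonical feature tibble of the modified peptides.
#' @param annotations Tibble with columns `feature_id`, `protein`
#'   (accession) and `sites` (character; `";"`-separated
#'   residue+position labels such as `"S236;S240"`, 1-based protein
#'   coordinates).
#' @return The feature tibble with the `protein` list column replaced by
#'   site-unit labels; feature rows without a site annotation are
#'   dropped with a message.
#' @export
expand_sites <- function(features, annotations) {
  assert_feature_table(features)
  required <- c("feature_id", "protein", "sites")
  if (!all(required %in% names(annotations))) {
    abort("`annotations` needs columns feature_id, protein, sites.")
  }
  site_map <- annotations |>
    dplyr::mutate(sites = stringr::str_split(.data$sites, stringr::fixed(";"))) |>
    tidyr::unnest_longer("sites") |>
    dplyr::filter(.data$sites != "") |>
    dplyr::mutate(site_ok = grepl("^[A-Z][0-9]+$", .data$sites))
  if (!all(site_map$site_ok)) {
    abort(sprintf(
      "Malformed site label(s): %s.",
      paste(unique(site_map$sites[!site_map$site_ok]), collapse = ", ")
    ))
  }
  site_map <- site_map |>
    dplyr::mutate(unit = paste(.data$protein, .data$sites, sep = "/")) |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(unit = list(sort(unique(.data$unit))), .groups = "drop")
  keep <- features$feature_id %in% site_map$feature_id
  if (any(!keep)) {
    inform(sprintf(
      "expand_sites: dropped %d feature row(s) without site annotation.",
      sum(!keep)
    ))
  }
  out <- features[keep, , drop = FALSE] |>
    dplyr::select(-"protein") |>
    dplyr::left_join(site_map, by = "feature_id") |>
    dplyr::rename(protein = "unit") |>
    dplyr::relocate("protein")
  out
}

#' Protein-abundance-adjusted differential PTM test
#'
#' Compares the change of a PTM site's abundance between conditions to
#' the change of the unmodified protein: the adjusted log2 fold change
#' is the difference of the two estimates, its standard error combines
#' both standard errors, and the degrees of freedom follow the
#' Satterthwaite approximation
#' \deqn{df = (se_{ptm}^2 + se_{prot}^2)^2 /
#'   (se_{ptm}^4/df_{ptm} + se_{prot}^4/df_{prot}).}
#'
#' @param ptm_results `differential_results` for the PTM site summaries
#'   (site unit labels of the form `"<protein>/<site>"`, as produced by
#'   [expand_sites()] + the standard pipeline).
#' @param protein_results `differential_results` for the corresponding
#'   unmodified-protein summaries (labeled by protein accession).
#' @return A `differential_results` tibble of adjusted site results with
#'   extra columns `protein_log2fc` and `adjusted` (`FALSE` when the
#'   protein result was missing and the unadjusted site result is
#'   returned, flagged via a message).
#' @export
adjusted_test <- function(ptm_results, protein_results) {
  ptm <- tibble::as_tibble(ptm_results) |>
    dplyr::mutate(accession = sub("/[^/]*$", "", .data$protein))
  prot <- tibble::as_tibble(protein_results) |>
    dplyr::select(
      accession = "protein", contrast = "contrast",
      prot_log2fc = "log2fc", prot_se = "se", prot_df = "df"
    )
  joined <- dplyr::left_join(ptm, prot, by = c("accession", "contrast"))
  n_missing <- sum(is.na(joined$prot_log2fc))
  if (n_missing > 0L) {
    inform(sprintf(
      "adjusted_test: %d site result(s) without a protein result; returned unadjusted.",
      n_missing
    ))
  }
  out <- joined
  out$adjusted <- !is.na(out$prot_log2fc)
  out$protein_log2fc <- out$prot_log2fc
  adj <- out$adjusted
  out$log2fc[adj] <- out$log2fc[adj] - out$prot_log2fc[adj]
  out$df[adj] <- satterthwaite_combine(
    out$se[adj], out$df[adj], out$prot_se[adj], out$prot_df[adj]
  )
  out$se[adj] <- sqrt(out$se[adj]^2 + out$prot_se[adj]^2)
  pos <- out$se > 0
  out$t[pos] <- out$log2fc[pos] / out$se[pos]
  out$p_value[pos] <- 2 * pt(-abs(out$t[pos]), df = out$df[pos])
  out <- out |>
    dplyr::select(-"prot_log2fc", -"prot_se", -"prot_df", -"accession")
  out$adj_p_value <- adjust_fdr_by_contrast(out)
  class(out) <- c("differential_results", class(tibble::tibble()))
  out
}

satterthwaite_combine <- function(se1, df1, se2, df2) {
  num <- (se1^2 + se2^2)^2
  den <- se1^4 / df1 + se2^4 / df2
  ifelse(den > 0, num / den, df1)
}

adjust_fdr_by_contrast <- function(results) {
  if (nrow(results) == 0L) {
    return(numeric(0))
  }
  stats::ave(results$p_value, results$contrast,
    FUN = function(p) p.adjust(p, method = "BH")
  )
}
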