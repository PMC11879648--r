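#' Read a feature-level quantification table
#'
#' Reads a delimited text file of feature-level TMT intensities in the
#' conventional wide-per-row format (one row per feature ion and channel)
#' with columns ProteinName, PeptideSequence, Charge (or PSM), Mixture,
#' Run, Channel, Condition, BioReplicate and Intensity, and returns the
#' canonical feature tibble used throughout the package.
#'
#' Raw intensities are log2-transformed. Rows with a missing, zero or
#' negative intensity are retained with `log2_intensity = NA` (the model
#' is defined on the log2 scale, where such values are undefined; fits
#' simply ignore missing cells). The protein field may list several
#' accessions separated by `protein_sep`; it is parsed into a list column
#' of accession vectors. Feature identity is the peptide sequence
#' concatenated with the charge state.
#'
#' @param path Path to a CSV/TSV file (delimiter guessed from the
#'   extension unless `delim` is given).
#' @param dialect Named character vector mapping canonical column names
#'   (`protein`, `peptide`, `charge`, `mixture`, `channel`, `condition`,
#'   `bio_replicate`, `intensity`) to the column names used in the file.
#'   Defaults cover the conventional spelling.
#' @param protein_sep Delimiter separating accessions within the protein
#'   field. Default `";"`.
#' @param delim Field delimiter; `NULL` (default) guesses from the file
#'   extension (`.csv` vs anything else = tab).
#' @return A tibble with columns `protein` (list of character vectors),
#'   `peptide`, `feature_id`, `mixture`, `channel`, `condition`,
#'   `bio_replicate`, `log2_intensity`.
#' @export
read_feature_table <- function(path,
                               dialect = NULL,
                               protein_sep = ";",
                               delim = NULL) {
  defaults <- c(
    protein = "ProteinName", peptide = "PeptideSequence",
    charge = "Charge", mixture = "Mixture", channel = "Channel",
    condition = "Condition", bio_replicate = "BioReplicate",
    intensity = "Intensity"
  )
  dialect <- utils::modifyList(as.list(defaults), as.list(dialect %||% list()))
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (nrow(raw) == 0L) {
    abort(sprintf("Feature table '%s' contains no rows.", path))
  }
  required <- c(
    "protein", "peptide", "mixture", "channel",
    "condition", "bio_replicate", "intensity"
  )
  for (key in required) {
    if (!dialect[[key]] %in% names(raw)) {
      abort(sprintf(
        "Feature table '%s' is missing required column '%s' (mapped from '%s').",
        path, dialect[[key]], key
      ))
    }
  }
  charge <- if (dialect$charge %in% names(raw)) raw[[dialect$charge]] else "1"
  intensity <- suppressWarnings(as.numeric(raw[[dialect$intensity]]))
  peptide <- raw[[dialect$peptide]]
  tibble::tibble(
    protein = stringr::str_split(raw[[dialect$protein]], stringr::fixed(protein_sep)),
    peptide = peptide,
    feature_id = paste(peptide, charge, sep = "_"),
    mixture = raw[[dialect$mixture]],
    channel = raw[[dialect$channel]],
    condition = raw[[dialect$condition]],
    bio_replicate = raw[[dialect$bio_replicate]],
    log2_intensity = ifelse(is.na(intensity) | intensity <= 0, NA_real_,
      log2(intensity)
    )
  )
}

#' Write and re-read protein summary tables
#'
#' `write_summaries()` writes the channel-level protein summaries of a
#' [summarize_proteins()] result as a delimited text file (one row per
#' protein, mixture and channel), together with companion files holding
#' the estimated peptide-protein weights (`<path>_weights.<ext>`) and the
#' per-cluster convergence record (`<path>_convergence.<ext>`).
#' `read_summaries()` reads the main table back.
#'
#' @param summaries A `protein_summaries` object from
#'   [summarize_proteins()], or a tibble shaped like its `summaries`
#'   element.
#' @param path Output path; extension decides the delimiter (`.csv` =
#'   comma, otherwise tab).
#' @return `write_summaries()` returns `path` invisibly;
#'   `read_summaries()` returns a summary tibble.
#' @export
write_summaries <- function(summaries, path) {
  tab <- if (inherits(summaries, "protein_summaries")) {
    summaries$summaries
  } else {
    summaries
  }
  writer <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv
  } else {
    readr::write_tsv
  }
  writer(tab, path)
  if (inherits(summaries, "protein_summaries")) {
    writer(summaries$weights, companion_path(path, "weights"))
    writer(summaries$convergence, companion_path(path, "convergence"))
  }
  invisible(path)
}

#' @rdname write_summaries
#' @export
read_summaries <- function(path) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  out <- reader(path, show_col_types = FALSE, progress = FALSE)
  for (col in intersect(
    c("protein", "mixture", "channel", "condition", "bio_replicate"),
    names(out)
  )) {
    out[[col]] <- as.character(out[[col]])
  }
  out
}

companion_path <- function(path, suffix) {
  ext <- tools::file_ext(path)
  base <- sub(sprintf("\\.%s$", ext), "", path)
  sprintf("%s_%s.%s", base, suffix, ext)
}

#' Optional median centering against a reference channel
#'
#' Between-mixture normalization is deliberately off by default: the
#' summarization model itself makes no between-mixture adjustment. When a
#' dedicated reference channel is present in every mixture, this helper
#' subtracts from each mixture the median log2 intensity of its reference
#' channel (bringing reference channels to a common zero median).
#'
#' @param features Canonical feature tibble.
#' @param reference_channel Channel label of the reference channel.
#' @return The feature tibble with shifted `log2_intensity`.
#' @export
normalize_reference_channel <- function(features, reference_channel) {
  assert_feature_table(features)
  shifts <- features |>
    dplyr::filter(.data$channel == reference_channel) |>
    dplyr::group_by(.data$mixture) |>
    dplyr::summarise(
      shift = median(.data$log2_intensity, na.rm = TRUE),
      .groups = "drop"
    )
  missing_mix <- setdiff(unique(features$mixture), shifts$mixture)
  if (length(missing_mix) > 0) {
    abort(sprintf(
      "Reference channel '%s' absent from mixture(s): %s.",
      reference_channel, paste(missing_mix, collapse = ", ")
    ))
  }
  features |>
    dplyr::left_join(shifts, by = "mixture") |>
    dplyr::mutate(log2_intensity = .data$log2_intensity - .data$shift) |>
    dplyr::select(-"shift")
}
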