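#' Read a protein FASTA database
#'
#' Loads a FASTA file of protein sequences into a named character vector
#' (accession -> amino-acid sequence). The accession is the first
#' whitespace-delimited token of the header; UniProt-style
#' `db|ACCESSION|NAME` headers are reduced to the accession.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase amino-acid sequences.
#' @export
read_fasta_db <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("read_fasta_db() requires the Biostrings package.")
  }
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) {
    abort(sprintf("FASTA file '%s' contains no sequences.", path))
  }
  acc <- vapply(
    strsplit(names(seqs), "\\s+"),
    function(x) x[[1L]], character(1)
  )
  uniprot <- grepl("^[a-z]{2}\\|[^|]+\\|", acc)
  acc[uniprot] <- vapply(
    strsplit(acc[uniprot], "|", fixed = TRUE),
    function(x) x[[2L]], character(1)
  )
  if (anyDuplicated(acc)) {
    abort("FASTA accessions must be unique.")
  }
  setNames(toupper(as.character(seqs)), acc)
}

#' Re-annotate peptides against a protein database
#'
#' Replaces each feature's protein membership by the full set of database
#' accessions whose sequence contains the peptide sequence as a
#' contiguous substring. Modified-residue annotations in the peptide
#' string (anything that is not an uppercase letter, e.g. `"S[+80]"` or
#' lowercase letters) are stripped before matching. Features whose
#' peptide matches no protein are dropped, with the count reported via
#' `message()`.
#'
#' The operation is idempotent: annotating an already annotated table
#' against the same database gives the same result.
#'
#' @param features Canonical feature tibble (see [read_feature_table()]).
#' @param db Named character vector of protein sequences, e.g. from
#'   [read_fasta_db()].
#' @return The feature tibble with the `protein` list column replaced.
#' @export
annotate_peptides <- function(features, db) {
  assert_feature_table(features)
  if (length(db) == 0L) {
    abort("`db` must contain at least one protein sequence.")
  }
  db <- toupper(db)
  peptides <- unique(features$peptide)
  stripped <- stringr::str_remove_all(peptides, "[^A-Z]")
  matches <- lapply(stripped, function(pep) {
    names(db)[stringr::str_detect(db, stringr::fixed(pep))]
  })
  names(matches) <- peptides
  hits <- matches[features$peptide]
  keep <- lengths(hits) > 0L
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    inform(sprintf(
      "annotate_peptides: dropped %d feature row(s) (%d peptide(s)) matching no protein.",
      n_dropped, length(unique(features$peptide[!keep]))
    ))
  }
  out <- features[keep, , drop = FALSE]
  out$protein <- unname(hits[keep])
  out
}
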