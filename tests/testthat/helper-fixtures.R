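# Programmatic fixtures: canonical feature tibbles built from compact
# topology descriptions, plus the classic two-cluster example layout.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Build a canonical feature tibble from an intensity matrix and a
# membership map. `membership` is a named list: feature_id -> character
# vector of proteins. Channels get round-robin conditions unless given.
make_features <- function(x, membership, mixture = "mix1",
                          conditions = NULL, bio_replicates = NULL) {
  stopifnot(nrow(x) == length(membership))
  channels <- colnames(x) %||% sprintf("ch%02d", seq_len(ncol(x)))
  feature_ids <- rownames(x) %||% names(membership)
  conditions <- conditions %||% sprintf("cond%d", seq_len(ncol(x)))
  bio_replicates <- bio_replicates %||% rep("rep1", ncol(x))
  tibble::tibble(
    protein = rep(unname(membership), each = ncol(x)),
    peptide = rep(feature_ids, each = ncol(x)),
    feature_id = rep(feature_ids, each = ncol(x)),
    mixture = mixture,
    channel = rep(channels, length(feature_ids)),
    condition = rep(conditions, length(feature_ids)),
    bio_replicate = rep(bio_replicates, length(feature_ids)),
    log2_intensity = as.vector(t(x))
  )
}

# Two-cluster example topology: proteins A and B share peptides 3 and 4
# (both also have unique peptides); C and D share peptides 7 and 8 but
# only D has a unique peptide (9).
example_two_cluster_membership <- function() {
  list(
    pep1 = "A", pep2 = "A", pep3 = c("A", "B"), pep4 = c("A", "B"),
    pep5 = "B", pep6 = "B",
    pep7 = c("C", "D"), pep8 = c("C", "D"), pep9 = "D"
  )
}

example_two_cluster_features <- function(n_channels = 3, seed = 42) {
  set.seed(seed)
  mem <- example_two_cluster_membership()
  x <- matrix(rnorm(length(mem) * n_channels, mean = 10),
    nrow = length(mem),
    dimnames = list(names(mem), sprintf("ch%02d", seq_len(n_channels)))
  )
  make_features(x, mem)
}

# Small 2-protein cluster generated exactly from the weighted model:
# distinct channel profiles, configurable true weights for the shared
# features and additive feature effects drawn in canonical position.
two_protein_cluster <- function(seed = 1, n_unique = 2, n_shared = 4,
                                C = 8, noise_sd = 0, shared_to = NULL) {
  cfg <- simulation_config(
    n_proteins = 2, n_unique_per_protein = n_unique,
    n_shared_per_pair = n_shared, n_conditions = C / 2, n_bioreps = 2,
    noise_sd = noise_sd, feature_sd = 0.5
  )
  simulate_cluster(cfg, seed = seed)
}
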