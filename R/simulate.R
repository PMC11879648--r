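#' Configuration of the synthetic cluster generator
#'
#' Defines the study conditions of the simulation benchmark: a cluster
#' of `n_proteins` proteins in which every pair of proteins shares
#' `n_shared_per_pair` peptides, each protein additionally has
#' `n_unique_per_protein` unique peptides, and the experiment profiles
#' `n_conditions` conditions with `n_bioreps` biological replicates per
#' condition, one channel per (condition, replicate), in a single TMT
#' mixture.
#'
#' Protein-level channel values are built deterministically from the
#' per-protein condition means (`true_log2fc`, relative to the first
#' condition as reference), plus an optional replicate-level normal
#' error (`biorep_sd`, 0 by default). Feature-level log2 intensities add
#' a drawn feature effect (normal sd `feature_sd`, centered), the
#' convex-combination of protein values under the true weights, and
#' i.i.d. normal noise with sd `noise_sd`.
#'
#' @param n_proteins,n_unique_per_protein,n_shared_per_pair,n_conditions,n_bioreps
#'   Cluster and design sizes. Defaults: 5 proteins, 2 unique peptides
#'   per protein, 5 shared peptides per protein pair, 5 conditions, 2
#'   biological replicates.
#' @param true_log2fc Matrix `n_proteins x n_conditions` of true log2
#'   fold changes versus the first (reference) condition; first column
#'   must be zero. The default makes proteins 1-3 differentially
#'   abundant with effects `(0.5, 1, 1.5, 2)` over conditions 2-5
#'   (signs +, -, + respectively) and proteins 4-5 null.
#' @param noise_sd Feature-level error sd (log2 units), default 0.2.
#' @param feature_sd Sd of the drawn feature effects, default 0.5.
#' @param biorep_sd Optional replicate-level protein error sd, default 0.
#' @param true_weights Rule for the true weights of shared peptides:
#'   `"alternating"` (default; each shared peptide belongs wholly to one
#'   protein of its pair, alternating), `"uniform"` (half/half), or
#'   `"random"` (uniform draw on the simplex edge).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_proteins = 5L,
                              n_unique_per_protein = 2L,
                              n_shared_per_pair = 5L,
                              n_conditions = 5L,
                              n_bioreps = 2L,
                              true_log2fc = NULL,
                              noise_sd = 0.2,
                              feature_sd = 0.5,
                              biorep_sd = 0,
                              true_weights = c("alternating", "uniform", "random")) {
  true_weights <- match.arg(true_weights)
  if (min(n_proteins, n_unique_per_protein, n_shared_per_pair,
    n_conditions, n_bioreps
  ) < 1L) {
    abort("all simulation counts must be positive.")
  }
  if (noise_sd < 0 || feature_sd < 0 || biorep_sd < 0) {
    abort("simulation standard deviations must be non-negative.")
  }
  if (is.null(true_log2fc)) {
    true_log2fc <- matrix(0, n_proteins, n_conditions)
    effects <- seq(0.5, 2, length.out = max(n_conditions - 1L, 1L))
    signs <- c(1, -1, 1)
    for (k in seq_len(min(3L, n_proteins))) {
      true_log2fc[k, -1L] <- signs[[k]] * effects
    }
  }
  true_log2fc <- as.matrix(true_log2fc)
  if (!all(dim(true_log2fc) == c(n_proteins, n_conditions))) {
    abort("`true_log2fc` must be n_proteins x n_conditions.")
  }
  if (any(true_log2fc[, 1L] != 0)) {
    abort("first column of `true_log2fc` is the reference and must be zero.")
  }
  structure(
    list(
      n_proteins = as.integer(n_proteins),
      n_unique_per_protein = as.integer(n_unique_per_protein),
      n_shared_per_pair = as.integer(n_shared_per_pair),
      n_conditions = as.integer(n_conditions),
      n_bioreps = as.integer(n_bioreps),
      true_log2fc = true_log2fc,
      noise_sd = noise_sd,
      feature_sd = feature_sd,
      biorep_sd = biorep_sd,
      true_weights = true_weights
    ),
    class = "simulation_config"
  )
}

#' Simulate one synthetic protein cluster with known ground truth
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; the generated table is deterministic given
#'   `(config, seed)`.
#' @return A list of class `sim_cluster`: `features` (canonical feature
#'   tibble) and `truth` (generating parameters: protein base
#'   abundances, channel layout, `true_log2fc`, feature effects and the
#'   true weight matrix).
#' @export
simulate_cluster <- function(config = simulation_config(), seed = 1L) {
  if (!inherits(config, "simulation_config")) {
    abort("`config` must be a simulation_config().")
  }
  set.seed(as.integer(seed))
  K <- config$n_proteins
  G <- config$n_conditions
  B <- config$n_bioreps
  C <- G * B
  proteins <- sprintf("P%02d", seq_len(K))
  layout <- tibble::tibble(
    channel = sprintf("ch%02d", seq_len(C)),
    condition = rep(sprintf("cond%d", seq_len(G)), each = B),
    bio_replicate = rep(sprintf("rep%d", seq_len(B)), times = G)
  )

  base <- rnorm(K, mean = 10, sd = 1)
  # protein-level channel values: condition means (+ optional biorep error)
  truth_mat <- matrix(NA_real_, K, C, dimnames = list(proteins, layout$channel))
  cond_idx <- rep(seq_len(G), each = B)
  for (k in seq_len(K)) {
    truth_mat[k, ] <- base[k] + config$true_log2fc[k, cond_idx]
  }
  if (config$biorep_sd > 0) {
    truth_mat <- truth_mat + matrix(rnorm(K * C, sd = config$biorep_sd), K, C)
  }

  # feature roster: unique peptides per protein, shared per protein pair
  pairs <- if (K > 1L) utils::combn(K, 2L, simplify = FALSE) else list()
  rows <- list()
  fid <- 0L
  for (k in seq_len(K)) {
    for (u in seq_len(config$n_unique_per_protein)) {
      fid <- fid + 1L
      rows[[fid]] <- list(feature_id = sprintf("uniq_%s_%d", proteins[k], u), members = k)
    }
  }
  for (p in seq_along(pairs)) {
    for (s in seq_len(config$n_shared_per_pair)) {
      fid <- fid + 1L
      rows[[fid]] <- list(
        feature_id = sprintf("shared_%s_%s_%d", proteins[pairs[[p]][1L]], proteins[pairs[[p]][2L]], s),
        members = pairs[[p]]
      )
    }
  }
  F_ <- length(rows)
  W <- matrix(0, F_, K, dimnames = list(vapply(rows, `[[`, "", "feature_id"), proteins))
  for (f in seq_len(F_)) {
    mem <- rows[[f]]$members
    if (length(mem) == 1L) {
      W[f, mem] <- 1
    } else {
      W[f, mem] <- switch(config$true_weights,
        alternating = if (f %% 2L == 0L) c(1, 0) else c(0, 1),
        uniform = c(0.5, 0.5),
        random = {
          w1 <- stats::runif(1)
          c(w1, 1 - w1)
        }
      )
    }
  }
  # draw feature effects in the canonical (identifiable) position:
  # orthogonalized against the membership-weight columns, so the truth
  # record is the decomposition the fit identifies
  feature_effects <- rnorm(F_, sd = config$feature_sd)
  Z <- if (K > 1L) {
    S <- rbind(diag(K - 1L), rep(-1, K - 1L))
    cbind(1, W %*% S)
  } else {
    matrix(1, F_, 1L)
  }
  cf <- stats::lm.fit(Z, feature_effects)$coefficients
  cf[is.na(cf)] <- 0
  feature_effects <- drop(feature_effects - Z %*% cf)

  X <- W %*% truth_mat + feature_effects +
    matrix(rnorm(F_ * C, sd = config$noise_sd), F_, C)

  features <- tibble::tibble(
    feature_id = rep(rownames(W), each = C),
    channel = rep(layout$channel, times = F_),
    log2_intensity = as.vector(t(X))
  ) |>
    dplyr::left_join(layout, by = "channel") |>
    dplyr::mutate(
      protein = purrr::map(
        rep(seq_len(F_), each = C),
        function(f) proteins[rows[[f]]$members]
      ),
      peptide = rep(rownames(W), each = C),
      mixture = "mix1"
    ) |>
    dplyr::select(
      "protein", "peptide", "feature_id", "mixture", "channel",
      "condition", "bio_replicate", "log2_intensity"
    )

  structure(
    list(
      features = features,
      truth = list(
        config = config, seed = as.integer(seed),
        proteins = proteins, layout = layout, base = base,
        protein_channel = truth_mat,
        true_log2fc = config$true_log2fc,
        feature_effects = setNames(feature_effects, rownames(W)),
        weights = W
      )
    ),
    class = "sim_cluster"
  )
}

#' Run the simulation benchmark
#'
#' Simulates `n_replicates` independent clusters, summarizes each with
#' the requested methods, tests every protein for each non-reference
#' condition against the reference with the per-protein linear model,
#' and aggregates the evaluation metrics per method: mean-squared error
#' and bias of the estimated log2 fold changes against the ground
#' truth, and sensitivity/specificity of detection at unadjusted
#' p < `alpha` (truly changed pairs = nonzero true log2 fold change).
#'
#' @param config A [simulation_config()].
#' @param n_replicates Number of independent simulation instances.
#' @param methods Summarization methods to benchmark.
#' @param seed Master seed; replicate `i` uses `seed + i`, so all
#'   methods see identical data.
#' @param alpha Unadjusted p-value cutoff for detection (default 0.05).
#' @param huber A [huber_config()] for the weighted method.
#' @return A `benchmark_result` list: `metrics` (tibble per method:
#'   `mse`, `bias`, `sensitivity`, `specificity`, `n_tests`,
#'   `n_failed`), and `estimates` (per replicate, method, protein and
#'   contrast: estimated and true log2 fold change and p-value).
#' @export
run_benchmark <- function(config = simulation_config(),
                          n_replicates = 20L,
                          methods = c("weighted", "unique", "all"),
                          seed = 1L,
                          alpha = 0.05,
                          huber = huber_config()) {
  if (n_replicates < 1L) abort("need at least one replicate.")
  conditions <- sprintf("cond%d", seq_len(config$n_conditions))
  contrasts <- ref_contrasts(conditions, reference = conditions[[1L]])
  truth_tab <- tibble::tibble(
    protein = rep(sprintf("P%02d", seq_len(config$n_proteins)),
      times = config$n_conditions - 1L
    ),
    contrast = rep(names(contrasts), each = config$n_proteins),
    true_log2fc = as.vector(config$true_log2fc[, -1L])
  )

  estimates <- purrr::map_dfr(seq_len(n_replicates), function(i) {
    sim <- simulate_cluster(config, seed = as.integer(seed) + i)
    purrr::map_dfr(methods, function(m) {
      res <- tryCatch(
        {
          summ <- summarize_proteins(sim$features,
            method = m, config = huber,
            keep_subset = FALSE
          )
          test_differential(summ, contrasts)
        },
        error = function(e) NULL
      )
      if (is.null(res)) {
        return(tibble::tibble(
          replicate = i, method = m, failed = TRUE,
          protein = NA_character_, contrast = NA_character_,
          log2fc = NA_real_, p_value = NA_real_
        ))
      }
      res |>
        dplyr::transmute(
          replicate = i, method = m, failed = FALSE,
          protein = .data$protein, contrast = .data$contrast,
          log2fc = .data$log2fc, p_value = .data$p_value
        )
    })
  })

  scored <- estimates |>
    dplyr::filter(!.data$failed) |>
    dplyr::inner_join(truth_tab, by = c("protein", "contrast")) |>
    dplyr::mutate(
      error = .data$log2fc - .data$true_log2fc,
      changed = .data$true_log2fc != 0,
      detected = .data$p_value < alpha
    )
  metrics <- scored |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      mse = mean(.data$error^2),
      bias = mean(.data$error),
      sensitivity = mean(.data$detected[.data$changed]),
      specificity = mean(!.data$detected[!.data$changed]),
      n_tests = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      estimates |>
        dplyr::group_by(.data$method) |>
        dplyr::summarise(
          n_failed = dplyr::n_distinct(.data$replicate[.data$failed]),
          .groups = "drop"
        ),
      by = "method"
    )

  structure(
    list(
      metrics = metrics, estimates = scored, alpha = alpha,
      config = config, n_replicates = n_replicates, seed = as.integer(seed)
    ),
    class = "benchmark_result"
  )
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf(
    "<benchmark_result> %d replicate(s), alpha = %g\n",
    x$n_replicates, x$alpha
  ))
  print(x$metrics)
  invisible(x)
}

#' @describeIn run_benchmark Metric tibble accessor.
#' @param x A `benchmark_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.benchmark_result <- function(x, ...) {
  x$metrics
}

#' @describeIn run_benchmark Boxplots of estimated log2 fold changes per
#'   method against the true values.
#' @param object A `benchmark_result`.
#' @exportS3Method ggplot2::autoplot
autoplot.benchmark_result <- function(object, ...) {
  ggplot2::ggplot(
    object$estimates,
    ggplot2::aes(x = .data$method, y = .data$log2fc, fill = .data$method)
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(
      ggplot2::aes(yintercept = .data$true_log2fc),
      linetype = "dashed"
    ) +
    ggplot2::facet_grid(protein ~ contrast) +
    ggplot2::labs(y = "estimated log2 fold change") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Subsample unique peptides (resampling harness)
#'
#' Retains `n_unique` randomly chosen unique features per protein and
#' all shared features. When `include_noisy = TRUE`, one of the retained
#' unique features is drawn from the protein's "noisy pool": the three
#' unique features with the lowest average Pearson correlation (across
#' channels) to the protein's other unique features.
#'
#' @param features Canonical feature tibble.
#' @param n_unique Number of unique features to keep per protein.
#' @param include_noisy Force one retained unique feature to come from
#'   the noisy pool.
#' @param seed Integer seed; the subsample is deterministic given it.
#' @return The subsampled feature tibble.
#' @export
resample_unique <- function(features, n_unique, include_noisy = FALSE,
                            seed = 1L) {
  assert_feature_table(features)
  set.seed(as.integer(seed))
  uniq <- features |>
    dplyr::filter(lengths(.data$protein) == 1L) |>
    dplyr::mutate(protein_label = purrr::map_chr(.data$protein, 1L))
  shared_ids <- unique(features$feature_id[lengths(features$protein) > 1L])

  keep_ids <- uniq |>
    dplyr::distinct(.data$protein_label, .data$feature_id) |>
    dplyr::group_by(.data$protein_label) |>
    dplyr::group_split() |>
    purrr::map(function(tab) {
      p <- tab$protein_label[[1L]]
      ids <- tab$feature_id
      if (length(ids) < n_unique) {
        abort(sprintf(
          "protein '%s' has only %d unique feature(s); %d requested.",
          p, length(ids), n_unique
        ))
      }
      if (!include_noisy) {
        return(sample(ids, n_unique))
      }
      pool <- noisy_pool(uniq[uniq$protein_label == p, , drop = FALSE])
      noisy_pick <- sample(pool, 1L)
      rest <- sample(setdiff(ids, noisy_pick), n_unique - 1L)
      c(noisy_pick, rest)
    }) |>
    unlist()

  features |>
    dplyr::filter(.data$feature_id %in% c(keep_ids, shared_ids))
}

#' @describeIn resample_unique The noisy pool of one protein: unique
#'   features ranked by average Pearson correlation to the protein's
#'   other unique features (lowest 3 returned).
#' @param protein_features Feature tibble of one protein's unique
#'   features.
#' @param pool_size Number of features in the pool (default 3).
#' @export
noisy_pool <- function(protein_features, pool_size = 3L) {
  mat <- feature_matrix(protein_features)
  if (nrow(mat) <= pool_size) {
    return(rownames(mat))
  }
  cors <- suppressWarnings(cor(t(mat), use = "pairwise.complete.obs"))
  diag(cors) <- NA
  avg <- rowMeans(cors, na.rm = TRUE)
  names(sort(avg))[seq_len(pool_size)]
}

#' Mean-squared error of estimates against a reference
#'
#' Aggregates, per method, the squared deviation of per-instance log2
#' fold change estimates from a reference estimate (e.g. the one based
#' on all available unique peptides).
#'
#' @param estimates Tibble with columns `method`, `protein`, `contrast`,
#'   `log2fc` (one row per instance).
#' @param reference Tibble with columns `protein`, `contrast`, `log2fc`.
#' @return Tibble per method: `mse`, `n`, `n_missing` (estimates without
#'   a matching reference or with `NA`, excluded).
#' @export
mse_against_reference <- function(estimates, reference) {
  if (nrow(estimates) == 0L) abort("no estimates supplied.")
  joined <- estimates |>
    dplyr::left_join(
      reference |> dplyr::select("protein", "contrast", ref_log2fc = "log2fc"),
      by = c("protein", "contrast")
    )
  joined |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      mse = mean((.data$log2fc - .data$ref_log2fc)^2, na.rm = TRUE),
      n = sum(is.finite(.data$log2fc - .data$ref_log2fc)),
      n_missing = sum(!is.finite(.data$log2fc - .data$ref_log2fc)),
      .groups = "drop"
    )
}
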