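test_that("the default simulated cluster has the documented dimensions", {
  cfg <- simulation_config()
  sim <- simulate_cluster(cfg, seed = 1)
  feats <- sim$features
  n_feat <- dplyr::n_distinct(feats$feature_id)
  expect_equal(n_feat, 5 * 2 + choose(5, 2) * 5) # 10 unique + 50 shared
  expect_equal(nrow(feats), n_feat * 10) # 5 conditions x 2 bioreps
  expect_equal(dplyr::n_distinct(feats$condition), 5L)
  shared <- feats$feature_id[lengths(feats$protein) == 2L]
  expect_equal(dplyr::n_distinct(shared), 50L)
  # truth record is internally consistent
  expect_equal(dim(sim$truth$weights), c(60L, 5L))
  expect_true(all(abs(rowSums(sim$truth$weights) - 1) < 1e-12))
  expect_equal(sum(sim$truth$feature_effects), 0, tolerance = 1e-10)
})

test_that("simulation is deterministic given the seed", {
  cfg <- simulation_config()
  s1 <- simulate_cluster(cfg, seed = 33)
  s2 <- simulate_cluster(cfg, seed = 33)
  s3 <- simulate_cluster(cfg, seed = 34)
  expect_identical(s1$features, s2$features)
  expect_false(identical(s1$features$log2_intensity, s3$features$log2_intensity))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_proteins = 0), "positive")
  expect_error(simulation_config(noise_sd = -1), "non-negative")
  expect_error(
    simulation_config(true_log2fc = matrix(1, 5, 5)),
    "reference"
  )
})

test_that("fitting zero-noise simulated data recovers the true fold changes", {
  cfg <- simulation_config(
    n_proteins = 3, n_unique_per_protein = 2, n_shared_per_pair = 3,
    n_conditions = 3, n_bioreps = 2, noise_sd = 0
  )
  sim <- simulate_cluster(cfg, seed = 8)
  summ <- summarize_proteins(sim$features, method = "weighted",
    config = huber_config(weight_tol = 1e-6))
  res <- suppressWarnings(test_differential(summ, ref_contrasts(sprintf("cond%d", 1:3))))
  truth <- tibble::tibble(
    protein = rep(sprintf("P%02d", 1:3), 2),
    contrast = rep(c("cond2 vs cond1", "cond3 vs cond1"), each = 3),
    true_fc = c(cfg$true_log2fc[, 2], cfg$true_log2fc[, 3])
  )
  merged <- dplyr::inner_join(res, truth, by = c("protein", "contrast"))
  expect_equal(nrow(merged), 6L)
  expect_lt(max(abs(merged$log2fc - merged$true_fc)), 1e-6)
})

test_that("unique-peptide resampling keeps the requested counts", {
  cfg <- simulation_config(
    n_proteins = 3, n_unique_per_protein = 6, n_shared_per_pair = 2,
    n_conditions = 3, n_bioreps = 2
  )
  sim <- simulate_cluster(cfg, seed = 10)
  sub <- resample_unique(sim$features, n_unique = 2, seed = 99)
  counts <- sub |>
    dplyr::filter(lengths(protein) == 1L) |>
    dplyr::distinct(feature_id, protein) |>
    dplyr::mutate(protein = purrr::map_chr(protein, 1)) |>
    dplyr::count(protein)
  expect_true(all(counts$n == 2L))
  shared_before <- unique(sim$features$feature_id[lengths(sim$features$protein) > 1L])
  expect_true(all(shared_before %in% sub$feature_id))
  # identity when asking for everything
  all_sub <- resample_unique(sim$features, n_unique = 6, seed = 1)
  expect_setequal(unique(all_sub$feature_id), unique(sim$features$feature_id))
  # deterministic given seed
  expect_identical(
    resample_unique(sim$features, 2, seed = 7),
    resample_unique(sim$features, 2, seed = 7)
  )
  expect_error(resample_unique(sim$features, 10, seed = 1), "only")
})

test_that("a planted anticorrelated peptide always enters the noisy pool", {
  cfg <- simulation_config(
    n_proteins = 2, n_unique_per_protein = 6, n_shared_per_pair = 2,
    n_conditions = 4, n_bioreps = 2, noise_sd = 0.05
  )
  sim <- simulate_cluster(cfg, seed = 21)
  feats <- sim$features
  # invert one unique peptide of P01 around its mean
  target <- "uniq_P01_1"
  idx <- feats$feature_id == target
  vals <- feats$log2_intensity[idx]
  feats$log2_intensity[idx] <- 2 * mean(vals) - vals
  uniq_p1 <- feats[purrr::map_lgl(feats$protein, ~ identical(.x, "P01")), ]
  pool <- noisy_pool(uniq_p1)
  expect_true(target %in% pool)
  # correlation-ranking oracle: the planted peptide has the lowest
  # average correlation
  mat <- t(vapply(
    split(uniq_p1$log2_intensity, uniq_p1$feature_id),
    identity, numeric(8)
  ))
  cors <- cor(t(mat))
  diag(cors) <- NA
  expect_equal(names(which.min(rowMeans(cors, na.rm = TRUE))), target)
  # resampling with include_noisy always keeps a pool member
  for (s in 1:5) {
    sub <- resample_unique(feats, n_unique = 2, include_noisy = TRUE, seed = s)
    kept <- sub |>
      dplyr::filter(purrr::map_lgl(protein, ~ identical(.x, "P01"))) |>
      dplyr::distinct(feature_id)
    expect_true(any(kept$feature_id %in% pool))
  }
})

test_that("mse against a reference matches hand arithmetic", {
  ref <- tibble::tibble(
    protein = c("A", "B"), contrast = "c", log2fc = c(1, 2)
  )
  est <- tibble::tibble(
    method = rep(c("m1", "m2"), each = 2),
    protein = rep(c("A", "B"), 2),
    contrast = "c",
    log2fc = c(1, 2, 1.5, 2.5)
  )
  out <- mse_against_reference(est, ref)
  expect_equal(out$mse[out$method == "m1"], 0)
  expect_equal(out$mse[out$method == "m2"], 0.25)
  # missing estimates are excluded and counted
  est2 <- est
  est2$log2fc[[1]] <- NA
  out2 <- mse_against_reference(est2, ref)
  expect_equal(out2$n_missing[out2$method == "m1"], 1L)
  expect_equal(out2$mse[out2$method == "m1"], 0)
})

test_that("huge effects saturate sensitivity for every method", {
  fc <- matrix(0, 2, 2)
  fc[, 2] <- 3
  cfg <- simulation_config(
    n_proteins = 2, n_unique_per_protein = 2, n_shared_per_pair = 2,
    n_conditions = 2, n_bioreps = 3, noise_sd = 0.1,
    true_log2fc = fc
  )
  bench <- run_benchmark(cfg, n_replicates = 2, seed = 5)
  expect_true(all(tidy(bench)$sensitivity == 1))
  expect_equal(tidy(bench)$n_failed, rep(0L, 3))
})
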