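make_summaries <- function(values, conditions, mixtures = "m1",
                           protein = "P") {
  tibble::tibble(
    protein = protein,
    abundance = values,
    condition = conditions,
    mixture = mixtures,
    channel = sprintf("ch%02d", seq_along(values)),
    bio_replicate = as.character(seq_along(values))
  )
}

test_that("balanced two-group contrasts equal the classical pooled t-test", {
  set.seed(5)
  y1 <- rnorm(4, 10)
  y2 <- rnorm(4, 11)
  summ <- make_summaries(c(y1, y2), rep(c("ctrl", "trt"), each = 4))
  fit <- fit_protein_model(summ)
  res <- test_contrast(fit, c(trt = 1, ctrl = -1))
  tt <- t.test(y2, y1, var.equal = TRUE)
  expect_equal(res$log2fc, unname(diff(c(mean(y1), mean(y2)))), tolerance = 1e-10)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(res$df, unname(tt$parameter))
})

test_that("the closed-form two-sample example reproduces the t table", {
  # difference 1.0, per-group sd 0.1, n = 3 per group
  y <- c(0, 0.1, -0.1, 1.0, 1.1, 0.9)
  summ <- make_summaries(y, rep(c("a", "b"), each = 3))
  res <- test_contrast(fit_protein_model(summ), c(b = 1, a = -1))
  s_pooled <- sqrt((var(y[1:3]) + var(y[4:6])) / 2)
  t_expect <- 1.0 / (s_pooled * sqrt(2 / 3))
  expect_equal(res$t, t_expect, tolerance = 1e-10)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * pt(-abs(t_expect), 4), tolerance = 1e-12)
})

test_that("mixture blocking removes additive per-mixture offsets", {
  set.seed(8)
  base <- rnorm(6, 10)
  one <- make_summaries(base, rep(c("a", "b"), each = 3), mixtures = "m1")
  two <- make_summaries(base + 1.7, rep(c("a", "b"), each = 3), mixtures = "m2")
  summ <- dplyr::bind_rows(one, two)
  res <- test_contrast(fit_protein_model(summ), c(b = 1, a = -1))
  res1 <- test_contrast(fit_protein_model(one), c(b = 1, a = -1))
  expect_equal(res$log2fc, res1$log2fc, tolerance = 1e-10)
  # matrix least-squares oracle with explicit blocking
  X <- cbind(a = rep(c(1, 0), each = 3), b = rep(c(0, 1), each = 3))
  Xfull <- rbind(cbind(X, m2 = 0), cbind(X, m2 = 1))
  beta <- solve(crossprod(Xfull), crossprod(Xfull, summ$abundance))
  expect_equal(res$log2fc, unname(beta["b", 1] - beta["a", 1]), tolerance = 1e-10)
})

test_that("contrasts are antisymmetric and degenerate cases handled", {
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- suppressWarnings(fit_protein_model(make_summaries(y, rep(c("a", "b"), each = 3))))
  plus <- test_contrast(fit, c(b = 1, a = -1))
  minus <- test_contrast(fit, c(b = -1, a = 1))
  expect_equal(plus$log2fc, -minus$log2fc)
  expect_equal(plus$p_value, minus$p_value)
  # zero residual variance: flagged degenerate with extreme p
  expect_true(plus$degenerate)
  expect_equal(plus$p_value, 0)
  null_fit <- suppressWarnings(fit_protein_model(make_summaries(rep(2, 6), rep(c("a", "b"), each = 3))))
  null_res <- test_contrast(null_fit, c(b = 1, a = -1))
  expect_equal(null_res$log2fc, 0)
  expect_equal(null_res$p_value, 1)
  expect_error(test_contrast(fit, c(b = 1, a = -0.5)), "sum to zero")
})

test_that("benjamini-hochberg adjustment matches the hand-coded step-up", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(0.2), 0.2)
  set.seed(12)
  p <- sort(runif(20))
  expect_equal(adjust_fdr(p), oracle_bh(p))
  # order invariance
  perm <- sample(20)
  expect_equal(adjust_fdr(p[perm]), oracle_bh(p)[perm])
  expect_error(adjust_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("test_differential assembles per-protein results with BH per contrast", {
  cfg <- simulation_config(
    n_proteins = 3, n_unique_per_protein = 3, n_shared_per_pair = 2,
    n_conditions = 3, n_bioreps = 3, noise_sd = 0.1
  )
  sim <- simulate_cluster(cfg, seed = 41)
  summ <- summarize_proteins(sim$features, method = "unique")
  contrasts <- ref_contrasts(sprintf("cond%d", 1:3))
  res <- test_differential(summ, contrasts)
  expect_s3_class(res, "differential_results")
  expect_equal(nrow(res), 3L * 2L)
  expect_true(all(res$adj_p_value >= res$p_value))
  for (ctr in unique(res$contrast)) {
    sub <- res[res$contrast == ctr, ]
    expect_equal(sub$adj_p_value, oracle_bh(sub$p_value))
  }
  # empty contrast list gives an empty result
  expect_equal(nrow(test_differential(summ, list())), 0L)
})

test_that("a condition without data yields an absent row, not an error", {
  summ <- make_summaries(rnorm(6, 10), rep(c("a", "b"), each = 3))
  fit <- fit_protein_model(summ)
  res <- test_contrast(fit, c(b = 1, c = -1)) # condition c never observed
  expect_equal(nrow(res), 0L)
})

test_that("method comparison reduces to identical results without shared peptides", {
  set.seed(19)
  mem <- list(
    a1 = "A", a2 = "A", a3 = "A",
    b1 = "B", b2 = "B", b3 = "B"
  )
  x <- matrix(rnorm(6 * 6, 10, 0.2), 6, 6,
    dimnames = list(names(mem), sprintf("ch%02d", 1:6))
  )
  feats <- make_features(x, mem,
    conditions = rep(c("ctrl", "trt"), each = 3),
    bio_replicates = as.character(rep(1:3, 2))
  )
  res <- compare_summarization_methods(
    feats,
    contrasts = list("trt vs ctrl" = c(trt = 1, ctrl = -1))
  )
  wide <- res |>
    dplyr::select(protein, method, log2fc) |>
    tidyr::pivot_wider(names_from = method, values_from = log2fc)
  expect_equal(wide$weighted, wide$unique, tolerance = 1e-6)
  expect_equal(wide$weighted, wide$all, tolerance = 1e-6)
})

test_that("condition-time designs fit cell means", {
  summ <- make_summaries(
    c(0, 0.2, 1.0, 1.2, 2.0, 2.2),
    rep(c("ctrl", "trt", "trt"), each = 2)
  )
  summ$time <- rep(c("t0", "t0", "t1"), each = 2)
  fit <- fit_protein_model(summ, design = "condition-time")
  res <- test_contrast(fit, c(`trt:t1` = 1, `trt:t0` = -1))
  expect_equal(res$log2fc, 1.0, tolerance = 1e-10)
})
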