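fit_constraints_ok <- function(fit) {
  expect_lt(abs(sum(fit$feature_effects)), 1e-8)
  expect_lt(abs(sum(fit$protein_effects)), 1e-8)
  expect_lt(max(abs(rowSums(fit$channel_effects))), 1e-8)
  W <- fit$weights
  expect_true(all(W >= -1e-12))
  for (f in seq_along(fit$membership)) {
    V <- fit$membership[[f]]
    expect_lt(abs(sum(W[f, V]) - 1), 1e-6)
    expect_true(all(W[f, -V] == 0) || length(V) == ncol(W))
    if (length(V) == 1L) expect_identical(W[f, V], 1)
  }
}

test_that("weight estimation allocates a profile-matching shared feature to its source", {
  # protein profiles differing in several channels; shared feature follows A
  C <- 8
  A_prof <- c(0, 0.5, 1, 1.5, 2, 1, 0.5, 0)
  B_prof <- c(2, 1.5, 1, 0.5, 0, 0.5, 1, 1.5)
  profiles <- list(
    mu = 10,
    feature_effects = rep(0, 1),
    protein_effects = c(0.5, -0.5),
    channel_effects = rbind(A_prof - mean(A_prof), B_prof - mean(B_prof))
  )
  Af <- profiles$protein_effects + profiles$channel_effects
  x <- matrix(10 + 0.3 + Af[1, ], 1, C) # shared feature = A's profile + offset
  membership <- list(c(1L, 2L))
  W <- estimate_weights(x, membership, profiles)
  expect_equal(unname(W[1, ]), c(1, 0), tolerance = 0.01)
  # grid-search oracle agrees
  w_star <- oracle_grid_weight2(drop(x) - profiles$mu, Af, M = 1e-3)
  expect_equal(unname(W[1, 1]), w_star, tolerance = 0.01)
})

test_that("indistinguishable profiles keep the previous (uniform) weights", {
  C <- 6
  prof <- c(0, 1, 2, 2, 1, 0)
  profiles <- list(
    mu = 10, feature_effects = rep(0, 1),
    protein_effects = c(0, 0),
    channel_effects = rbind(prof - mean(prof), prof - mean(prof))
  )
  x <- matrix(10 + prof - mean(prof), 1, C)
  W <- estimate_weights(x, list(c(1L, 2L)), profiles)
  expect_equal(unname(W[1, ]), c(0.5, 0.5))
  # unique feature: weight 1 without optimization
  W1 <- estimate_weights(x, list(2L), profiles)
  expect_equal(unname(W1[1, ]), c(0, 1))
})

test_that("weighted summaries reduce to the single-protein robust fit without sharing", {
  # well-posed regime (see test-huber.R): inliers in the quadratic zone,
  # one gross outlier in the linear zone
  set.seed(31)
  mem <- list(a1 = "A", a2 = "A", a3 = "A")
  x <- matrix(rnorm(3 * 5, 10, 0.01), 3, 5,
    dimnames = list(names(mem), sprintf("ch%02d", 1:5))
  ) + rnorm(3, sd = 0.4) + rep(rnorm(5, sd = 0.3), each = 3)
  x[2, 4] <- x[2, 4] + 6
  feats <- make_features(x, mem)
  fit_a <- fit_weighted_model(feats, huber_config(M = 0.05))
  oracle <- oracle_huber_eq1(x, M = 0.05)
  got <- extract_summaries(fit_a)
  expect_equal(got$abundance, unname(oracle), tolerance = 1e-4)
})

test_that("zero-noise clusters are recovered exactly and weights at low noise approximately", {
  sim <- two_protein_cluster(seed = 13, noise_sd = 0)
  fit <- fit_weighted_model(sim$features, huber_config(weight_tol = 1e-6))
  fit_constraints_ok(fit)
  expect_true(fit$converged)
  W_true <- sim$truth$weights[fit$features, fit$proteins]
  expect_lt(max(abs(fit$weights - W_true)), 1e-6)
  est <- extract_summaries(fit)
  truth_long <- as.vector(t(sim$truth$protein_channel))
  expect_lt(max(abs(est$abundance - truth_long)), 1e-6)

  for (seed in 1:5) {
    simn <- two_protein_cluster(seed = seed, noise_sd = 0.05)
    fitn <- fit_weighted_model(simn$features)
    fit_constraints_ok(fitn)
    expect_lt(
      max(abs(fitn$weights - simn$truth$weights[fitn$features, fitn$proteins])),
      0.1
    )
  }
})

test_that("the joint objective is non-increasing across half-steps", {
  for (seed in c(2, 9)) {
    sim <- two_protein_cluster(seed = seed, noise_sd = 0.2)
    fit <- fit_weighted_model(sim$features)
    expect_true(all(diff(fit$objective) <= 1e-6))
  }
})

test_that("outputs are equivariant under protein relabeling and intensity shifts", {
  sim <- two_protein_cluster(seed = 17, noise_sd = 0.1)
  feats <- sim$features
  fit <- fit_weighted_model(feats)

  # swap protein labels
  relabel <- c(P01 = "Q2", P02 = "Q1")
  feats2 <- feats
  feats2$protein <- lapply(feats$protein, function(v) unname(relabel[v]))
  fit2 <- fit_weighted_model(feats2)
  s1 <- extract_summaries(fit)
  s2 <- extract_summaries(fit2)
  merged <- dplyr::inner_join(
    s1 |> dplyr::mutate(protein = unname(relabel[protein])),
    s2,
    by = c("protein", "channel")
  )
  expect_equal(merged$abundance.x, merged$abundance.y, tolerance = 1e-6)

  # adding a constant shifts all summaries by that constant
  feats3 <- feats |> dplyr::mutate(log2_intensity = log2_intensity + 2.5)
  fit3 <- fit_weighted_model(feats3)
  expect_equal(
    extract_summaries(fit3)$abundance,
    extract_summaries(fit)$abundance + 2.5,
    tolerance = 1e-6
  )
})

test_that("a single gross outlier leaves the summaries essentially unchanged", {
  # cluster sized like a real degrader-study cluster: several proteins
  # with a healthy number of unique peptides each
  cfg <- simulation_config(
    n_proteins = 3, n_unique_per_protein = 6, n_shared_per_pair = 5,
    n_conditions = 5, n_bioreps = 2, noise_sd = 0.1
  )
  sim <- simulate_cluster(cfg, seed = 23)
  feats <- sim$features
  fit <- fit_weighted_model(feats)
  dirty <- feats
  idx <- which(dirty$feature_id == dirty$feature_id[[1]] & dirty$channel == "ch03")
  dirty$log2_intensity[idx] <- dirty$log2_intensity[idx] + 10
  fit_d <- fit_weighted_model(dirty)
  expect_lt(
    max(abs(extract_summaries(fit_d)$abundance - extract_summaries(fit)$abundance)),
    10 * 0.01
  )
})

test_that("uniform-weight and trivial-cluster paths behave as documented", {
  sim <- two_protein_cluster(seed = 3, noise_sd = 0.1)
  fit_u <- fit_weighted_model(sim$features, update_weights = FALSE)
  expect_equal(fit_u$n_iter, 1L)
  shared <- lengths(fit_u$membership) > 1L
  expect_true(all(abs(fit_u$weights[shared, ] - 0.5) < 1e-12))
  expect_true(all(fit_u$weights[!shared, ] %in% c(0, 1)))

  # trivial cluster: converges immediately, weights all one
  mem <- list(f1 = "P", f2 = "P")
  feats <- make_features(
    matrix(rnorm(8, 10), 2, dimnames = list(names(mem), NULL)), mem
  )
  fit_t <- fit_weighted_model(feats)
  expect_true(fit_t$converged)
  expect_equal(fit_t$n_iter, 1L)
  expect_true(all(fit_t$weights == 1))
})

test_that("an all-shared cluster is flagged as unidentifiable", {
  mem <- list(s1 = c("A", "B"), s2 = c("A", "B"), s3 = c("A", "B"))
  feats <- make_features(
    matrix(rnorm(12, 10), 3, dimnames = list(names(mem), NULL)), mem
  )
  fit <- fit_weighted_model(feats)
  expect_true(fit$unidentifiable)
  expect_true(all(fit$init_fallback))
})

test_that("accessors expose weights and convergence records", {
  sim <- two_protein_cluster(seed = 29, noise_sd = 0.1)
  fit <- fit_weighted_model(sim$features)
  w <- tidy(fit)
  expect_setequal(names(w), c("feature_id", "protein", "weight", "is_unique"))
  expect_equal(sum(!w$is_unique), 2L * sum(lengths(fit$membership) > 1L))
  g <- glance(fit)
  expect_equal(nrow(g), 1L)
  expect_true(g$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("multi-mixture tables are summarized per mixture with per-mixture weights", {
  sim1 <- two_protein_cluster(seed = 41, noise_sd = 0.1)
  sim2 <- two_protein_cluster(seed = 42, noise_sd = 0.1)
  f2 <- sim2$features
  f2$mixture <- "mix2"
  feats <- dplyr::bind_rows(sim1$features, f2)
  summ <- summarize_proteins(feats, method = "weighted")
  expect_setequal(unique(summ$summaries$mixture), c("mix1", "mix2"))
  expect_setequal(unique(summ$weights$mixture), c("mix1", "mix2"))
  expect_equal(nrow(summ$convergence), 2L)
  # each mixture's summary agrees with fitting that mixture alone
  solo <- summarize_proteins(sim1$features, method = "weighted")
  m1 <- summ$summaries[summ$summaries$mixture == "mix1", ]
  expect_equal(
    m1$abundance[order(m1$protein, m1$channel)],
    solo$summaries$abundance[order(solo$summaries$protein, solo$summaries$channel)],
    tolerance = 1e-10
  )
  expect_error(fit_weighted_model(feats), "one mixture")
})
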