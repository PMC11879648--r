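#' Configuration for the weighted cluster fit
#'
#' @param M Positive Huber threshold; small values (default `1e-3`, with
#'   `1e-6` as a common alternative) make the fit robust to outliers and
#'   help convergence of the alternating search.
#' @param max_iter Maximum number of alternating iterations.
#' @param weight_tol Convergence tolerance: the fit stops when the
#'   maximum absolute change of any peptide-protein weight between
#'   consecutive iterations falls below this value.
#' @param loss One of `"huber"` (default), `"l2"`, `"l1"`. `"l1"` is
#'   provided for completeness but its non-differentiability can prevent
#'   convergence of the alternating search.
#' @param obj_tol Secondary stopping rule: the alternation also stops
#'   once the relative objective decrease over a full iteration stays
#'   below this value for two consecutive iterations (weights of
#'   profile-indistinguishable features can wander in flat directions of
#'   the objective without ever meeting `weight_tol`).
#' @param irls_iter,irls_tol Iteration cap and coefficient tolerance of
#'   the inner IRLS solver of the profile step.
#' @return A list of class `huber_config`.
#' @export
huber_config <- function(M = 1e-3, max_iter = 100L, weight_tol = 1e-3,
                         loss = c("huber", "l2", "l1"),
                         obj_tol = 1e-6,
                         irls_iter = 30L, irls_tol = 1e-9) {
  loss <- match.arg(loss)
  if (loss == "huber") check_huber_m(M)
  if (weight_tol <= 0) abort("`weight_tol` must be positive.")
  if (max_iter < 1L) abort("`max_iter` must be a positive integer.")
  structure(
    list(
      M = M, max_iter = as.integer(max_iter), weight_tol = weight_tol,
      loss = loss, obj_tol = obj_tol,
      irls_iter = as.integer(irls_iter), irls_tol = irls_tol
    ),
    class = "huber_config"
  )
}

# ---------------------------------------------------------------------------
# matrix-level core. x: F x C matrix of log2 intensities (NA = missing),
# membership: list of length F of integer vectors (subsets of 1..K).

check_membership <- function(x, membership, K = NULL) {
  if (length(membership) != nrow(x)) {
    abort("`membership` must have one element per row of `x`.")
  }
  if (any(lengths(membership) == 0L)) {
    abort("every feature must match at least one protein.")
  }
  K <- K %||% max(unlist(membership))
  K
}

# objective of the joint model at given weights and profiles
cluster_objective <- function(x, membership, weights, profiles, config) {
  fitted <- cluster_fitted(membership, weights, profiles, ncol(x))
  r <- x - fitted
  sum(loss_value(r[!is.na(r)], config$loss, config$M))
}

# F x C matrix of fitted values
cluster_fitted <- function(membership, weights, profiles, C) {
  A <- profiles$protein_effects + profiles$channel_effects # K x C
  profiles$mu + profiles$feature_effects + weights %*% A
}

#' Initialize profiles from unique features
#'
#' Starting point of the alternating search: each protein's channel
#' profile is the median-polish summary of its unique features. Proteins
#' without unique features fall back to the profile of a uniform-weight
#' inclusion fit of the whole cluster (flagged in the result). Profiles
#' are re-parameterized to satisfy the sum-to-zero constraints, and
#' per-feature effects are initialized as robust locations of the
#' residuals under uniform weights.
#'
#' @param x Numeric feature-by-channel matrix of log2 intensities.
#' @param membership List (length `nrow(x)`) of integer vectors giving
#'   the proteins matched by each feature.
#' @param config A [huber_config()].
#' @return A profile list: `mu`, `feature_effects` (length F, sum 0),
#'   `protein_effects` (length K, sum 0), `channel_effects` (K x C
#'   matrix, rows sum 0), and `fallback` (logical per protein).
#' @export
init_profiles <- function(x, membership, config = huber_config()) {
  K <- check_membership(x, membership)
  C <- ncol(x)
  if (C < 1L || nrow(x) < 1L) abort("`x` must have at least one row and column.")
  unique_of <- lapply(seq_len(K), function(k) {
    which(vapply(membership, function(v) identical(v, k), logical(1)))
  })
  fallback <- lengths(unique_of) == 0L

  Y <- matrix(NA_real_, K, C, dimnames = list(NULL, colnames(x)))
  for (k in seq_len(K)) {
    if (!fallback[k]) {
      mp <- suppressWarnings(median_polish(x[unique_of[[k]], , drop = FALSE]))
      Y[k, ] <- mp$overall + mp$col
    }
  }
  if (any(fallback)) {
    W0 <- uniform_weights(membership, K)
    unif <- estimate_profiles(x, membership, W0, config)
    Yu <- unif$mu + unif$protein_effects + unif$channel_effects
    Y[fallback, ] <- Yu[fallback, , drop = FALSE]
  }
  # unobserved channels of a protein carry no information: flat profile
  Y <- t(apply(Y, 1L, function(row) {
    row[is.na(row)] <- mean(row, na.rm = TRUE)
    row
  }))

  protein_means <- rowMeans(Y)
  mu <- mean(protein_means)
  protein_effects <- protein_means - mu
  channel_effects <- Y - protein_means

  W0 <- uniform_weights(membership, K)
  A <- protein_effects + channel_effects
  expected <- mu + W0 %*% A
  feature_effects <- vapply(seq_len(nrow(x)), function(f) {
    loss_location(x[f, ] - expected[f, ], config$loss, config$M)
  }, numeric(1))
  feature_effects[!is.finite(feature_effects)] <- 0
  shift <- mean(feature_effects)
  list(
    mu = mu + shift,
    feature_effects = feature_effects - shift,
    protein_effects = protein_effects,
    channel_effects = channel_effects,
    fallback = fallback
  )
}

uniform_weights <- function(membership, K) {
  F_ <- length(membership)
  W <- matrix(0, F_, K)
  for (f in seq_len(F_)) {
    W[f, membership[[f]]] <- 1 / length(membership[[f]])
  }
  W
}

#' Estimate peptide-protein weights at fixed profiles
#'
#' For each shared feature independently, minimizes the robust loss of
#' the residuals over the simplex of membership weights (non-negative,
#' summing to one over the feature's candidate proteins), holding the
#' overall mean and the protein/channel profiles fixed. The feature's
#' own additive effect is profiled out (re-estimated as the robust
#' location of the residuals at each candidate weight), which keeps the
#' per-feature problem jointly convex and makes the alternating search
#' land on boundary weights directly instead of creeping towards them.
#' Unique features get weight 1 without optimization. When the
#' objective is flat in the weights (indistinguishable profiles) or the
#' solver fails, the previous weights are retained (and, transitively,
#' the uniform initialization).
#'
#' @inheritParams init_profiles
#' @param profiles A profile list as returned by [init_profiles()] or
#'   [estimate_profiles()].
#' @param prev_weights F x K matrix of current weights (the iterate to
#'   fall back to); defaults to uniform over each feature's proteins.
#' @return F x K weight matrix: rows sum to 1 over the feature's
#'   proteins and are 0 elsewhere. The profiled feature effects of the
#'   shared features are attached as the `"feature_effects"` attribute
#'   (named by row index).
#' @export
estimate_weights <- function(x, membership, profiles,
                             config = huber_config(),
                             prev_weights = NULL) {
  K <- check_membership(x, membership)
  W <- prev_weights %||% uniform_weights(membership, K)
  A <- profiles$protein_effects + profiles$channel_effects
  feat_upd <- numeric(0)
  for (f in seq_len(nrow(x))) {
    V <- membership[[f]]
    if (length(V) == 1L) {
      W[f, ] <- 0
      W[f, V] <- 1
      next
    }
    obs <- which(!is.na(x[f, ]))
    if (length(obs) == 0L) next
    r <- x[f, obs] - profiles$mu
    Af <- A[V, obs, drop = FALSE]
    w_prev <- W[f, V]
    # profiled objective: feature effect re-estimated per candidate w
    profiled <- function(w) {
      res0 <- r - drop(w %*% Af)
      Ff <- loss_location(res0, config$loss, config$M, max_iter = 40L)
      list(value = sum(loss_value(res0 - Ff, config$loss, config$M)), Ff = Ff)
    }
    w_new <- solve_simplex_weights(
      function(w) profiled(w)$value, w_prev, config,
      d = length(V) - 1L, Af = Af, r = r,
      loc = function(w) profiled(w)$Ff
    )
    # monotone acceptance doubles as the tie rule: a flat objective keeps
    # the previous iterate
    prev_eval <- profiled(w_prev)
    new_eval <- if (is.null(w_new)) NULL else profiled(w_new)
    if (is.null(new_eval) || !(new_eval$value < prev_eval$value - 1e-12)) {
      w_new <- w_prev
      new_eval <- prev_eval
    }
    W[f, ] <- 0
    W[f, V] <- w_new
    feat_upd[as.character(f)] <- new_eval$Ff
  }
  attr(W, "feature_effects") <- feat_upd
  W
}

# minimize obj_w(w) over the probability simplex.
# dim 2: golden-section on [0, 1] with boundary polish (convex).
# dim > 2: barrier method from the interior-projected previous iterate,
# with an envelope-theorem gradient evaluated at the profiled residuals.
solve_simplex_weights <- function(obj_w, w_prev, config, d, Af, r, loc) {
  obj_u <- function(u) obj_w(c(u, 1 - sum(u)))
  res <- tryCatch(
    {
      if (d == 1L) {
        opt <- optimize(obj_u, interval = c(0, 1), tol = 1e-9)
        # golden section never lands exactly on 0 or 1
        cand <- c(opt$minimum, 0, 1)
        u <- cand[which.min(vapply(cand, obj_u, numeric(1)))]
      } else {
        eps <- 1e-4
        u0 <- (1 - eps) * w_prev[-length(w_prev)] + eps / length(w_prev)
        grad_u <- function(u) {
          w <- c(u, 1 - sum(u))
          res_c <- r - drop(w %*% Af) - loc(w)
          psi <- if (config$loss == "l2") 2 * res_c else huber_psi(res_c, config$M)
          -drop((Af[-nrow(Af), , drop = FALSE] -
            matrix(Af[nrow(Af), ], d, length(res_c), byrow = TRUE)) %*% psi)
        }
        opt <- constrOptim(u0, obj_u,
          grad = if (config$loss == "l1") NULL else grad_u,
          ui = rbind(diag(d), rep(-1, d)), ci = c(rep(0, d), -1),
          mu = 1e-8, method = "BFGS", outer.iterations = 50L
        )
        # project tiny barrier slack onto the boundary if it improves
        u <- pmin(pmax(opt$par, 0), 1)
        u_round <- ifelse(u < 1e-6, 0, u)
        if (sum(u_round) <= 1 && obj_u(u_round) <= obj_u(u)) u <- u_round
        u
      }
      c(u, 1 - sum(u))
    },
    error = function(e) NULL
  )
  res
}

#' Estimate profiles at fixed weights
#'
#' Given fixed peptide-protein weights, the model is linear in the
#' overall mean, feature effects and per-protein channel effects; these
#' are estimated by minimizing the robust loss over observed cells
#' (IRLS). Sum-to-zero constraints hold by construction through a
#' reduced (sum-contrast) parameterization. Missing intensities are
#' omitted.
#'
#' The split of the fitted per-feature levels between `mu`, the feature
#' effects and the protein effects is not determined by the loss (the
#' weighted protein term is a function of the feature index only);
#' protein effects are identified by an explicit convention: the
#' sum-to-zero-constrained least-squares attribution of the feature
#' levels to the membership weights, which minimizes the feature-effect
#' norm and reduces to per-protein separate fits when the cluster
#' decouples. Fitted values, channel shapes and fold changes do not
#' depend on this convention.
#'
#' A protein carrying (numerically) zero total weight over the observed
#' cells is not estimable; its effects are taken from `init` and
#' flagged.
#'
#' @inheritParams estimate_weights
#' @param weights F x K matrix of fixed weights (rows on the simplex).
#' @param init Optional profile list supplying values for non-estimable
#'   parameters.
#' @param start Optional coefficient warm start (as returned in the
#'   `beta` element) to speed up the inner IRLS solver.
#' @return A profile list (`mu`, `feature_effects`, `protein_effects`,
#'   `channel_effects`) plus `residual_scale` (robust estimate of the
#'   error sd), `flagged_proteins` (integer indices held at `init`) and
#'   `beta` (internal coefficient vector for warm starts).
#' @export
estimate_profiles <- function(x, membership, weights,
                              config = huber_config(), init = NULL,
                              start = NULL) {
  K <- check_membership(x, membership)
  F_ <- nrow(x)
  C <- ncol(x)
  obs <- which(!is.na(x), arr.ind = TRUE)
  if (nrow(obs) == 0L) abort("estimate_profiles: no observed intensities.")
  y <- x[obs]
  fi <- obs[, 1L]
  ci <- obs[, 2L]

  dead <- which(colSums(abs(weights[fi, , drop = FALSE])) < 1e-10)
  alive <- setdiff(seq_len(K), dead)
  if (length(alive) == 0L) abort("estimate_profiles: no estimable protein.")
  Ka <- length(alive)
  Wobs <- weights[fi, alive, drop = FALSE]

  # reduced design: intercept | feature contrasts | per-protein channel
  # contrasts (last level = negative sum). No protein columns: the
  # weighted protein term is exactly collinear with intercept + feature
  # contrasts and is recovered afterwards by the identification
  # convention (see above).
  n_feat <- if (F_ > 1L) F_ - 1L else 0L
  n_chan <- Ka * (C - 1L)
  X <- matrix(0, nrow(obs), 1L + n_feat + n_chan)
  X[, 1L] <- 1
  if (n_feat > 0L) {
    lastf <- (fi == F_)
    for (j in seq_len(n_feat)) {
      X[, 1L + j] <- (fi == j) - lastf
    }
  }
  off <- 1L + n_feat
  if (C > 1L) {
    last <- (ci == C)
    for (a in seq_len(Ka)) {
      wk <- Wobs[, a]
      cols <- off + (a - 1L) * (C - 1L) + seq_len(C - 1L)
      for (cc in seq_len(C - 1L)) {
        X[, cols[cc]] <- wk * ((ci == cc) - last)
      }
    }
  }

  if (!is.null(start) && length(start) != ncol(X)) start <- NULL
  beta <- irls_fit(X, y, config, start = start)
  aliased <- attr(beta, "aliased")
  beta_clean <- unclass(beta)
  attributes(beta_clean) <- NULL
  beta_clean[is.na(beta_clean)] <- 0

  mu <- beta_clean[1L]
  feature_levels <- if (n_feat > 0L) {
    b <- beta_clean[1L + seq_len(n_feat)]
    c(b, -sum(b))
  } else {
    rep(0, F_)
  }
  channel_alive <- matrix(0, Ka, C)
  if (C > 1L) {
    for (a in seq_len(Ka)) {
      b <- beta_clean[off + (a - 1L) * (C - 1L) + seq_len(C - 1L)]
      channel_alive[a, ] <- c(b, -sum(b))
    }
  }

  # identification convention: regress the feature levels on the weight
  # columns (sum-contrast basis over alive proteins, plus intercept);
  # the fitted part defines the protein effects, the residuals the
  # feature effects. Fitted values are unchanged by construction.
  Wall <- weights[, alive, drop = FALSE]
  protein_alive <- rep(0, Ka)
  dmu <- 0
  if (Ka > 1L) {
    S <- rbind(diag(Ka - 1L), rep(-1, Ka - 1L))
    Z <- cbind(1, Wall %*% S)
    cf <- stats::lm.fit(Z, feature_levels)$coefficients
    cf[is.na(cf)] <- 0
    dmu <- cf[[1L]]
    p_free <- cf[-1L]
    protein_alive <- drop(S %*% p_free)
    feature_levels <- feature_levels - drop(Z %*% cf)
  } else {
    # single protein: any common level of the features belongs to mu
    dmu <- mean(feature_levels)
    feature_levels <- feature_levels - dmu
  }
  mu <- mu + dmu

  protein_effects <- rep(0, K)
  channel_effects <- matrix(0, K, C, dimnames = list(NULL, colnames(x)))
  protein_effects[alive] <- protein_alive
  channel_effects[alive, ] <- channel_alive
  if (length(dead) > 0L) {
    if (!is.null(init)) {
      protein_effects[dead] <- init$protein_effects[dead]
      channel_effects[dead, ] <- init$channel_effects[dead, , drop = FALSE]
    }
    # re-center over all proteins; compensated through mu, which leaves
    # fitted values unchanged because weights sum to 1 per feature
    d_shift <- mean(protein_effects)
    protein_effects <- protein_effects - d_shift
    mu <- mu + d_shift
  }

  res <- y - X %*% beta_clean
  residual_scale <- stats::mad(res, center = 0)
  list(
    mu = mu,
    feature_effects = feature_levels,
    protein_effects = protein_effects,
    channel_effects = channel_effects,
    residual_scale = residual_scale,
    flagged_proteins = dead,
    aliased = aliased,
    beta = beta_clean
  )
}

# IRLS solver for the reduced linear model under the configured loss
irls_fit <- function(X, y, config, start = NULL) {
  beta <- NULL
  w <- rep(1, length(y))
  if (!is.null(start)) {
    w <- loss_irls_weight(drop(y - X %*% start), config$loss, config$M)
  }
  aliased <- FALSE
  for (it in seq_len(if (config$loss == "l2") 1L else config$irls_iter)) {
    # tight pivot tolerance: the protein-location direction can be weakly
    # identified (curvature scales with the imbalance of total weight mass
    # across proteins) and must not be pivoted out unless exactly aliased
    fit <- lm.wfit(X, y, w, tol = 1e-12)
    b <- fit$coefficients
    aliased <- aliased || anyNA(b)
    b_num <- ifelse(is.na(b), 0, b)
    if (!is.null(beta) &&
      max(abs(b_num - beta)) < config$irls_tol * (1 + max(abs(b_num)))) {
      beta <- b_num
      break
    }
    beta <- b_num
    r <- y - X %*% beta
    w <- loss_irls_weight(drop(r), config$loss, config$M)
  }
  structure(beta, aliased = aliased)
}

#' Fit the weighted summarization model for one cluster and mixture
#'
#' Alternating convex search: profiles are initialized from unique
#' features, then the weight step ([estimate_weights()]) and the profile
#' step ([estimate_profiles()]) alternate until the maximum absolute
#' change in the weights drops below `config$weight_tol` or `max_iter`
#' is reached. Both half-steps minimize the same joint robust objective,
#' which is therefore non-increasing along the iterations.
#'
#' @param features Canonical feature tibble restricted to one protein
#'   cluster and one TMT mixture; the `protein` list column defines the
#'   membership sets.
#' @param config A [huber_config()].
#' @param update_weights If `FALSE`, weights are held at the uniform
#'   initialization (inclusion fit) and only one profile step is run.
#' @return A `cluster_fit` object; see [extract_summaries()] and
#'   [tidy.cluster_fit()].
#' @export
fit_weighted_model <- function(features, config = huber_config(),
                               update_weights = TRUE) {
  assert_feature_table(features)
  if (nrow(features) == 0L) abort("fit_weighted_model: empty cluster.")
  if (dplyr::n_distinct(features$mixture) > 1L) {
    abort("fit_weighted_model() fits one mixture at a time; see summarize_proteins().")
  }
  proteins <- sort(unique(unlist(features$protein)))
  x <- feature_matrix(features)
  feat_ids <- rownames(x)
  mem_map <- features |>
    dplyr::distinct(.data$feature_id, .data$protein) |>
    tidyr::unnest_longer("protein") |>
    dplyr::distinct(.data$feature_id, .data$protein)
  membership <- lapply(feat_ids, function(f) {
    sort(match(mem_map$protein[mem_map$feature_id == f], proteins))
  })
  fit <- fit_weighted_core(x, membership, config, update_weights)
  fit$proteins <- proteins
  fit$channels <- colnames(x)
  fit$features <- feat_ids
  fit$mixture <- features$mixture[[1L]]
  fit$channel_info <- features |>
    dplyr::distinct(.data$channel, .data$condition, .data$bio_replicate)
  fit
}

# matrix-level driver (exported surface is fit_weighted_model)
fit_weighted_core <- function(x, membership, config = huber_config(),
                              update_weights = TRUE) {
  K <- check_membership(x, membership)
  profiles <- init_profiles(x, membership, config)
  W <- uniform_weights(membership, K)
  unidentifiable <- all(lengths(membership) > 1L) && K > 1L
  objective <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  final_change <- NA_real_

  if (!update_weights || K == 1L) {
    if (K == 1L) W[] <- 1
    profiles <- estimate_profiles(x, membership, W, config, init = profiles)
    objective <- cluster_objective(x, membership, W, profiles, config)
    converged <- TRUE
    n_iter <- 1L
    final_change <- 0
  } else {
    stalled <- 0L
    for (it in seq_len(config$max_iter)) {
      W_new <- estimate_weights(x, membership, profiles, config, W)
      # the weight step profiles the shared features' effects; fold them
      # back in so the recorded objective reflects the half-step
      feat_upd <- attr(W_new, "feature_effects")
      if (length(feat_upd) > 0L) {
        idx <- as.integer(names(feat_upd))
        profiles$feature_effects[idx] <- feat_upd
      }
      attr(W_new, "feature_effects") <- NULL
      objective <- c(
        objective,
        cluster_objective(x, membership, W_new, profiles, config)
      )
      final_change <- max(abs(W_new - W))
      W <- W_new
      profiles <- estimate_profiles(x, membership, W, config,
        init = profiles, start = profiles$beta
      )
      objective <- c(
        objective,
        cluster_objective(x, membership, W, profiles, config)
      )
      n_iter <- it
      if (final_change < config$weight_tol) {
        converged <- TRUE
        break
      }
      # secondary stop: weights of profile-indistinguishable features can
      # wander in flat directions; stop once the objective has stalled
      n_obj <- length(objective)
      if (it > 1L) {
        rel_drop <- (objective[n_obj - 2L] - objective[n_obj]) /
          max(abs(objective[n_obj]), 1e-12)
        stalled <- if (rel_drop < (config$obj_tol %||% 1e-6)) stalled + 1L else 0L
        if (stalled >= 2L) {
          converged <- TRUE
          break
        }
      }
    }
  }

  structure(
    list(
      mu = profiles$mu,
      feature_effects = profiles$feature_effects,
      protein_effects = profiles$protein_effects,
      channel_effects = profiles$channel_effects,
      weights = W,
      converged = converged,
      n_iter = n_iter,
      final_weight_change = final_change,
      residual_scale = profiles$residual_scale %||% NA_real_,
      objective = objective,
      flagged_proteins = profiles$flagged_proteins,
      init_fallback = profiles$fallback,
      unidentifiable = unidentifiable,
      config = config,
      membership = membership
    ),
    class = "cluster_fit"
  )
}

#' @export
print.cluster_fit <- function(x, ...) {
  cat(sprintf(
    "<cluster_fit> %d protein(s), %d feature(s), %d channel(s); %s in %d iteration(s), final weight change %.2e\n",
    length(x$protein_effects), length(x$feature_effects),
    ncol(x$channel_effects),
    if (isTRUE(x$converged)) "converged" else "NOT converged",
    x$n_iter, x$final_weight_change
  ))
  invisible(x)
}

#' Per-protein channel summaries of a fitted cluster
#'
#' Assembles the protein-level summary for protein `k` in channel `c` as
#' the estimated overall mean plus protein effect plus per-protein
#' channel effect.
#'
#' @param fit A `cluster_fit` from [fit_weighted_model()].
#' @return Tibble with columns `protein`, `channel`, `abundance`, plus
#'   `mixture`, `condition` and `bio_replicate` when the fit carries
#'   channel metadata.
#' @export
extract_summaries <- function(fit) {
  if (!inherits(fit, "cluster_fit")) abort("`fit` must be a cluster_fit.")
  K <- length(fit$protein_effects)
  C <- ncol(fit$channel_effects)
  proteins <- fit$proteins %||% as.character(seq_len(K))
  channels <- fit$channels %||% colnames(fit$channel_effects) %||%
    as.character(seq_len(C))
  out <- tibble::tibble(
    protein = rep(proteins, each = C),
    channel = rep(channels, K),
    abundance = as.vector(t(fit$mu + fit$protein_effects + fit$channel_effects))
  )
  if (!is.null(fit$mixture)) out$mixture <- fit$mixture
  if (!is.null(fit$channel_info)) {
    out <- dplyr::left_join(out, fit$channel_info, by = "channel")
  }
  out
}

#' @describeIn extract_summaries Broom-style accessor for the estimated
#'   peptide-protein weights: one row per (feature, protein) pair in the
#'   feature's membership set.
#' @param x A `cluster_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cluster_fit <- function(x, ...) {
  feats <- x$features %||% as.character(seq_along(x$feature_effects))
  prots <- x$proteins %||% as.character(seq_along(x$protein_effects))
  purrr::map_dfr(seq_along(feats), function(f) {
    V <- x$membership[[f]]
    tibble::tibble(
      feature_id = feats[[f]],
      protein = prots[V],
      weight = x$weights[f, V],
      is_unique = length(V) == 1L
    )
  })
}

#' @describeIn extract_summaries One-row convergence record.
#' @exportS3Method generics::glance
glance.cluster_fit <- function(x, ...) {
  tibble::tibble(
    n_proteins = length(x$protein_effects),
    n_features = length(x$feature_effects),
    converged = x$converged,
    n_iter = x$n_iter,
    final_weight_change = x$final_weight_change,
    residual_scale = x$residual_scale,
    objective = if (length(x$objective)) x$objective[length(x$objective)] else NA_real_,
    unidentifiable = x$unidentifiable
  )
}
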