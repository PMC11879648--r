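# Independent oracles used across the suite. These deliberately avoid the
# package's own numerical routes: stats::medpolish for the polish sweep,
# optim-BFGS on the smooth objective for Huber fits, grid search on the
# simplex for the weight step, and hand-coded closed forms for the tests.

# Tukey polish oracle (independent sweep implementation)
oracle_medpolish <- function(mat, eps = 1e-13) {
  fit <- stats::medpolish(mat, eps = eps, maxiter = 200, na.rm = TRUE, trace.iter = FALSE)
  list(overall = fit$overall, row = fit$row, col = fit$col, residuals = fit$residuals)
}

huber_rho <- function(x, M) ifelse(abs(x) < M, x^2, 2 * M * abs(x) - M^2)

# direct convex-solver fit of the single-protein two-way Huber model:
# X_fc = mu + F_f + C_c, sum F = sum C = 0. Returns per-channel summaries
# mu + C_c. Optimizer: BFGS with analytic gradient on the reduced
# parameterization, long leash.
oracle_huber_eq1 <- function(mat, M = 1e-3) {
  F_ <- nrow(mat)
  C <- ncol(mat)
  obs <- which(!is.na(mat), arr.ind = TRUE)
  y <- mat[obs]
  fi <- obs[, 1L]
  ci <- obs[, 2L]
  unpack <- function(par) {
    mu <- par[1L]
    Fv <- if (F_ > 1) c(par[2:F_], -sum(par[2:F_])) else 0
    Cv <- if (C > 1) c(par[(F_ + 1):(F_ + C - 1)], -sum(par[(F_ + 1):(F_ + C - 1)])) else 0
    list(mu = mu, Fv = Fv, Cv = Cv)
  }
  objfun <- function(par) {
    p <- unpack(par)
    sum(huber_rho(y - p$mu - p$Fv[fi] - p$Cv[ci], M))
  }
  gradfun <- function(par) {
    p <- unpack(par)
    r <- y - p$mu - p$Fv[fi] - p$Cv[ci]
    psi <- ifelse(abs(r) < M, 2 * r, 2 * M * sign(r))
    g_mu <- -sum(psi)
    g_F <- if (F_ > 1) {
      vapply(1:(F_ - 1), function(j) -sum(psi[fi == j]) + sum(psi[fi == F_]), numeric(1))
    } else {
      numeric(0)
    }
    g_C <- if (C > 1) {
      vapply(1:(C - 1), function(cc) -sum(psi[ci == cc]) + sum(psi[ci == C]), numeric(1))
    } else {
      numeric(0)
    }
    c(g_mu, g_F, g_C)
  }
  start <- c(mean(y), rep(0, F_ - 1), rep(0, C - 1))
  opt <- optim(start, objfun, gradfun,
    method = "BFGS",
    control = list(maxit = 5000, reltol = 1e-15)
  )
  p <- unpack(opt$par)
  p$mu + p$Cv
}

# grid-search oracle for the 2-protein weight step with the feature
# effect profiled out (location solved by 1-d optimize, independently of
# the package IRLS)
oracle_grid_weight2 <- function(r, Af, M = 1e-3, step = 0.001) {
  grid <- seq(0, 1, by = step)
  loc_obj <- function(res0) {
    opt <- optimize(function(f) sum(huber_rho(res0 - f, M)),
      interval = range(res0) + c(-1, 1), tol = 1e-10
    )
    opt$objective
  }
  vals <- vapply(grid, function(w) {
    loc_obj(r - w * Af[1, ] - (1 - w) * Af[2, ])
  }, numeric(1))
  grid[which.min(vals)]
}

# hand-coded Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# union-find oracle for connected components of a bipartite edge list
oracle_components <- function(edges) {
  nodes <- unique(c(paste0("f:", edges$feature_id), paste0("p:", edges$protein)))
  parent <- setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[[i]] != i) i <- parent[[i]]
    i
  }
  for (e in seq_len(nrow(edges))) {
    a <- find(match(paste0("f:", edges$feature_id[[e]]), nodes))
    b <- find(match(paste0("p:", edges$protein[[e]]), nodes))
    parent[[a]] <- b
  }
  roots <- vapply(seq_along(nodes), find, numeric(1))
  split(nodes, roots)
}
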