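#' Huber loss
#'
#' The robust loss used by the weighted summarization objective:
#' quadratic for small residuals, linear in the tails,
#' \deqn{L_H(x, M) = x^2 \;\mathrm{if}\; |x| < M, \quad 2M|x| - M^2
#'   \;\mathrm{otherwise.}}
#' It is convex, continuous and differentiable at \eqn{|x| = M}. Small
#' values of `M` make the fit robust to outlying feature intensities
#' (the loss is then close to an L1 loss while remaining smooth).
#'
#' @param x Numeric vector of residuals (log2 scale).
#' @param M Positive scalar threshold between the quadratic and linear
#'   branches. Typical values are `1e-3` (default throughout the package)
#'   or `1e-6`.
#' @return Numeric vector of loss values, same length as `x`.
#' @examples
#' huber_loss(c(0, 0.0005, 1), M = 0.001)
#' @export
huber_loss <- function(x, M = 1e-3) {
  check_huber_m(M)
  ax <- abs(x)
  ifelse(ax < M, x^2, 2 * M * ax - M^2)
}

# derivative of huber_loss w.r.t. x
huber_psi <- function(x, M) {
  ax <- abs(x)
  ifelse(ax < M, 2 * x, 2 * M * sign(x))
}

# IRLS case weight for huber_loss: omega(r) * r = psi(r) / 2
huber_irls_weight <- function(r, M) {
  ar <- abs(r)
  w <- rep.int(1, length(r))
  idx <- ar >= M
  w[idx] <- M / ar[idx]
  w
}

check_huber_m <- function(M) {
  if (!is.numeric(M) || length(M) != 1L || !is.finite(M) || M <= 0) {
    abort("`M` must be a single positive number.")
  }
  invisible(M)
}

# loss dispatch: "huber" (default), "l2", "l1".
# l1 is provided for completeness; its non-differentiability can make the
# alternating fit fragile, which is why huber with small M is the default.
loss_value <- function(x, loss = "huber", M = 1e-3) {
  switch(loss,
    huber = {
      ax <- abs(x)
      out <- x * x
      idx <- ax >= M
      out[idx] <- 2 * M * ax[idx] - M * M
      out
    },
    l2 = x^2,
    l1 = abs(x),
    abort(sprintf("Unknown loss '%s'.", loss))
  )
}

loss_irls_weight <- function(r, loss = "huber", M = 1e-3) {
  switch(loss,
    huber = huber_irls_weight(r, M),
    l2 = rep(1, length(r)),
    l1 = 1 / pmax(abs(r), 1e-8),
    abort(sprintf("Unknown loss '%s'.", loss))
  )
}

# robust location estimate under the given loss (1-d M-estimation by IRLS)
loss_location <- function(x, loss = "huber", M = 1e-3, tol = 1e-11,
                          max_iter = 100L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) {
    return(NA_real_)
  }
  mu <- median(x)
  if (loss == "l2") {
    return(mean(x))
  }
  for (i in seq_len(max_iter)) {
    w <- loss_irls_weight(x - mu, loss, M)
    mu_new <- sum(w * x) / sum(w)
    if (abs(mu_new - mu) < tol) {
      mu <- mu_new
      break
    }
    mu <- mu_new
  }
  mu
}
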