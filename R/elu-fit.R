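## Four-parameter ELU curve fit, y ~ a * ELU(b * (x - x0)) + c with
## ELU alpha = 1, minimized by Adam on the mean squared error. Used to
## describe the upper envelope of SHAP values against log10 insertion
## rates, where the response saturates at low rates and falls off roughly
## linearly above a threshold.

#' Fit an ELU-shaped curve by Adam
#'
#' Minimizes `mean((a * ELU(b * (x - x0)) + c - y)^2)` with analytic
#' gradients and Adam updates. Several seeded starting points are tried
#' (heuristic inits jittered), and the best final loss wins.
#'
#' @param x,y Numeric vectors (at least 5 points).
#' @param lr Adam learning rate.
#' @param iters Iterations per start.
#' @param seed Seed for the jittered restarts.
#' @param n_starts Number of starting points.
#' @return Object of class `elu_fit`: `par` (a, b, x0, c), `r_squared`,
#'   `fitted`, plus the optimizer settings.
#' @export
fit_elu <- function(x, y, lr = 0.01, iters = 2000L, seed = 1L,
                    n_starts = 5L) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5L) stop("need at least 5 points")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  elu <- function(u) ifelse(u > 0, u, exp(pmin(u, 0)) - 1)
  elu_grad <- function(u) ifelse(u > 0, 1, exp(pmin(u, 0)))
  loss_of <- function(p) {
    r <- p[1] * elu(p[2] * (x - p[3])) + p[4] - y
    mean(r^2)
  }

  sx <- stats::sd(x); sy <- stats::sd(y)
  slope_sign <- sign(stats::cor(x, y))
  if (!is.finite(slope_sign) || slope_sign == 0) slope_sign <- 1
  base_init <- c(a = slope_sign * max(sy, 1e-3),
                 b = 1 / max(sx, 1e-3),
                 x0 = stats::median(x),
                 c = mean(y))

  best <- NULL; best_loss <- Inf
  for (s in seq_len(n_starts)) {
    p <- base_init
    if (s > 1L) p <- p * (1 + stats::rnorm(4, sd = 0.3)) +
        c(0, 0, stats::rnorm(1, sd = sx), 0)
    m <- numeric(4); v <- numeric(4)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    for (it in seq_len(iters)) {
      u <- p[2] * (x - p[3])
      E <- elu(u); dE <- elu_grad(u)
      r <- p[1] * E + p[4] - y
      g <- 2 * c(mean(r * E),
                 mean(r * p[1] * dE * (x - p[3])),
                 mean(r * p[1] * dE * (-p[2])),
                 mean(r))
      if (!all(is.finite(g)))
        stop("non-finite gradient at iteration ", it,
             "; parameters: ", paste(signif(p, 4), collapse = ", "))
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      p <- p - lr * (m / (1 - beta1^it)) / (sqrt(v / (1 - beta2^it)) + eps)
    }
    l <- loss_of(p)
    if (l < best_loss) { best_loss <- l; best <- p }
  }
  fitted <- best[1] * elu(best[2] * (x - best[3])) + best[4]
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum((fitted - y)^2) / ss_tot
  structure(list(par = stats::setNames(best, c("a", "b", "x0", "c")),
                 r_squared = r2, fitted = fitted, x = x, y = y,
                 lr = lr, iters = iters, n_starts = n_starts),
            class = "elu_fit")
}

#' @export
print.elu_fit <- function(x, ...) {
  cat("ELU curve fit: y = a * ELU(b * (x - x0)) + c\n")
  cat("  a =", signif(x$par[["a"]], 4), " b =", signif(x$par[["b"]], 4),
      " x0 =", signif(x$par[["x0"]], 4), " c =", signif(x$par[["c"]], 4),
      "\n")
  cat("  R-squared:", signif(x$r_squared, 4), "\n")
  invisible(x)
}

#' @export
predict.elu_fit <- function(object, newdata = NULL, ...) {
  x <- newdata %||% object$x
  p <- object$par
  u <- p[["b"]] * (x - p[["x0"]])
  p[["a"]] * ifelse(u > 0, u, exp(pmin(u, 0)) - 1) + p[["c"]]
}

#' Rank-clustered ELU fit of SHAP values against insertion rates
#'
#' Drops zero rates (log10 undefined; no pseudocount is added), clusters
#' the remaining rates into `k` ranks, and fits the ELU curve to
#' (log10 mean rank rate, max rank SHAP).
#'
#' @param insertion_rates,shap Per-position rate and SHAP vectors.
#' @param k Number of ranks.
#' @param seed Seed for clustering and fit restarts.
#' @param ... Passed to [fit_elu()].
#' @return List: `ranks` (the clustered table), `fit` (an `elu_fit`).
#' @export
elu_upper_bound <- function(insertion_rates, shap, k = 50L, seed = 1L, ...) {
  keep <- insertion_rates > 0
  if (!any(keep)) stop("all insertion rates are zero")
  if (any(!keep))
    message(sum(!keep), " zero-rate positions dropped before log10")
  ranks <- rank_cluster_upper_bound(insertion_rates[keep], shap[keep],
                                    k = k, seed = seed)
  fit <- fit_elu(log10(ranks$mean_rate), ranks$max_shap, seed = seed, ...)
  list(ranks = ranks, fit = fit)
}
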