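## Kernel SHAP attribution of k-mer count features. Each prediction is
## treated as a cooperative game over the record's active features; masked
## features take their values from a background set. Exact Shapley values
## by subset enumeration when few features are active, otherwise the
## Kernel SHAP weighted-least-squares estimator with the efficiency
## constraint enforced, so local accuracy (phi0 + sum(phi) = f(x)) holds
## in both modes.

#' Kernel SHAP attribution for one instance
#'
#' @param predict_fn Function taking a numeric matrix (rows = instances)
#'   and returning a numeric vector of predictions.
#' @param x Numeric feature vector of the instance to explain.
#' @param background Numeric matrix of background rows (the "feature
#'   absent" reference distribution).
#' @param n_samples Number of sampled coalitions in the sampling estimator
#'   (at least `M + 2` for `M` active features).
#' @param active Indices of features to attribute over; defaults to the
#'   features whose value differs from at least one background row
#'   (all other features are null players with zero attribution).
#' @param exact_limit Use exact subset enumeration when the number of
#'   active features is at most this (capped at 20).
#' @param seed Seed for coalition sampling.
#' @return List of class `shap_attribution`: `phi` (per-feature values,
#'   zeros for inactive features), `phi0` (expected prediction over the
#'   background), `prediction` (`f(x)`), `active`, `mode`.
#' @export
kernel_shap <- function(predict_fn, x, background, n_samples = 2000L,
                        active = NULL, exact_limit = 12L, seed = 1L) {
  background <- as.matrix(background)
  if (!nrow(background)) stop("background set is empty")
  stopifnot(ncol(background) == length(x))
  if (is.null(active))
    active <- which(vapply(seq_along(x), function(j)
      any(background[, j] != x[j]), logical(1)))
  M <- length(active)
  fx <- predict_fn(matrix(x, nrow = 1L))
  if (!is.finite(fx)) stop("prediction for x is not finite")
  phi0 <- mean(predict_fn(background))
  phi <- numeric(length(x))
  names(phi) <- names(x)
  if (M == 0L)
    return(structure(list(phi = phi, phi0 = phi0, prediction = fx,
                          active = active, mode = "trivial"),
                     class = "shap_attribution"))

  # v(S): mean prediction with features outside S drawn from the background.
  # Coalitions are stacked into large prediction batches so predict_fn is
  # called few times (matters when it is itself a model forward pass).
  n_bg <- nrow(background)
  coalition_value <- function(Z) {
    # Z: logical matrix, rows = coalitions over the active features
    n_coal <- nrow(Z)
    per_chunk <- max(1L, floor(2e7 / (length(x) * n_bg)))
    vals <- numeric(n_coal)
    for (start in seq(1L, n_coal, by = per_chunk)) {
      idx <- start:min(start + per_chunk - 1L, n_coal)
      Xb <- background[rep(seq_len(n_bg), length(idx)), , drop = FALSE]
      for (k in seq_along(idx)) {
        rows <- (k - 1L) * n_bg + seq_len(n_bg)
        on_idx <- active[Z[idx[k], ]]
        Xb[rows, on_idx] <- matrix(x[on_idx], n_bg, length(on_idx),
                                   byrow = TRUE)
      }
      pr <- predict_fn(Xb)
      vals[idx] <- colMeans(matrix(pr, n_bg))
    }
    vals
  }

  if (M <= min(exact_limit, 20L)) {
    n_sub <- bitwShiftL(1L, M)
    Z <- matrix(FALSE, n_sub, M)
    for (j in seq_len(M))
      Z[, j] <- bitwAnd(seq_len(n_sub) - 1L, bitwShiftL(1L, j - 1L)) > 0L
    v <- coalition_value(Z)
    sizes <- rowSums(Z)
    w_size <- factorial(0:(M - 1)) * factorial(M - 1 - (0:(M - 1))) /
      factorial(M)
    for (j in seq_len(M)) {
      without <- which(!Z[, j])
      with_j <- without + bitwShiftL(1L, j - 1L)
      phi[active[j]] <- sum(w_size[sizes[without] + 1L] *
                              (v[with_j] - v[without]))
    }
    mode <- "exact"
  } else {
    if (n_samples < M + 2L) stop("n_samples must be at least M + 2")
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    # sample coalition sizes from the Shapley kernel size distribution,
    # uniform subsets within a size: the kernel weight is folded into the
    # sampling, so the regression is unweighted
    s_prob <- (M - 1) / ((1:(M - 1)) * (M - (1:(M - 1))))
    s_prob <- s_prob / sum(s_prob)
    sizes <- sample.int(M - 1L, n_samples, replace = TRUE, prob = s_prob)
    Z <- matrix(FALSE, n_samples, M)
    for (ci in seq_len(n_samples))
      Z[ci, sample.int(M, sizes[ci])] <- TRUE
    v <- coalition_value(Z)
    e <- fx - phi0
    # efficiency constraint eliminated through the last active feature
    zM <- Z[, M]
    y <- v - phi0 - zM * e
    D <- Z[, -M, drop = FALSE] - zM
    storage.mode(D) <- "double"
    A <- crossprod(D) + diag(1e-10, M - 1L)
    b_free <- solve(A, crossprod(D, y))
    phi_act <- c(drop(b_free), e - sum(b_free))
    phi[active] <- phi_act
    mode <- "sampling"
  }
  structure(list(phi = phi, phi0 = phi0, prediction = fx,
                 active = active, mode = mode),
            class = "shap_attribution")
}

#' @export
print.shap_attribution <- function(x, ...) {
  cat("Kernel SHAP attribution (", x$mode, " mode)\n", sep = "")
  cat("  phi0 =", signif(x$phi0, 5), "| f(x) =", signif(x$prediction, 5),
      "| active features:", length(x$active), "\n")
  cat("  local accuracy gap:",
      format(abs(x$phi0 + sum(x$phi) - x$prediction), digits = 3), "\n")
  invisible(x)
}

#' Attribute a random sample of records
#'
#' Draws a seeded subsample of the records (10% by default, mirroring the
#' usual interpretation workflow) and computes a Kernel SHAP attribution
#' for each over its non-zero k-mer features.
#'
#' @param object A fitted [sem()] model.
#' @param seqs Named character vector of sequences.
#' @param fraction Fraction of records to sample (in `(0, 1]`).
#' @param background_size Number of seeded background count vectors drawn
#'   from `seqs` (capped at the number of records).
#' @param n_samples,exact_limit Passed to [kernel_shap()].
#' @param seed Seed for the subsample, background and coalition sampling.
#' @return Named list of `shap_attribution` objects (names = record ids).
#' @export
sample_and_attribute <- function(object, seqs, fraction = 0.10,
                                 background_size = 100L,
                                 n_samples = 2000L, exact_limit = 12L,
                                 seed = 1L) {
  stopifnot(inherits(object, "sem"))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- length(seqs)
  take <- if (fraction == 1) seq_len(n)
          else sort(sample.int(n, max(1L, round(fraction * n))))
  X <- kmer_counts(seqs, object$vocabulary)
  storage.mode(X) <- "double"
  bg_idx <- sample.int(n, min(background_size, n))
  background <- X[bg_idx, , drop = FALSE]
  predict_fn <- function(M) {
    pmax(ridge_predict(object$ridge, .sem_design(object, M)), 1)
  }
  out <- vector("list", length(take))
  names(out) <- names(seqs)[take]
  for (i in seq_along(take)) {
    xi <- X[take[i], ]
    out[[i]] <- kernel_shap(predict_fn, xi, background,
                            n_samples = n_samples,
                            active = which(xi != 0),
                            exact_limit = exact_limit, seed = seed + i)
  }
  out
}
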