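## A dense multi-layer perceptron for regression, trained by Adam on the
## root-mean-squared-error loss. Written directly in matrix algebra: the
## whole network is a handful of GEMMs per pass, which BLAS handles well
## even at the full published architecture (six hidden layers of
## 489/926/645/929/582/82 units plus a linear output unit).

#' Construct an untrained MLP
#'
#' @param input_dim Number of input features.
#' @param layers Hidden layer sizes. A single linear output unit is always
#'   appended after the last hidden layer.
#' @param activations One activation name per hidden layer
#'   (see [activation()]).
#' @param seed Integer seed for the weight initialization.
#' @return Object of class `mlp`: weights `W`, biases `b`, `activations`
#'   (with the final "linear" output appended), `input_dim`.
#' @export
mlp_init <- function(input_dim,
                     layers = c(489L, 926L, 645L, 929L, 582L, 82L),
                     activations = c("gelu", "relu", "relu",
                                     "elu", "gelu", "linear"),
                     seed = 1L) {
  if (length(layers) != length(activations))
    stop("need one activation per hidden layer")
  dims <- c(input_dim, layers, 1L)
  acts <- c(activations, "linear")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  W <- vector("list", length(dims) - 1L)
  b <- vector("list", length(dims) - 1L)
  for (l in seq_along(W)) {
    # He-style scaling keeps the forward variance stable across depths
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L],
                                  sd = sqrt(2 / dims[l])),
                     dims[l], dims[l + 1L])
    b[[l]] <- numeric(dims[l + 1L])
  }
  structure(list(W = W, b = b, activations = acts, input_dim = input_dim),
            class = "mlp")
}

# save/restore the global RNG state so seeded constructors do not disturb
# the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# forward pass keeping pre-activations for backprop
.mlp_forward_full <- function(net, X) {
  A <- list(X)
  Z <- vector("list", length(net$W))
  for (l in seq_along(net$W)) {
    Z[[l]] <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    A[[l + 1L]] <- activation(net$activations[l], Z[[l]])
  }
  list(A = A, Z = Z)
}

#' Forward pass of an MLP
#'
#' @param net An `mlp` object.
#' @param X Numeric matrix (samples x features) or a single feature vector.
#' @return Numeric vector of predictions.
#' @export
mlp_forward <- function(net, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != net$input_dim)
    stop("input has ", ncol(X), " features; network expects ", net$input_dim)
  drop(.mlp_forward_full(net, X)$A[[length(net$W) + 1L]])
}

#' Train an MLP by Adam on the RMSE loss
#'
#' Minimizes `sqrt(mean((yhat - y)^2))` by mini-batch Adam. A fraction of
#' the data is held out as a validation set for early stopping (the weights
#' with the best validation RMSE are kept).
#'
#' @param X Numeric matrix, samples x features.
#' @param y Numeric response vector.
#' @param layers,activations,seed Passed to [mlp_init()]; seeding also
#'   fixes the batch shuffling, making training bit-reproducible.
#' @param lr Adam learning rate.
#' @param epochs Maximum number of epochs.
#' @param batch_size Mini-batch size.
#' @param weight_decay Decoupled (AdamW-style) L2 weight decay applied to
#'   the weight matrices (not the biases).
#' @param validation_fraction Held-out fraction for early stopping
#'   (0 disables early stopping).
#' @param patience Epochs without validation improvement before stopping.
#' @param lr_patience Epochs without validation improvement before the
#'   learning rate is halved (reduce-on-plateau schedule; the RMSE loss has
#'   scale-invariant gradients, so Adam needs a decaying step to settle).
#' @param verbose Print the loss every 10 epochs.
#' @return Trained `mlp` with a `loss_trace` element (per-epoch training
#'   RMSE) and `val_trace` when validation is enabled.
#' @export
mlp_train <- function(X, y, layers = c(489L, 926L, 645L, 929L, 582L, 82L),
                      activations = c("gelu", "relu", "relu",
                                      "elu", "gelu", "linear"),
                      lr = 1e-3, epochs = 200L, batch_size = 32L,
                      weight_decay = 0, validation_fraction = 0.1,
                      patience = 20L, lr_patience = 5L, seed = 1L,
                      verbose = FALSE) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 samples")
  stopifnot(length(y) == nrow(X))
  net <- mlp_init(ncol(X), layers, activations, seed = seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed + 1L)

  n <- nrow(X)
  n_val <- if (validation_fraction > 0) max(1L, round(validation_fraction * n))
           else 0L
  val_idx <- if (n_val > 0L && n - n_val >= 2L) sample.int(n, n_val)
             else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
  Xval <- X[val_idx, , drop = FALSE]; yval <- y[val_idx]

  nW <- length(net$W)
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(b) b * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  loss_trace <- numeric(0); val_trace <- numeric(0)
  best_val <- Inf; best <- NULL; wait <- 0L; lr_wait <- 0L
  lr_cur <- lr

  for (ep in seq_len(epochs)) {
    perm <- sample.int(nrow(Xtr))
    starts <- seq(1L, nrow(Xtr), by = batch_size)
    for (s in starts) {
      idx <- perm[s:min(s + batch_size - 1L, nrow(Xtr))]
      Xb <- Xtr[idx, , drop = FALSE]; yb <- ytr[idx]
      fw <- .mlp_forward_full(net, Xb)
      yhat <- drop(fw$A[[nW + 1L]])
      r <- yhat - yb
      rmse <- sqrt(mean(r^2))
      if (!is.finite(rmse))
        stop("NaN/Inf loss at epoch ", ep, "; lower the learning rate")
      # d RMSE / d yhat = r / (B * RMSE); guarded near zero loss
      dL <- matrix(r / (length(r) * max(rmse, 1e-12)), ncol = 1L)
      delta <- dL
      step <- step + 1L
      for (l in nW:1) {
        dZ <- delta * activation_grad(net$activations[l], fw$Z[[l]])
        gW <- crossprod(fw$A[[l]], dZ)
        gb <- colSums(dZ)
        if (l > 1L) delta <- dZ %*% t(net$W[[l]])
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        mhW <- mW[[l]] / (1 - beta1^step); vhW <- vW[[l]] / (1 - beta2^step)
        mhb <- mb[[l]] / (1 - beta1^step); vhb <- vb[[l]] / (1 - beta2^step)
        net$W[[l]] <- net$W[[l]] - lr_cur * (mhW / (sqrt(vhW) + eps) +
                                             weight_decay * net$W[[l]])
        net$b[[l]] <- net$b[[l]] - lr_cur * mhb / (sqrt(vhb) + eps)
      }
    }
    tr_rmse <- sqrt(mean((mlp_forward(net, Xtr) - ytr)^2))
    loss_trace <- c(loss_trace, tr_rmse)
    if (length(val_idx)) {
      v_rmse <- sqrt(mean((mlp_forward(net, Xval) - yval)^2))
      val_trace <- c(val_trace, v_rmse)
      if (v_rmse < best_val - 1e-10) {
        best_val <- v_rmse; best <- net[c("W", "b")]; wait <- 0L; lr_wait <- 0L
      } else {
        wait <- wait + 1L
        lr_wait <- lr_wait + 1L
        if (lr_wait >= lr_patience) { lr_cur <- lr_cur / 2; lr_wait <- 0L }
        if (wait >= patience) break
      }
    }
    if (verbose && ep %% 10L == 0L)
      message(sprintf("epoch %d: train RMSE %.4f", ep, tr_rmse))
  }
  if (!is.null(best)) { net$W <- best$W; net$b <- best$b }
  net$loss_trace <- loss_trace
  net$val_trace <- val_trace
  net
}
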