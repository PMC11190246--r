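## The stacked ensemble regressor for 16S gene copy number. Two base
## learners see the 6-mer count matrix: a deep MLP on the raw counts, and
## an RBF support vector regression on the top principal-component scores.
## A ridge meta-learner aggregates [mlp_pred, svr_pred, PCA scores] into
## the final copies/genome estimate. Published hyperparameters are the
## defaults: K = 6, 100 components, SVR C = 11 with gamma = 'auto'
## (1/n_components), ridge alpha = 49.

# ---- PCA ----------------------------------------------------------------

pca_fit <- function(X, n) {
  n <- as.integer(n)
  if (n > min(dim(X))) stop("pca_components exceeds min(n_samples, n_features)")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = n)
  structure(list(mean = mu, rotation = sv$v[, seq_len(n), drop = FALSE],
                 sdev = sv$d[seq_len(n)] / sqrt(max(1, nrow(X) - 1))),
            class = "gcn16_pca")
}

pca_transform <- function(pca, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  sweep(X, 2, pca$mean) %*% pca$rotation
}

# ---- ridge meta-learner -------------------------------------------------

#' Closed-form ridge regression with unpenalized intercept
#'
#' Solves `beta = (F'F + alpha I)^-1 F'y` on the centered design, with the
#' intercept recovered from the means (so the intercept carries no
#' penalty, matching the usual convention).
#'
#' @param F Numeric design matrix.
#' @param y Response vector.
#' @param alpha Ridge penalty (>= 0).
#' @return List with `coef` and `intercept`.
#' @export
ridge_fit <- function(F, y, alpha = 49) {
  F <- as.matrix(F)
  stopifnot(alpha >= 0, nrow(F) == length(y))
  mu <- colMeans(F); ybar <- mean(y)
  Fc <- sweep(F, 2, mu)
  beta <- solve(crossprod(Fc) + diag(alpha, ncol(F)), crossprod(Fc, y - ybar))
  list(coef = drop(beta), intercept = ybar - sum(mu * drop(beta)))
}

ridge_predict <- function(fit, F) {
  drop(as.matrix(F) %*% fit$coef) + fit$intercept
}

# ---- SVR (kernel machine persisted as plain arrays) ---------------------

svr_fit <- function(Z, y, cost = 11, gamma = 1 / ncol(Z), epsilon = 0.1) {
  fit <- e1071::svm(x = Z, y = y, type = "eps-regression", kernel = "radial",
                    cost = cost, gamma = gamma, epsilon = epsilon,
                    scale = FALSE, fitted = FALSE)
  if (is.null(fit$SV) || nrow(fit$SV) == 0L) {
    # every residual inside the epsilon tube (constant labels): the
    # machine reduces to its offset
    return(list(sv = matrix(0, 0L, ncol(Z)), coefs = numeric(0),
                rho = -mean(y), gamma = gamma))
  }
  list(sv = as.matrix(fit$SV), coefs = drop(fit$coefs), rho = fit$rho,
       gamma = gamma)
}

svr_predict <- function(svr, Z) {
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1L)
  if (nrow(svr$sv) == 0L) return(rep(-svr$rho, nrow(Z)))
  # k(a,b) = exp(-gamma ||a-b||^2); prediction = sum_i alpha_i k(z, sv_i) - rho
  d2 <- outer(rowSums(Z^2), rowSums(svr$sv^2), "+") - 2 * Z %*% t(svr$sv)
  drop(exp(-svr$gamma * pmax(d2, 0)) %*% svr$coefs) - svr$rho
}

# ---- the stacked ensemble ----------------------------------------------

#' Fit the stacked ensemble copy-number regressor
#'
#' Fits the k-mer vocabulary on the training sequences, trains the MLP on
#' the raw count matrix and the SVR on the principal-component scores, and
#' aggregates `[mlp_pred, svr_pred, scores]` with a ridge meta-learner.
#' With `stacking = "holdout"` the base learners are fit on 80%
#' of the training data and the ridge on their predictions for the other
#' 20%; the deployed base learners are refit on the full training set. `stacking = "insample"` fits the ridge on
#' in-sample base outputs, and `stacking = "oof"` on 5-fold out-of-fold
#' predictions.
#'
#' @param x Named character vector of DNA sequences (plus strand).
#' @param y Numeric copy-number labels (copies/genome), aligned with `x`.
#' @param K K-mer length.
#' @param pca_components Number of principal components (reduced with a
#'   message when the training set is too small to support it).
#' @param svr_cost,svr_gamma,svr_epsilon SVR hyperparameters;
#'   `svr_gamma = "auto"` means `1/pca_components`.
#' @param ridge_alpha Ridge penalty of the meta-learner.
#' @param mlp_layers,mlp_activations MLP architecture (see [mlp_train()]).
#' @param lr,epochs,batch_size MLP optimizer settings.
#' @param stacking `"oof"` (default), `"insample"` or `"holdout"`.
#' @param oof_folds Folds for out-of-fold stacking.
#' @param seed Integer seed controlling every random choice in the fit.
#' @return Object of class `sem`.
#' @seealso [predict.sem()], [contribution_fractions()], [sem_crossvalidate()]
#' @export
sem <- function(x, y, K = 6L, pca_components = 100L,
                svr_cost = 11, svr_gamma = "auto", svr_epsilon = 0.1,
                ridge_alpha = 49,
                mlp_layers = c(489L, 926L, 645L, 929L, 582L, 82L),
                mlp_activations = c("gelu", "relu", "relu",
                                    "elu", "gelu", "linear"),
                lr = 1e-3, epochs = 200L, batch_size = 32L,
                stacking = c("oof", "insample", "holdout"),
                oof_folds = 2L, seed = 1L) {
  stacking <- match.arg(stacking)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 2L) stop("need at least 2 training sequences")
  if (any(y < 1)) stop("copy-number labels must be >= 1")

  vocab <- kmer_vocabulary(x, K = K)
  X <- kmer_counts(x, vocab)
  storage.mode(X) <- "double"

  n_comp <- min(pca_components, nrow(X) - 1L, ncol(X))
  if (n_comp < pca_components)
    message("pca_components reduced to ", n_comp, " (small training set)")
  pca <- pca_fit(X, n_comp)
  Z <- pca_transform(pca, X)
  gamma <- if (identical(svr_gamma, "auto")) 1 / n_comp else svr_gamma

  mlp <- mlp_train(X, y, layers = mlp_layers, activations = mlp_activations,
                   lr = lr, epochs = epochs, batch_size = batch_size,
                   seed = seed)
  svr <- svr_fit(Z, y, cost = svr_cost, gamma = gamma, epsilon = svr_epsilon)

  if (stacking == "insample") {
    mlp_pred <- mlp_forward(mlp, X)
    svr_pred <- svr_predict(svr, Z)
    meta_idx <- seq_along(y)
  } else if (stacking == "holdout") {
    old <- .Random.seed_save()
    set.seed(seed + 1000L)
    meta_idx <- sort(sample.int(length(y), max(2L, round(0.2 * length(y)))))
    .Random.seed_restore(old)
    base_idx <- setdiff(seq_along(y), meta_idx)
    m_h <- mlp_train(X[base_idx, , drop = FALSE], y[base_idx],
                     layers = mlp_layers, activations = mlp_activations,
                     lr = lr, epochs = epochs, batch_size = batch_size,
                     seed = seed)
    s_h <- svr_fit(Z[base_idx, , drop = FALSE], y[base_idx],
                   cost = svr_cost, gamma = gamma, epsilon = svr_epsilon)
    mlp_pred <- mlp_forward(m_h, X[meta_idx, , drop = FALSE])
    svr_pred <- svr_predict(s_h, Z[meta_idx, , drop = FALSE])
  } else {
    # out-of-fold stacking: base learners refit per fold; meta sees
    # predictions for samples the bases never trained on
    folds <- stratified_folds(y, oof_folds, seed = seed)
    mlp_pred <- numeric(length(y)); svr_pred <- numeric(length(y))
    meta_idx <- seq_along(y)
    for (f in unique(folds)) {
      in_f <- folds == f
      m_f <- mlp_train(X[!in_f, , drop = FALSE], y[!in_f],
                       layers = mlp_layers, activations = mlp_activations,
                       lr = lr, epochs = epochs, batch_size = batch_size,
                       seed = seed + f)
      s_f <- svr_fit(Z[!in_f, , drop = FALSE], y[!in_f],
                     cost = svr_cost, gamma = gamma, epsilon = svr_epsilon)
      mlp_pred[in_f] <- mlp_forward(m_f, X[in_f, , drop = FALSE])
      svr_pred[in_f] <- svr_predict(s_f, Z[in_f, , drop = FALSE])
    }
  }

  Fmat <- cbind(mlp = mlp_pred, svr = svr_pred,
                Z[meta_idx, , drop = FALSE])
  ridge <- ridge_fit(Fmat, y[meta_idx], alpha = ridge_alpha)

  obj <- structure(list(
    vocabulary = vocab, pca = pca, mlp = mlp, svr = svr, ridge = ridge,
    config = list(K = K, pca_components = n_comp, svr_cost = svr_cost,
                  svr_gamma = gamma, svr_epsilon = svr_epsilon,
                  ridge_alpha = ridge_alpha, mlp_layers = mlp_layers,
                  mlp_activations = mlp_activations, lr = lr,
                  epochs = epochs, batch_size = batch_size,
                  stacking = stacking, oof_folds = oof_folds, seed = seed),
    n_train = length(y)), class = "sem")
  obj$train_rmse <- rmse(predict(obj, x), y)
  obj
}

# base-learner outputs and meta design for a count matrix
.sem_design <- function(object, X) {
  Z <- pca_transform(object$pca, X)
  cbind(mlp = mlp_forward(object$mlp, X),
        svr = svr_predict(object$svr, Z), Z)
}

#' Predict copy numbers for new sequences
#'
#' @param object A fitted [sem()] model.
#' @param newdata Named character vector of DNA sequences.
#' @param clamp Clamp predictions to >= 1 copy/genome (a detected genome
#'   carries at least one 16S copy). Predictions are never rounded.
#' @param ... Unused.
#' @return Numeric vector of copies/genome, named by record. Sequences
#'   shorter than K yield `NA` with a warning rather than failing the batch.
#' @export
predict.sem <- function(object, newdata, clamp = TRUE, ...) {
  seqs <- newdata
  too_short <- nchar(seqs) < object$config$K
  if (any(too_short))
    warning(sum(too_short), " sequence(s) shorter than K = ",
            object$config$K, "; returning NA for them")
  out <- rep(NA_real_, length(seqs))
  names(out) <- names(seqs)
  if (any(!too_short)) {
    X <- kmer_counts(seqs[!too_short], object$vocabulary)
    storage.mode(X) <- "double"
    pred <- ridge_predict(object$ridge, .sem_design(object, X))
    if (clamp) pred <- pmax(pred, 1)
    out[!too_short] <- pred
  }
  out
}

#' @export
print.sem <- function(x, ...) {
  cat("Stacked ensemble 16S copy-number model\n")
  cat("  training sequences:", x$n_train,
      "| k-mer vocabulary:", length(x$vocabulary$kmers),
      paste0("(K = ", x$config$K, ")"), "\n")
  cat("  MLP:", paste(x$config$mlp_layers, collapse = "-"), "+ linear out |",
      "PCA components:", x$config$pca_components, "\n")
  cat("  SVR: C =", x$config$svr_cost, ", gamma =",
      signif(x$config$svr_gamma, 3),
      "| ridge alpha =", x$config$ridge_alpha,
      paste0("(", x$config$stacking, " stacking)"), "\n")
  cat("  training RMSE:", signif(x$train_rmse, 4), "copies/genome\n")
  invisible(x)
}

#' @export
summary.sem <- function(object, ...) {
  ans <- list(config = object$config, n_train = object$n_train,
              train_rmse = object$train_rmse,
              ridge_coef = coef(object),
              n_support_vectors = nrow(object$svr$sv),
              mlp_epochs_run = length(object$mlp$loss_trace),
              final_mlp_loss = utils::tail(object$mlp$loss_trace, 1))
  class(ans) <- "summary.sem"
  ans
}

#' @export
print.summary.sem <- function(x, ...) {
  cat("Stacked ensemble model on", x$n_train, "sequences\n")
  cat("Training RMSE:", signif(x$train_rmse, 4), "copies/genome\n")
  cat("MLP epochs run:", x$mlp_epochs_run,
      "| final training loss:", signif(x$final_mlp_loss, 4), "\n")
  cat("SVR support vectors:", x$n_support_vectors, "\n")
  cat("Ridge coefficients (meta-learner):\n")
  cat("  mlp:", signif(x$ridge_coef[["mlp"]], 4),
      " svr:", signif(x$ridge_coef[["svr"]], 4),
      " |pca| max:", signif(max(abs(x$ridge_coef[-(1:2)])), 4), "\n")
  invisible(x)
}

#' @export
coef.sem <- function(object, ...) {
  cf <- object$ridge$coef
  names(cf) <- c("mlp", "svr", paste0("PC", seq_len(length(cf) - 2L)))
  c(`(Intercept)` = object$ridge$intercept, cf)
}

#' Feature-extractor contribution fractions
#'
#' Decomposes a prediction into the shares contributed by each feature
#' extractor, by weighing each extractor's output with its ridge
#' coefficient and dividing by the final (pre-clamp) output: the MLP term,
#' the SVR term, the summed PCA-score terms and the intercept. The four
#' fractions sum to 1 exactly.
#'
#' @param object A fitted [sem()] model.
#' @param newdata Character vector of sequences.
#' @return Data frame with columns mlp, svr, pca, intercept (one row per
#'   sequence).
#' @export
contribution_fractions <- function(object, newdata) {
  stopifnot(inherits(object, "sem"))
  X <- kmer_counts(newdata, object$vocabulary)
  storage.mode(X) <- "double"
  F <- .sem_design(object, X)
  beta <- object$ridge$coef
  final <- ridge_predict(object$ridge, F)
  if (any(final == 0)) stop("final prediction is zero; fractions undefined")
  data.frame(
    mlp = beta[1] * F[, 1] / final,
    svr = beta[2] * F[, 2] / final,
    pca = drop(F[, -(1:2), drop = FALSE] %*% beta[-(1:2)]) / final,
    intercept = object$ridge$intercept / final,
    row.names = names(newdata))
}

# ---- evaluation ---------------------------------------------------------

#' Root-mean-squared error
#' @param pred,truth Numeric vectors.
#' @return `sqrt(mean((pred - truth)^2))`.
#' @export
rmse <- function(pred, truth) sqrt(mean((pred - truth)^2))

#' Coefficient of determination
#' @param pred,truth Numeric vectors.
#' @return `1 - SS_res / SS_tot`.
#' @export
r_squared <- function(pred, truth) {
  1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2)
}

#' Fold assignment stratified by label quantile
#'
#' Assigns each sample to one of `folds` folds such that every fold spans
#' the label distribution (round-robin within label-quantile strata).
#'
#' @param y Numeric labels.
#' @param folds Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id per sample.
#' @export
stratified_folds <- function(y, folds = 5L, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # within each label-quantile stratum, deal fold labels round-robin
  strata <- cut(rank(y, ties.method = "random"), folds, labels = FALSE)
  fold <- integer(length(y))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

#' Cross-validated RMSE of the stacked ensemble
#'
#' K-fold cross-validation with folds stratified by label quantile.
#'
#' @param x Named character vector of sequences.
#' @param y Numeric labels.
#' @param folds Number of folds (>= 2).
#' @param seed Seed for fold assignment and fits.
#' @param ... Passed to [sem()].
#' @return List: `fold_rmse`, `mean`, `sd`, `predictions` (out-of-fold).
#' @export
sem_crossvalidate <- function(x, y, folds = 5L, seed = 1L, ...) {
  if (folds < 2L) stop("folds must be >= 2")
  fold <- stratified_folds(y, folds, seed = seed)
  if (min(table(fold)) < 2L) stop("a fold has fewer than 2 samples")
  per <- numeric(folds)
  oof <- rep(NA_real_, length(y))
  for (f in seq_len(folds)) {
    in_f <- fold == f
    fit <- sem(x[!in_f], y[!in_f], seed = seed + f, ...)
    p <- predict(fit, x[in_f])
    per[f] <- rmse(p, y[in_f])
    oof[in_f] <- p
  }
  list(fold_rmse = per, mean = mean(per), sd = stats::sd(per),
       predictions = oof, fold = fold)
}
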