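# small stacked-ensemble fits throughout: a compact MLP and few principal
# components keep each fit under a couple of seconds
fit_small_sem <- function(seqs, y, seed = 1, ...) {
  sem(seqs, y, mlp_layers = c(24L, 12L), mlp_activations = c("gelu", "relu"),
      epochs = 40, batch_size = 16, pca_components = 20, seed = seed, ...)
}

sim_small <- function(seed = 31, n = 70) {
  simulate_gcn_dataset(n_tips = n, seed = seed)
}

test_that("closed-form ridge equals OLS at alpha 0 and shrinks correctly", {
  set.seed(1)
  F <- matrix(rnorm(40 * 3), 40)
  y <- drop(F %*% c(1, -1, 2)) + rnorm(40, sd = 0.1) + 5
  r0 <- ridge_fit(F, y, alpha = 0)
  ols <- lm.fit(cbind(1, F), y)$coefficients
  expect_equal(unname(c(r0$intercept, r0$coef)), unname(ols),
               tolerance = 1e-10)
  rbig <- ridge_fit(F, y, alpha = 1e9)
  expect_lt(max(abs(rbig$coef)), 1e-5)
  expect_equal(rbig$intercept, mean(y), tolerance = 1e-3)
})

test_that("ridge closed form matches an iterative solver", {
  set.seed(2)
  F <- matrix(rnorm(30 * 4), 30)
  y <- rnorm(30)
  alpha <- 3
  cf <- ridge_fit(F, y, alpha)
  obj <- function(p) {
    b0 <- p[1]; b <- p[-1]
    sum((y - b0 - drop(F %*% b))^2) + alpha * sum(b^2)
  }
  it <- optim(rep(0, 5), obj, method = "BFGS",
              control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(unname(c(cf$intercept, cf$coef)), it$par, tolerance = 1e-6)
})

test_that("PCA basis is exact on planar data and orthonormal", {
  set.seed(3)
  B <- matrix(rnorm(2 * 6), 2)
  X <- matrix(rnorm(50 * 2), 50) %*% B  # rank-2 data in 6 dims
  p <- gcn16:::pca_fit(X, 2)
  Z <- gcn16:::pca_transform(p, X)
  recon <- sweep(Z %*% t(p$rotation), 2, p$mean, "+")
  expect_lt(max(abs(recon - X)), 1e-10)
  expect_equal(crossprod(p$rotation), diag(2), tolerance = 1e-8)
  expect_lt(max(abs(gcn16:::pca_transform(p, p$mean))), 1e-10)
  p3 <- gcn16:::pca_fit(X, 4)
  expect_true(all(diff(p3$sdev) <= 1e-8))
  expect_error(gcn16:::pca_fit(X, 10), "exceeds")
})

test_that("manual RBF-SVR prediction matches e1071 and handles constants", {
  set.seed(4)
  Z <- matrix(rnorm(40 * 5), 40)
  y <- sin(Z[, 1]) + rnorm(40, sd = 0.05)
  s <- gcn16:::svr_fit(Z, y, cost = 11, gamma = 0.2, epsilon = 0.1)
  ref <- e1071::svm(x = Z, y = y, type = "eps-regression",
                    kernel = "radial", cost = 11, gamma = 0.2,
                    epsilon = 0.1, scale = FALSE)
  Znew <- matrix(rnorm(10 * 5), 10)
  expect_equal(gcn16:::svr_predict(s, Znew),
               unname(predict(ref, Znew)), tolerance = 1e-8)
  sc <- gcn16:::svr_fit(Z, rep(2, 40))
  expect_lt(max(abs(gcn16:::svr_predict(sc, Z) - 2)), 0.1 + 1e-6)
})

test_that("SVR on 20 smooth-function points beats the mean predictor", {
  set.seed(5)
  z <- matrix(seq(-2, 2, length.out = 20), ncol = 1)
  y <- z[, 1]^2
  s <- gcn16:::svr_fit(z, y, cost = 11, gamma = 1, epsilon = 0.01)
  ztest <- matrix(seq(-1.9, 1.9, length.out = 15), ncol = 1)
  ytest <- ztest[, 1]^2
  expect_lt(rmse(gcn16:::svr_predict(s, ztest), ytest),
            rmse(rep(mean(y), 15), ytest))
})

test_that("the fitted ensemble predicts finite in-range values", {
  sim <- sim_small()
  fit <- fit_small_sem(sim$sequences, sim$labels)
  p <- predict(fit, sim$sequences)
  expect_true(all(is.finite(p)))
  expect_true(all(p >= 1 & p <= 30))
  expect_output(print(fit), "Stacked ensemble")
  expect_output(print(summary(fit)), "Ridge coefficients")
  expect_length(coef(fit), 2 + fit$config$pca_components + 1)
})

test_that("prediction is deterministic, order-invariant, batch-invariant", {
  sim <- sim_small()
  fit <- fit_small_sem(sim$sequences, sim$labels)
  p1 <- predict(fit, sim$sequences)
  perm <- sample(length(sim$sequences))
  p2 <- predict(fit, sim$sequences[perm])
  expect_equal(p2, p1[perm], tolerance = 1e-12)
  one_by_one <- vapply(seq_along(sim$sequences), function(i)
    predict(fit, sim$sequences[i]), numeric(1))
  expect_equal(unname(p1), one_by_one, tolerance = 1e-9)
  # identical sequences, identical predictions
  dup <- c(a = sim$sequences[[1]], b = sim$sequences[[1]])
  pd <- predict(fit, dup)
  expect_identical(unname(pd[1]), unname(pd[2]))
})

test_that("refitting with one seed reproduces predictions exactly", {
  sim <- sim_small(seed = 32, n = 50)
  f1 <- fit_small_sem(sim$sequences, sim$labels, seed = 9)
  f2 <- fit_small_sem(sim$sequences, sim$labels, seed = 9)
  expect_identical(predict(f1, sim$sequences), predict(f2, sim$sequences))
})

test_that("sequences shorter than K give per-record NA, not batch failure", {
  sim <- sim_small(seed = 33, n = 50)
  fit <- fit_small_sem(sim$sequences, sim$labels)
  q <- c(ok = sim$sequences[[1]], short = "ACG")
  expect_warning(p <- predict(fit, q), "shorter than K")
  expect_true(is.finite(p[["ok"]]))
  expect_true(is.na(p[["short"]]))
})

test_that("contribution fractions sum to one and respect zeroed paths", {
  sim <- sim_small(seed = 34, n = 60)
  fit <- fit_small_sem(sim$sequences, sim$labels)
  cf <- contribution_fractions(fit, sim$sequences[1:10])
  expect_equal(unname(rowSums(cf)), rep(1, 10), tolerance = 1e-9)
  # zero out svr and pca paths: mlp + intercept must carry everything
  fit0 <- fit
  fit0$ridge$coef[-1] <- 0
  cf0 <- contribution_fractions(fit0, sim$sequences[1:5])
  expect_equal(unname(cf0$mlp + cf0$intercept), rep(1, 5), tolerance = 1e-9)
  expect_equal(unname(cf0$svr), rep(0, 5))
})

test_that("the model archive round-trips through plain text", {
  sim <- sim_small(seed = 35, n = 50)
  fit <- fit_small_sem(sim$sequences, sim$labels)
  dir <- tempfile("semarchive")
  write_sem(fit, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  # text-only archive
  for (f in list.files(dir, full.names = TRUE))
    expect_true(grepl("\\.(json|txt)$", f))
  back <- read_sem(dir)
  expect_equal(predict(back, sim$sequences), predict(fit, sim$sequences),
               tolerance = 1e-10)
})

test_that("RMSE and R-squared obey their identities", {
  y <- c(2, 4, 6, 8)
  expect_identical(rmse(y, y), 0)
  expect_identical(rmse(y + 1, y), 1)
  # mean predictor: RMSE equals the biased population SD
  expect_equal(rmse(rep(mean(y), 4), y), sqrt(mean((y - mean(y))^2)))
  expect_equal(r_squared(y, y), 1)
})

test_that("cross-validation assigns stratified folds and reports spread", {
  sim <- sim_small(seed = 36, n = 60)
  f <- stratified_folds(sim$labels, 3, seed = 1)
  expect_identical(sort(unique(f)), 1:3)
  # each fold spans the label range: no fold misses the top/bottom tercile
  terc <- cut(sim$labels, quantile(sim$labels, c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE, labels = FALSE)
  expect_true(all(table(f, terc) > 0))
  expect_error(sem_crossvalidate(sim$sequences, sim$labels, folds = 1),
               ">= 2")
})

test_that("rare high-copy labels are underestimated (regression to the bulk)", {
  sim <- sim_small(seed = 37, n = 120)
  # plant a rare high tail: a handful of tips get a large copy-number boost
  set.seed(38)
  y <- sim$labels
  tail_ids <- sample(names(y), 8)
  y[tail_ids] <- y[tail_ids] + 8
  fit <- fit_small_sem(sim$sequences, y, seed = 3)
  pred <- predict(fit, sim$sequences)
  top <- names(sort(y, decreasing = TRUE))[1:12]   # top label decile
  expect_lt(mean(pred[top] - y[top]), 0)
})
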