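## Plain-text model archive: a directory with a JSON manifest (config,
## shapes, vocabulary) and one whitespace-delimited text file per numeric
## array. Versioned so later formats can stay readable.

.write_mat <- function(m, path) {
  utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
}
.read_mat <- function(path, nrow, ncol) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == nrow, ncol(m) == ncol)
  m
}

#' Save a fitted stacked ensemble to a directory
#'
#' @param object A [sem()] model.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sem <- function(object, dir) {
  stopifnot(inherits(object, "sem"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format_version = 1L,
    config = object$config,
    n_train = object$n_train,
    train_rmse = object$train_rmse,
    vocabulary = list(K = object$vocabulary$K, kmers = object$vocabulary$kmers),
    mlp_dims = vapply(object$mlp$W, nrow, integer(1)),
    mlp_out_dims = vapply(object$mlp$W, ncol, integer(1)),
    mlp_activations = object$mlp$activations,
    n_sv = nrow(object$svr$sv),
    svr_rho = object$svr$rho, svr_gamma = object$svr$gamma,
    ridge_intercept = object$ridge$intercept)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (l in seq_along(object$mlp$W)) {
    .write_mat(object$mlp$W[[l]], file.path(dir, sprintf("mlp_W%d.txt", l)))
    .write_mat(object$mlp$b[[l]], file.path(dir, sprintf("mlp_b%d.txt", l)))
  }
  .write_mat(object$pca$mean, file.path(dir, "pca_mean.txt"))
  .write_mat(object$pca$rotation, file.path(dir, "pca_rotation.txt"))
  .write_mat(object$svr$sv, file.path(dir, "svr_sv.txt"))
  .write_mat(object$svr$coefs, file.path(dir, "svr_coefs.txt"))
  .write_mat(object$ridge$coef, file.path(dir, "ridge_coef.txt"))
  invisible(dir)
}

#' Load a stacked ensemble saved by [write_sem()]
#'
#' @param dir Archive directory.
#' @return A `sem` object usable with [predict.sem()].
#' @export
read_sem <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  if (man$format_version != 1L)
    stop("unsupported model archive version: ", man$format_version)
  nl <- length(man$mlp_dims)
  W <- vector("list", nl); b <- vector("list", nl)
  for (l in seq_len(nl)) {
    W[[l]] <- .read_mat(file.path(dir, sprintf("mlp_W%d.txt", l)),
                        man$mlp_dims[l], man$mlp_out_dims[l])
    b[[l]] <- drop(.read_mat(file.path(dir, sprintf("mlp_b%d.txt", l)),
                             man$mlp_out_dims[l], 1L))
  }
  vocab <- structure(list(K = man$vocabulary$K, kmers = man$vocabulary$kmers),
                     class = "kmer_vocabulary")
  p <- length(vocab$kmers)
  n_comp <- man$config$pca_components
  structure(list(
    vocabulary = vocab,
    pca = structure(list(mean = drop(.read_mat(file.path(dir, "pca_mean.txt"),
                                               p, 1L)),
                         rotation = .read_mat(file.path(dir,
                                                        "pca_rotation.txt"),
                                              p, n_comp)),
                    class = "gcn16_pca"),
    mlp = structure(list(W = W, b = b, activations = man$mlp_activations,
                         input_dim = p, loss_trace = numeric(0)),
                    class = "mlp"),
    svr = list(sv = .read_mat(file.path(dir, "svr_sv.txt"),
                              man$n_sv, n_comp),
               coefs = drop(.read_mat(file.path(dir, "svr_coefs.txt"),
                                      man$n_sv, 1L)),
               rho = man$svr_rho, gamma = man$svr_gamma),
    ridge = list(coef = drop(.read_mat(file.path(dir, "ridge_coef.txt"),
                                       n_comp + 2L, 1L)),
                 intercept = man$ridge_intercept),
    config = man$config, n_train = man$n_train,
    train_rmse = man$train_rmse), class = "sem")
}
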