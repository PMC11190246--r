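## Taxonomy-based copy-number baseline. Training lineages form a
## hierarchical tree (root above the domain rank); every terminal taxon
## pools its sequences' labels by mean, and every internal node takes the
## unweighted mean of its child taxa (not of its leaves), mirroring the
## pan-taxa aggregation used by taxonomy-based GCN tools. Queries descend
## the tree and receive the value of the deepest matched node.

.path_sep <- "\r"  # never appears in taxon names

#' Fit the taxonomy-aggregation estimator
#'
#' @param lineages Data frame of ranked taxon names, one row per training
#'   sequence, columns ordered from the highest rank (e.g. domain) to the
#'   lowest (species). `NA` or `""` marks an unassigned rank; assigned
#'   ranks must be contiguous from the top.
#' @param labels Numeric copy-number labels aligned with the rows.
#' @param weighted If `TRUE`, internal nodes average their children
#'   weighted by leaf counts instead of the default mean-of-child-taxa.
#' @return Object of class `taxonomy_tree`.
#' @export
taxonomy_tree <- function(lineages, labels, weighted = FALSE) {
  lineages <- as.data.frame(lineages)
  id_col <- which(tolower(names(lineages)) == "id")
  if (length(id_col)) lineages <- lineages[, -id_col, drop = FALSE]
  stopifnot(nrow(lineages) == length(labels))
  ranks <- names(lineages)
  mat <- as.matrix(lineages)
  mat[mat == ""] <- NA
  if (all(is.na(mat))) stop("all lineages are empty")

  depth <- apply(mat, 1L, function(r) {
    assigned <- !is.na(r)
    d <- sum(assigned)
    if (d > 0L && any(!assigned[seq_len(d)]))
      stop("rank order violation: unassigned rank above an assigned one")
    d
  })
  if (any(depth == 0L)) stop("empty lineage at row ", which(depth == 0L)[1])

  # terminal taxon of each sequence = its deepest assigned path
  paths <- vapply(seq_len(nrow(mat)), function(i)
    paste(mat[i, seq_len(depth[i])], collapse = .path_sep), character(1))
  pooled <- tapply(labels, paths, mean)  # duplicate terminal taxa pooled

  # collect every node path (all prefixes of every terminal path)
  node_paths <- unique(unlist(lapply(strsplit(names(pooled), .path_sep,
                                              fixed = TRUE),
                                     function(p) vapply(seq_along(p),
                                       function(d) paste(p[seq_len(d)],
                                                         collapse = .path_sep),
                                       character(1)))))
  node_depth <- lengths(strsplit(node_paths, .path_sep, fixed = TRUE))
  parent <- vapply(strsplit(node_paths, .path_sep, fixed = TRUE), function(p)
    if (length(p) == 1L) "" else paste(p[-length(p)], collapse = .path_sep),
    character(1))

  value <- stats::setNames(rep(NA_real_, length(node_paths)), node_paths)
  n_leaves <- stats::setNames(integer(length(node_paths)), node_paths)
  for (d in sort(unique(node_depth), decreasing = TRUE)) {
    for (np in node_paths[node_depth == d]) {
      kids <- node_paths[parent == np]
      vals <- value[kids]; lv <- n_leaves[kids]
      if (np %in% names(pooled)) {
        # direct sequences at this taxon act as one pseudo-child
        vals <- c(vals, pooled[[np]])
        lv <- c(lv, sum(paths == np))
      }
      value[np] <- if (weighted) sum(vals * lv) / sum(lv) else mean(vals)
      n_leaves[np] <- sum(lv)
    }
  }
  roots <- node_paths[node_depth == 1L]
  root_value <- if (weighted) {
    sum(value[roots] * n_leaves[roots]) / sum(n_leaves[roots])
  } else mean(value[roots])

  structure(list(ranks = ranks, value = value, n_leaves = n_leaves,
                 parent = parent, root_value = root_value,
                 weighted = weighted),
            class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("Taxonomy-aggregation copy-number estimator\n")
  cat("  ranks:", paste(x$ranks, collapse = " > "), "\n")
  cat("  nodes:", length(x$value), "| root mean:",
      signif(x$root_value, 4), "copies/genome",
      if (x$weighted) "(leaf-weighted)" else "(mean of sub-taxa)", "\n")
  invisible(x)
}

#' Predict copy numbers from query lineages
#'
#' Each query descends the tree while its ranks match; the value of the
#' deepest matched node is returned. Unassigned or unmatched ranks fall
#' back to the deepest matched ancestor; a fully unmatched lineage gets the
#' root mean. A query never fails.
#'
#' @param object A [taxonomy_tree()].
#' @param newdata Data frame of ranked lineages (same column convention as
#'   for fitting).
#' @param ... Unused.
#' @return Numeric vector of predictions, one per row.
#' @export
predict.taxonomy_tree <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  id_col <- which(tolower(names(newdata)) == "id")
  if (length(id_col)) newdata <- newdata[, -id_col, drop = FALSE]
  mat <- as.matrix(newdata)
  mat[mat == ""] <- NA
  vapply(seq_len(nrow(mat)), function(i) {
    path <- ""
    val <- object$root_value
    for (name in mat[i, ]) {
      if (is.na(name)) break
      cand <- if (path == "") name else paste(path, name, sep = .path_sep)
      if (!cand %in% names(object$value)) break
      path <- cand
      val <- object$value[[cand]]
    }
    val
  }, numeric(1))
}

#' Export the aggregated copy-number table
#'
#' One row per taxon with its rank, aggregated value and leaf count —
#' the same shape as precomputed "pan-taxa" GCN tables.
#'
#' @param object A [taxonomy_tree()].
#' @return Data frame with columns lineage, rank, gcn, n_leaves.
#' @export
taxonomy_table <- function(object) {
  parts <- strsplit(names(object$value), .path_sep, fixed = TRUE)
  data.frame(
    lineage = vapply(parts, paste, character(1), collapse = ";"),
    rank = object$ranks[lengths(parts)],
    gcn = unname(object$value),
    n_leaves = unname(object$n_leaves),
    stringsAsFactors = FALSE)
}
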