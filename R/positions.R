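## Projection of k-mer attributions onto reference coordinates of a
## multiple sequence alignment, and per-locus mutation rates relative to a
## reference row. Reference positions are 1-based; alignment columns where
## the reference is gapped (insertions relative to the reference) attach
## to the preceding reference position, and insertion columns before the
## first reference base are ignored.

.split_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# per-column reference position (0 for columns before the first reference
# base), and the reference position of each non-gap reference column
.ref_coordinates <- function(ref_row) {
  chars <- .split_chars(ref_row)
  non_gap <- chars != "-"
  ref_pos <- cumsum(non_gap)          # gap columns inherit preceding position
  list(ref_pos = ref_pos, is_ref = non_gap, n_ref = sum(non_gap))
}

#' Map a k-mer attribution onto reference positions
#'
#' Every occurrence of a k-mer in the record adds that k-mer's SHAP value
#' to each of the K sequence positions it covers (set `split = TRUE` to
#' spread `phi/K` instead); position sums are then translated through the
#' alignment to reference coordinates.
#'
#' @param attribution A `shap_attribution` whose `phi` is named by k-mer.
#' @param seq The record's ungapped sequence.
#' @param alignment Named character vector of equal-length gapped rows,
#'   containing the record and the reference.
#' @param record_id,reference_id Row names in `alignment`.
#' @param K K-mer length.
#' @param split Spread `phi/K` per covered position instead of full `phi`.
#' @return Numeric vector of length `n_ref` (per-reference-position summed
#'   contribution for this record).
#' @export
map_shap_to_positions <- function(attribution, seq, alignment,
                                  record_id, reference_id, K = 6L,
                                  split = FALSE) {
  if (!record_id %in% names(alignment)) stop("record not in alignment")
  if (!reference_id %in% names(alignment)) stop("reference not in alignment")
  row <- alignment[[record_id]]
  ungapped <- gsub("-", "", row, fixed = TRUE)
  if (ungapped != toupper(seq))
    stop("alignment row does not match the record sequence")
  phi <- attribution$phi
  L <- nchar(seq)
  pos_contrib <- numeric(L)
  if (L >= K) {
    km <- kmerize(seq, K)
    phi_k <- phi[km]
    phi_k[is.na(phi_k)] <- 0
    add <- if (split) phi_k / K else phi_k
    for (i in which(add != 0)) {
      idx <- i:(i + K - 1L)
      pos_contrib[idx] <- pos_contrib[idx] + add[i]
    }
  }
  rc <- .ref_coordinates(alignment[[reference_id]])
  row_chars <- .split_chars(row)
  col_of_pos <- which(row_chars != "-")     # ungapped position -> column
  out <- numeric(rc$n_ref)
  refp <- rc$ref_pos[col_of_pos]            # ungapped position -> ref pos
  keep <- refp >= 1L
  for (i in which(keep)) out[refp[i]] <- out[refp[i]] + pos_contrib[i]
  out
}

#' Aggregate per-position attributions over records
#'
#' @param attributions Named list of attributions (ids matching rows of
#'   `alignment`), as produced by [sample_and_attribute()].
#' @param seqs Named character vector of the ungapped record sequences.
#' @param alignment,reference_id,K,split As in [map_shap_to_positions()].
#' @return Data frame: `position`, `mean_abs_shap` (mean over records of
#'   the absolute per-position sum) and `rms_shap`
#'   (`sqrt(mean(sum^2))`).
#' @export
aggregate_shap_positions <- function(attributions, seqs, alignment,
                                     reference_id, K = 6L, split = FALSE) {
  ids <- names(attributions)
  mats <- vapply(ids, function(id)
    map_shap_to_positions(attributions[[id]], seqs[[id]], alignment,
                          id, reference_id, K = K, split = split),
    numeric(.ref_coordinates(alignment[[reference_id]])$n_ref))
  mats <- matrix(mats, ncol = length(ids))
  data.frame(position = seq_len(nrow(mats)),
             mean_abs_shap = rowMeans(abs(mats)),
             rms_shap = sqrt(rowMeans(mats^2)))
}

#' Per-locus substitution, deletion and insertion rates
#'
#' For every reference (non-gap) column: the substitution rate is the
#' fraction of non-gap residues differing from the reference base; the
#' deletion rate is the fraction of gapped rows. The insertion rate at
#' reference position p is the fraction of rows carrying at least one
#' residue in the reference-gap columns between p and p+1.
#'
#' @param alignment Named character vector of equal-length gapped rows.
#' @param reference_id Name of the reference row.
#' @return Data frame: position, ref_base, substitution_rate,
#'   deletion_rate, insertion_rate.
#' @export
mutation_rates <- function(alignment, reference_id) {
  if (!reference_id %in% names(alignment)) stop("reference id not found")
  rows <- lapply(alignment, .split_chars)
  len <- unique(lengths(rows))
  if (length(len) != 1L) stop("alignment rows differ in length")
  A <- do.call(rbind, rows)
  N <- nrow(A)
  rc <- .ref_coordinates(alignment[[reference_id]])
  ref_chars <- .split_chars(alignment[[reference_id]])
  ref_cols <- which(rc$is_ref)
  n_ref <- rc$n_ref

  sub_rate <- del_rate <- numeric(n_ref)
  for (p in seq_len(n_ref)) {
    col <- A[, ref_cols[p]]
    non_gap <- col != "-"
    del_rate[p] <- sum(!non_gap) / N
    sub_rate[p] <- if (any(non_gap))
      sum(col[non_gap] != ref_chars[ref_cols[p]]) / sum(non_gap) else 0
  }
  ins_rate <- numeric(n_ref)
  ins_cols <- which(!rc$is_ref & rc$ref_pos >= 1L)
  if (length(ins_cols)) {
    for (p in unique(rc$ref_pos[ins_cols])) {
      cols <- ins_cols[rc$ref_pos[ins_cols] == p]
      occupied <- rowSums(A[, cols, drop = FALSE] != "-") > 0
      ins_rate[p] <- sum(occupied) / N
    }
  }
  data.frame(position = seq_len(n_ref),
             ref_base = ref_chars[ref_cols],
             substitution_rate = sub_rate,
             deletion_rate = del_rate,
             insertion_rate = ins_rate)
}

#' Cluster rates into ranks and take per-rank upper bounds
#'
#' One-dimensional k-means (seeded k-means++ initialization) on the rates;
#' each cluster reports its mean rate and the maximum SHAP value among its
#' members — the rank-wise upper envelope used for curve fitting.
#'
#' @param rates Numeric vector (e.g. insertion rates).
#' @param shap Numeric vector of the same length (e.g. per-position RMS
#'   SHAP).
#' @param k Number of ranks; reduced with a warning if there are fewer
#'   distinct rates.
#' @param seed Seed for the initialization.
#' @return Data frame ordered by mean rate: mean_rate, max_shap, n.
#' @export
rank_cluster_upper_bound <- function(rates, shap, k = 50L, seed = 1L) {
  stopifnot(length(rates) == length(shap))
  n_distinct <- length(unique(rates))
  if (k > n_distinct) {
    warning("k reduced to the number of distinct rates (", n_distinct, ")")
    k <- n_distinct
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  centers <- kmeanspp_centers(rates, k)
  cl <- if (k == 1L) rep(1L, length(rates))
        else stats::kmeans(rates, centers = matrix(centers, ncol = 1),
                           iter.max = 100L)$cluster
  agg <- data.frame(
    mean_rate = as.numeric(tapply(rates, cl, mean)),
    max_shap = as.numeric(tapply(shap, cl, max)),
    n = as.integer(table(cl)))
  agg[order(agg$mean_rate), , drop = FALSE]
}

# k-means++ seeding in one dimension (over distinct values, so the k
# centers are guaranteed distinct)
kmeanspp_centers <- function(x, k) {
  ux <- unique(x)
  counts <- as.numeric(table(match(x, ux)))
  centers <- ux[sample.int(length(ux), 1L, prob = counts)]
  while (length(centers) < k) {
    d2 <- vapply(ux, function(v) min((v - centers)^2), numeric(1)) * counts
    if (sum(d2) == 0) break
    centers <- c(centers, ux[sample.int(length(ux), 1L, prob = d2)])
  }
  centers
}
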