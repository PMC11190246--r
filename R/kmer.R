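## K-mer count featurization. Sequences become rows of a fixed-vocabulary
## count matrix: the vocabulary is the sorted union of k-mers observed in
## the training corpus, and prediction-time sequences are projected onto
## that fixed column space (unseen k-mers are dropped). K = 6 by default;
## with the four plain bases that is at most 4096 columns plus whatever
## ambiguity-containing tokens the corpus holds.

#' Split a sequence into overlapping k-mers
#'
#' Sliding window of length `K`, stride 1.
#'
#' @param seq Character scalar.
#' @param K K-mer length (>= 1).
#' @return Character vector of `nchar(seq) - K + 1` k-mers (empty when the
#'   sequence is shorter than `K`).
#' @export
kmerize <- function(seq, K = 6L) {
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("K must be a positive integer")
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < K) return(character(0))
  substring(seq, 1:(L - K + 1L), K:L)
}

#' Build a k-mer vocabulary from a corpus
#'
#' The vocabulary is the lexicographically sorted set of all k-mers seen in
#' the corpus. K-mers containing ambiguity codes are kept as literal tokens
#' unless `drop_ambiguous = TRUE`.
#'
#' @param seqs Character vector of sequences.
#' @param K K-mer length.
#' @param drop_ambiguous Remove k-mers containing characters outside ACGT.
#' @return Object of class `kmer_vocabulary`: list with `K` and `kmers`.
#' @export
kmer_vocabulary <- function(seqs, K = 6L, drop_ambiguous = FALSE) {
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("K must be a positive integer")
  all_kmers <- unlist(lapply(seqs, kmerize, K = K), use.names = FALSE)
  if (!length(all_kmers)) stop("no sequence of length >= K = ", K)
  kmers <- sort(unique(all_kmers))
  if (drop_ambiguous) kmers <- kmers[!grepl("[^ACGT]", kmers)]
  structure(list(K = K, kmers = kmers), class = "kmer_vocabulary")
}

#' @export
print.kmer_vocabulary <- function(x, ...) {
  cat("k-mer vocabulary: K =", x$K, "|", length(x$kmers), "k-mers\n")
  invisible(x)
}

#' Count vocabulary k-mers in sequences
#'
#' Counts occurrences of each vocabulary k-mer per sequence; k-mers absent
#' from the vocabulary are dropped silently and tallied in the `dropped`
#' attribute.
#'
#' @param seqs Character vector (named for row labels).
#' @param vocab A [kmer_vocabulary()].
#' @return Integer matrix, sequences x k-mers, with attribute `dropped`
#'   (out-of-vocabulary k-mer count per sequence).
#' @export
kmer_counts <- function(seqs, vocab) {
  stopifnot(inherits(vocab, "kmer_vocabulary"))
  n <- length(seqs)
  p <- length(vocab$kmers)
  counts <- matrix(0L, n, p, dimnames = list(names(seqs), vocab$kmers))
  dropped <- integer(n)
  for (i in seq_len(n)) {
    km <- kmerize(seqs[[i]], vocab$K)
    idx <- match(km, vocab$kmers)
    dropped[i] <- sum(is.na(idx))
    idx <- idx[!is.na(idx)]
    if (length(idx)) {
      tab <- tabulate(idx, nbins = p)
      counts[i, ] <- tab
    }
  }
  attr(counts, "dropped") <- dropped
  counts
}
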