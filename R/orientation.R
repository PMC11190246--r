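## Strand orientation against a conserved template, by a simplified
## seed-and-extend local alignment (exact word seeding, ungapped extension,
## Karlin-Altschul E-values). The template is typically the first ~50 bp of
## a reference 16S gene, a conserved region, so a genuine 16S sequence hits
## it on exactly one strand.

#' Best ungapped local alignment score of a template against a subject
#'
#' Exact `word_size`-mer seeding followed by ungapped extension: on every
#' diagonal that carries at least one seed word, the maximum-scoring
#' contiguous segment is found (match/mismatch scoring). Degenerate bases
#' match when their IUPAC sets intersect.
#'
#' @param template,subject IUPAC DNA strings.
#' @param word_size Exact seed word length.
#' @param match,mismatch Per-base scores.
#' @return Best score (0 if no seed word is shared).
#' @keywords internal
best_ungapped_score <- function(template, subject, word_size = 11L,
                                match = 2, mismatch = -3) {
  m <- nchar(template); n <- nchar(subject)
  if (m < word_size || n < word_size) return(0)
  tw <- substring(template, 1:(m - word_size + 1L), word_size:m)
  sw <- substring(subject, 1:(n - word_size + 1L), word_size:n)
  t_index <- split(seq_along(tw), tw)
  hit_s <- which(sw %in% names(t_index))
  if (!length(hit_s)) return(0)
  tm <- iupac_masks(template)
  sm <- iupac_masks(subject)
  # diagonals (subject_pos - template_pos) holding at least one seed
  diags <- unique(unlist(lapply(hit_s, function(si) si - t_index[[sw[si]]]),
                         use.names = FALSE))
  best <- 0
  for (d in diags) {
    ti <- max(1L, 1L - d):min(m, n - d)
    if (!length(ti)) next
    sc <- ifelse(bitwAnd(tm[ti], sm[ti + d]) > 0L, match, mismatch)
    # maximum contiguous subsequence score on this diagonal (Kadane)
    run <- 0; dbest <- 0
    for (v in sc) {
      run <- max(0, run + v)
      if (run > dbest) dbest <- run
    }
    if (dbest > best) best <- dbest
  }
  best
}

#' Detect the strand orientation of a sequence
#'
#' Aligns the template against the sequence and against its reverse
#' complement; the strand carrying the better template hit wins, provided
#' its expectation value `E = K * m * n * exp(-lambda * S)` is below the
#' threshold. If neither strand reaches the threshold the sequence is
#' labelled `unrecognized`.
#'
#' @param seq IUPAC DNA string.
#' @param template Conserved-region template (plus strand).
#' @param evalue_threshold Maximum E-value for a recognized hit.
#' @param word_size,match,mismatch Seeding/extension parameters.
#' @param lambda,K Karlin-Altschul parameters for the score scale.
#' @param invert If `TRUE`, swap the plus/minus labelling (for templates
#'   written on the minus strand).
#' @return List with `label` ("plus", "minus" or "unrecognized"),
#'   `best_score` and `evalue` of the winning strand.
#' @export
detect_orientation <- function(seq, template, evalue_threshold = 0.01,
                               word_size = 11L, match = 2, mismatch = -3,
                               lambda = 1.28, K = 0.46, invert = FALSE) {
  seq <- check_iupac(seq)
  template <- check_iupac(template, "template")
  if (nchar(template) < word_size)
    stop("template shorter than seed word size (", word_size, ")")
  s_fwd <- best_ungapped_score(template, seq, word_size, match, mismatch)
  s_rev <- best_ungapped_score(template, reverse_complement(seq),
                               word_size, match, mismatch)
  mn <- as.numeric(nchar(template)) * nchar(seq)
  e_fwd <- K * mn * exp(-lambda * s_fwd)
  e_rev <- K * mn * exp(-lambda * s_rev)
  if (e_fwd >= evalue_threshold && e_rev >= evalue_threshold) {
    return(list(label = "unrecognized",
                best_score = max(s_fwd, s_rev),
                evalue = min(e_fwd, e_rev)))
  }
  plus_is_fwd <- s_fwd >= s_rev
  label <- if (xor(plus_is_fwd, invert)) "plus" else "minus"
  list(label = label,
       best_score = if (plus_is_fwd) s_fwd else s_rev,
       evalue = if (plus_is_fwd) e_fwd else e_rev)
}

#' Orient a set of sequences to the plus strand
#'
#' Minus-strand sequences are replaced by their reverse complement;
#' unrecognized sequences are dropped and reported.
#'
#' @param seqs Named character vector of sequences.
#' @param template Conserved-region template.
#' @param ... Passed to [detect_orientation()].
#' @return List: `sequences` (named, all plus strand), `n_excluded`,
#'   `rejects` (data.frame id/reason for the excluded records).
#' @export
orient_all <- function(seqs, template, ...) {
  labels <- vapply(seqs, function(s)
    detect_orientation(s, template, ...)$label, character(1))
  out <- seqs
  is_minus <- labels == "minus"
  if (any(is_minus)) out[is_minus] <- reverse_complement(out[is_minus])
  keep <- labels != "unrecognized"
  rejects <- data.frame(id = names(seqs)[!keep],
                        reason = rep("unrecognized orientation", sum(!keep)),
                        stringsAsFactors = FALSE)
  list(sequences = out[keep], n_excluded = sum(!keep), rejects = rejects)
}
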