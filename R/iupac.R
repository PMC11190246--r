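## IUPAC nucleotide code handling shared by the preprocessing functions.
## Each code is a subset of {A,C,G,T}; matching and complementation work on
## those sets, so degenerate primers and ambiguous reference bases behave
## like the character classes they denote.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# bitmask per code: A=1, C=2, G=4, T=8
.iupac_mask_table <- local({
  base_bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  m <- integer(256)
  for (code in names(IUPAC_SETS)) {
    bits <- sum(base_bit[IUPAC_SETS[[code]]])
    m[utf8ToInt(code) + 1L] <- bits
    m[utf8ToInt(tolower(code)) + 1L] <- bits
  }
  m
})

# complement character lookup (A<->T, C<->G, M<->K, R<->Y, etc.)
.iupac_complement <- local({
  from <- c("A","C","G","T","U","R","Y","S","W","K","M","B","D","H","V","N")
  to   <- c("T","G","C","A","A","Y","R","S","W","M","K","V","H","D","B","N")
  stats::setNames(to, from)
})

#' Validate an IUPAC DNA string
#'
#' Checks that a sequence contains only IUPAC nucleotide codes
#' (case-insensitive). Used as the entry guard of every sequence operation.
#'
#' @param seq Character scalar.
#' @param what Label used in error messages.
#' @return The sequence, uppercased, invisibly usable.
#' @keywords internal
check_iupac <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string")
  s <- toupper(seq)
  if (nchar(s) == 0L) stop(what, " is empty")
  codes <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(codes), names(IUPAC_SETS))
  if (length(bad))
    stop(what, " contains non-IUPAC characters: ", paste(bad, collapse = ", "))
  s
}

#' Convert a sequence to a vector of IUPAC bitmasks
#' @keywords internal
iupac_masks <- function(seq) {
  .iupac_mask_table[utf8ToInt(seq) + 1L]
}

#' Reverse complement of an IUPAC DNA string
#'
#' IUPAC-aware: degenerate codes map to the code of the complemented set
#' (M to K, R to Y, N to N, ...). An involution on valid input.
#'
#' @param seq Character scalar (IUPAC DNA). Vectors are handled elementwise.
#' @return Character of the same length as `seq`.
#' @examples
#' reverse_complement("ACGT")  # "ACGT"
#' reverse_complement("AAM")   # "KTT"
#' @export
reverse_complement <- function(seq) {
  vapply(seq, function(s) {
    s <- check_iupac(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    paste(rev(unname(.iupac_complement[chars])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
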