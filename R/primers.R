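## Degenerate-primer matching and hypervariable-region extraction.
## A primer base matches a sequence base iff their IUPAC sets intersect
## (so N matches everything, M matches A or C, ...). Coordinates are
## 0-based half-open internally.

#' Locate a primer on a sequence
#'
#' Scans every offset and scores mismatches by IUPAC set intersection.
#' Returns the interval of the lowest-mismatch site, provided that best
#' site has at most `max_mismatch` mismatches. Ties are broken to the
#' leftmost site (`from = "left"`, forward primers) or the rightmost
#' (`from = "right"`, reverse primers).
#'
#' @param seq IUPAC DNA string (plus strand).
#' @param primer IUPAC primer string, written in the orientation in which
#'   it should appear in `seq`.
#' @param max_mismatch Maximum tolerated mismatches.
#' @param from Tie-break direction, "left" or "right".
#' @return Integer vector `c(start, end)` (0-based, half-open) or `NULL`
#'   if there is no acceptable site (including primer longer than seq).
#' @export
find_primer_site <- function(seq, primer, max_mismatch = 0L,
                             from = c("left", "right")) {
  from <- match.arg(from)
  seq <- check_iupac(seq)
  primer <- check_iupac(primer, "primer")
  L <- nchar(seq); l <- nchar(primer)
  if (l > L) return(NULL)
  S <- iupac_masks(seq); P <- iupac_masks(primer)
  n_off <- L - l + 1L
  mism <- integer(n_off)
  for (j in seq_len(l)) {
    mism <- mism + as.integer(bitwAnd(S[j:(j + n_off - 1L)], P[j]) == 0L)
  }
  best <- min(mism)
  if (best > max_mismatch) return(NULL)
  hits <- which(mism == best)
  o <- if (from == "left") hits[1] else hits[length(hits)]
  c(start = o - 1L, end = o - 1L + l)
}

#' Extract the region delimited by a primer pair
#'
#' Locates the forward primer on the plus strand (leftmost best site) and
#' the reverse primer as the reverse complement of its 5'->3' minus-strand
#' sequence, searched downstream of the forward site (rightmost best site).
#' By convention the primers themselves are excluded from the returned
#' insert; set `include_primers = TRUE` to keep them.
#'
#' @param seq IUPAC DNA string, oriented plus.
#' @param forward,reverse Primer strings, both written 5'->3' on their own
#'   strand (the reverse primer on the minus strand, as primers are
#'   conventionally given).
#' @param max_mismatch Maximum mismatches per primer.
#' @param include_primers Keep the primer sites in the output.
#' @return The extracted subsequence, or `NULL` when either primer is not
#'   found or the reverse site is not downstream of the forward site.
#' @export
extract_region <- function(seq, forward, reverse, max_mismatch = 0L,
                           include_primers = FALSE) {
  seq <- check_iupac(seq)
  fwd <- find_primer_site(seq, forward, max_mismatch, from = "left")
  if (is.null(fwd)) return(NULL)
  rev_plus <- reverse_complement(reverse)
  tail_seq <- substr(seq, fwd[["end"]] + 1L, nchar(seq))
  rv <- find_primer_site(tail_seq, rev_plus, max_mismatch, from = "right")
  if (is.null(rv)) return(NULL)
  rv <- rv + fwd[["end"]]  # back to full-sequence coordinates
  if (include_primers) {
    substr(seq, fwd[["start"]] + 1L, rv[["end"]])
  } else {
    if (rv[["start"]] <= fwd[["end"]]) return(NULL)
    substr(seq, fwd[["end"]] + 1L, rv[["start"]])
  }
}

#' Read a primer configuration file
#'
#' JSON mapping region label to `forward`, `reverse` and optional
#' `max_mismatch` (default 0).
#'
#' @param path JSON file path.
#' @return Named list of lists with elements forward/reverse/max_mismatch.
#' @export
read_primers <- function(path) {
  cfg <- jsonlite::read_json(path)
  lapply(cfg, function(p) {
    if (is.null(p$forward) || is.null(p$reverse))
      stop("primer config entries need 'forward' and 'reverse'")
    list(forward = check_iupac(p$forward, "forward primer"),
         reverse = check_iupac(p$reverse, "reverse primer"),
         max_mismatch = if (is.null(p$max_mismatch)) 0L
                        else as.integer(p$max_mismatch))
  })
}

#' Prepare a sequence set: orient, then trim to a region
#'
#' Convenience wrapper chaining [orient_all()] and [extract_region()];
#' records whose primers are not found join the rejects table.
#'
#' @param seqs Named character vector.
#' @param template Orientation template.
#' @param primers A single entry of [read_primers()] output (list with
#'   forward/reverse/max_mismatch), or `NULL` to skip trimming.
#' @param ... Passed to [detect_orientation()].
#' @return List: `sequences`, `rejects` (data.frame id/reason).
#' @export
prep_sequences <- function(seqs, template, primers = NULL, ...) {
  ori <- orient_all(seqs, template, ...)
  out <- ori$sequences
  rejects <- ori$rejects
  if (!is.null(primers)) {
    ext <- lapply(out, extract_region,
                  forward = primers$forward, reverse = primers$reverse,
                  max_mismatch = primers$max_mismatch)
    miss <- vapply(ext, is.null, logical(1))
    if (any(miss))
      rejects <- rbind(rejects,
                       data.frame(id = names(out)[miss],
                                  reason = rep("primer not found", sum(miss)),
                                  stringsAsFactors = FALSE))
    out <- unlist(ext[!miss])
  }
  list(sequences = out, rejects = rejects)
}
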