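## FASTA I/O. Sequences travel through the package as named character
## vectors (names = record ids, values = uppercase IUPAC strings); that is
## the lightest container that keeps ids and order attached.

#' Read a FASTA file
#'
#' @param path Path to a FASTA file. An empty file yields an empty vector.
#' @return Named character vector of uppercase sequences, in file order.
#'   Header text after the first whitespace is dropped from the id.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L) return(stats::setNames(character(0), character(0)))
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (anyNA(ids) || any(ids == ""))
    stop("malformed FASTA header at record ", which(is.na(ids) | ids == "")[1])
  empty <- nchar(seqs) == 0L
  if (any(empty))
    stop("empty sequence for record '", ids[which(empty)[1]], "'")
  stats::setNames(unname(seqs), ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector (ids as names).
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("sequences must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
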