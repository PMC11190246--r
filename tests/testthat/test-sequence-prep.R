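test_that("reverse complement follows the IUPAC table and is an involution", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("AAM"), "KTT")
  expect_error(reverse_complement("ACGX"), "non-IUPAC")
  set.seed(1)
  for (i in 1:20) {
    s <- rand_iupac(sample(5:60, 1))
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("FASTA reading normalizes case, preserves order, handles empties", {
  path <- tempfile(fileext = ".fa")
  writeLines(c(">s1 some description", "acgtACGT", ">s2", "GGGC", "CCAA"),
             path)
  recs <- read_fasta(path)
  expect_identical(names(recs), c("s1", "s2"))
  expect_identical(unname(recs), c("ACGTACGT", "GGGCCCAA"))

  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  expect_length(read_fasta(empty), 0)

  bad <- tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">empty_rec", "", ">c", "GG"), bad)
  expect_error(read_fasta(bad), "empty_rec")

  # round trip
  out <- tempfile(fileext = ".fa")
  write_fasta(recs, out, width = 5)
  expect_identical(read_fasta(out), recs)
})

test_that("orientation detection recognizes constructed strands", {
  set.seed(7)
  tpl <- rand_dna(50)
  plus <- paste0(rand_dna(25), tpl, rand_dna(300))
  expect_identical(detect_orientation(plus, tpl)$label, "plus")
  minus <- reverse_complement(plus)
  expect_identical(detect_orientation(minus, tpl)$label, "minus")
  res <- detect_orientation(plus, tpl)
  expect_lt(res$evalue, 0.01)
  expect_error(detect_orientation(plus, "ACGTACGT"), "word size")
})

test_that("a random sequence is unrecognized, confirmed by a scan oracle", {
  set.seed(0)
  tpl <- rand_dna(50)
  seq <- rand_dna(1000)
  res <- detect_orientation(seq, tpl)
  expect_identical(res$label, "unrecognized")

  # independent oracle: on every diagonal carrying an exact 11-base match
  # run (a seed word), the best segment score via prefix sums; then the
  # Karlin-Altschul E-value
  best_diag <- function(a, b) {
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    best <- 0
    for (d in (-(length(av) - 1)):(length(bv) - 1)) {
      ai <- max(1, 1 - d):min(length(av), length(bv) - d)
      if (!length(ai)) next
      eq <- av[ai] == bv[ai + d]
      runs <- rle(eq)
      if (!any(runs$values & runs$lengths >= 11)) next
      sc <- ifelse(eq, 2, -3)
      pref <- cumsum(c(0, sc))
      best <- max(best, max(pref - cummin(pref)))
    }
    best
  }
  s1 <- best_diag(tpl, seq)
  s2 <- best_diag(tpl, reverse_complement(seq))
  e_min <- 0.46 * 50 * 1000 * exp(-1.28 * max(s1, s2))
  expect_gte(e_min, 0.01)
})

test_that("a sequence and its reverse complement get opposite labels", {
  set.seed(11)
  tpl <- rand_dna(50)
  for (i in 1:5) {
    s <- paste0(rand_dna(sample(10:80, 1)), tpl, rand_dna(200))
    if (i %% 2 == 0) s <- reverse_complement(s)
    a <- detect_orientation(s, tpl)$label
    b <- detect_orientation(reverse_complement(s), tpl)$label
    expect_setequal(c(a, b), c("plus", "minus"))
  }
})

test_that("orient_all flips minus strands, drops unrecognized, idempotent", {
  set.seed(3)
  tpl <- rand_dna(50)
  plus1 <- paste0(rand_dna(20), tpl, rand_dna(150))
  plus2 <- paste0(rand_dna(5), tpl, rand_dna(90))
  minus <- reverse_complement(plus2)
  noise <- rand_dna(400)
  seqs <- c(a = plus1, b = minus, c = noise)
  out <- orient_all(seqs, tpl)
  expect_identical(out$n_excluded, 1L)
  expect_identical(out$rejects$id, "c")
  expect_identical(unname(out$sequences["b"]), plus2)
  expect_identical(unname(out$sequences["a"]), plus1)
  again <- orient_all(out$sequences, tpl)
  expect_identical(again$sequences, out$sequences)
  expect_identical(again$n_excluded, 0L)
})

test_that("primer sites honor IUPAC degeneracy, mismatch caps, tie-breaks", {
  expect_identical(
    find_primer_site("GGAGAGTTTGATCATGGCTCAGCC", "AGAGTTTGATCMTGGCTCAG", 0),
    c(start = 2L, end = 22L))
  # one mismatch: rejected at cap 0, found at cap 1
  seq <- "TTTTAACCGGTTAAAA"
  expect_null(find_primer_site(seq, "AACCGCTT", 0))
  expect_identical(find_primer_site(seq, "AACCGCTT", 1),
                   c(start = 4L, end = 12L))
  # duplicate exact site: leftmost for forward, rightmost for reverse
  dup <- "AACGTAAAAACGTAAA"
  expect_identical(find_primer_site(dup, "ACGTA", 0, from = "left")[["start"]],
                   1L)
  expect_identical(find_primer_site(dup, "ACGTA", 0, from = "right")[["start"]],
                   9L)
  # primer longer than sequence is a miss, not an error
  expect_null(find_primer_site("ACGT", "ACGTACGT", 0))
})

test_that("region extraction returns the insert between the primer sites", {
  set.seed(5)
  fwd <- "AGAGTTTGATCATGGCTCAG"
  rev <- "TACCTTGTTACGACTT"
  core <- rand_dna(200)
  seq <- paste0(rand_dna(12), fwd, core, reverse_complement(rev), rand_dna(9))
  expect_identical(extract_region(seq, fwd, rev), core)
  expect_identical(extract_region(seq, fwd, rev, include_primers = TRUE),
                   paste0(fwd, core, reverse_complement(rev)))
  expect_null(extract_region(seq, fwd, "GGGGGGGGGGGGGGGG"))
  # output is a substring and shorter than input minus both primers
  expect_true(grepl(extract_region(seq, fwd, rev), seq, fixed = TRUE))
  expect_lte(nchar(extract_region(seq, fwd, rev)),
             nchar(seq) - nchar(fwd) - nchar(rev))
})

test_that("nested extraction equals direct extraction of the inner region", {
  set.seed(6)
  fwd_out <- "AGAGTTTGATCATGGCTCAG"; rev_out <- "TACCTTGTTACGACTT"
  fwd_in <- "GTGCCAGCAGCCGCGGTAA"; rev_in <- "GGACTACAAGGGTATCTAAT"
  v4 <- rand_dna(120)
  inner <- paste0(rand_dna(60), fwd_in, v4, reverse_complement(rev_in),
                  rand_dna(40))
  full <- paste0(rand_dna(15), fwd_out, inner, reverse_complement(rev_out),
                 rand_dna(10))
  direct <- extract_region(full, fwd_in, rev_in)
  nested <- extract_region(extract_region(full, fwd_out, rev_out),
                           fwd_in, rev_in)
  expect_identical(nested, direct)
  expect_identical(direct, v4)
})

test_that("prep_sequences chains orientation and trimming with rejects", {
  set.seed(8)
  tpl <- rand_dna(50)
  fwd <- "AGAGTTTGATCATGGCTCAG"; rev <- "TACCTTGTTACGACTT"
  core <- rand_dna(150)
  good <- paste0(tpl, rand_dna(10), fwd, core, reverse_complement(rev))
  noprimer <- paste0(tpl, rand_dna(220))
  seqs <- c(g = good, m = reverse_complement(good), n = noprimer,
            r = rand_dna(400))
  out <- prep_sequences(seqs, tpl,
                        list(forward = fwd, reverse = rev, max_mismatch = 0L))
  expect_identical(sort(out$rejects$id), c("n", "r"))
  expect_identical(unname(out$sequences[c("g", "m")]), c(core, core))
})

test_that("primer configs read from JSON validate their fields", {
  cfg <- tempfile(fileext = ".json")
  writeLines('{"V4": {"forward": "GTGCCAGCMGCCGCGGTAA",
                      "reverse": "GGACTACHVGGGTWTCTAAT", "max_mismatch": 2}}',
             cfg)
  p <- read_primers(cfg)
  expect_identical(p$V4$max_mismatch, 2L)
  bad <- tempfile(fileext = ".json")
  writeLines('{"V4": {"forward": "ACGT"}}', bad)
  expect_error(read_primers(bad), "forward")
})
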