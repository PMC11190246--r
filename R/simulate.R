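## Seeded simulators providing ground truth for every other component:
## Yule trees, sequences evolved along them under Jukes-Cantor
## substitutions plus geometric-length indels (with the true alignment
## tracked column by column, so positional statistics have an exact
## oracle), copy-number traits (Brownian or motif-determined), nested
## lineages cut from the tree, and mock communities.

#' Simulate a Yule (pure-birth) tree
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth Birth rate.
#' @param seed Integer seed.
#' @return An `ape::phylo` tree with tips `t1..tn`.
#' @export
simulate_tree <- function(n_tips, birth = 1, seed = 1L) {
  if (n_tips < 2L) stop("need at least 2 tips")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth, death = 0)
  tree$tip.label <- paste0("t", seq_len(n_tips))
  tree
}

#' Evolve sequences along a tree, tracking the true alignment
#'
#' Jukes-Cantor substitutions (per-site change probability
#' `3/4 * (1 - exp(-4 * sub_rate * t / 3))` on a branch of length `t`) and
#' indels arriving as a Poisson process (`indel_rate` per site per unit
#' branch length, insertion/deletion equally likely, lengths
#' 1 + Geometric(`indel_geom_p`)). Every residue carries a column
#' identity, so the emitted alignment is the true one: homologous residues
#' share a column and each insertion opens its own column(s).
#'
#' @param tree `ape::phylo` tree.
#' @param root_length Length of the (uniform-random) root sequence.
#' @param sub_rate Substitution rate per site per unit branch length.
#' @param indel_rate Indel event rate per site per unit branch length.
#' @param indel_geom_p Geometric parameter of indel lengths.
#' @param rate_factors Optional per-site substitution rate multipliers for
#'   the root sequence positions (length `root_length`), modelling the
#'   conserved-backbone / hypervariable-island mosaic of rRNA genes;
#'   positions inserted later evolve at factor 1.
#' @param seed Integer seed.
#' @param include_root Include the root sequence as alignment row "root"
#'   (handy as a mutation-rate reference).
#' @return List: `sequences` (named ungapped tip sequences), `alignment`
#'   (named gapped rows over the true columns, all-gap columns removed),
#'   `details` (column bookkeeping for exact positional oracles:
#'   `master` column ids in order, `root_cols`, and per-row `cols`/`bases`).
#' @export
evolve_sequences <- function(tree, root_length = 1500L, sub_rate = 0.02,
                             indel_rate = 0.001, indel_geom_p = 0.5,
                             rate_factors = NULL, seed = 1L,
                             include_root = TRUE) {
  if (!is.null(rate_factors) && length(rate_factors) != root_length)
    stop("rate_factors must have one entry per root position")
  if (root_length < 100L) stop("root sequence must be at least 100 nt")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")

  env <- new.env()
  env$master <- paste0("c", seq_len(root_length))
  env$counter <- root_length
  factor_of <- if (is.null(rate_factors)) NULL
               else stats::setNames(rate_factors, env$master)

  root_state <- list(cols = env$master,
                     bases = sample(bases, root_length, replace = TRUE))

  evolve_branch <- function(state, t) {
    n <- length(state$cols)
    if (n > 0L && sub_rate > 0) {
      rate <- rep(sub_rate, n)
      if (!is.null(factor_of)) {
        f <- factor_of[state$cols]
        rate <- rate * ifelse(is.na(f), 1, f)
      }
      p_change <- 0.75 * (1 - exp(-4 * rate * t / 3))
      hit <- which(stats::runif(n) < p_change)
      for (i in hit)
        state$bases[i] <- sample(setdiff(bases, state$bases[i]), 1L)
    }
    if (indel_rate > 0 && length(state$cols) > 0L) {
      n_events <- stats::rpois(1L, indel_rate * t * length(state$cols))
      for (ev in seq_len(n_events)) {
        len <- 1L + stats::rgeom(1L, indel_geom_p)
        cur <- length(state$cols)
        if (cur == 0L) break
        if (stats::runif(1L) < 0.5) {  # insertion after position pos (0..cur)
          pos <- sample.int(cur + 1L, 1L) - 1L
          new_ids <- paste0("c", env$counter + seq_len(len))
          env$counter <- env$counter + len
          anchor <- if (pos == 0L) match(state$cols[1L], env$master) - 1L
                    else match(state$cols[pos], env$master)
          env$master <- append(env$master, new_ids, after = anchor)
          state$cols <- append(state$cols, new_ids, after = pos)
          state$bases <- append(state$bases,
                                sample(bases, len, replace = TRUE),
                                after = pos)
        } else {                        # deletion starting at position pos
          pos <- sample.int(cur, 1L)
          idx <- pos:min(pos + len - 1L, cur)
          state$cols <- state$cols[-idx]
          state$bases <- state$bases[-idx]
        }
      }
    }
    state
  }

  n_tips <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  states <- vector("list", max(tree$edge))
  root <- po[nrow(po), 1]
  states[[root]] <- root_state
  # preorder traversal = reversed postorder edges
  edge_len <- ape::reorder.phylo(tree, "postorder")$edge.length
  for (e in rev(seq_len(nrow(po)))) {
    parent <- po[e, 1]; child <- po[e, 2]
    states[[child]] <- evolve_branch(states[[parent]], edge_len[e])
  }

  rows <- stats::setNames(states[seq_len(n_tips)], tree$tip.label)
  if (include_root) rows <- c(rows, list(root = root_state))

  used <- unique(unlist(lapply(rows, `[[`, "cols"), use.names = FALSE))
  master <- env$master[env$master %in% used]
  aln <- vapply(rows, function(st) {
    chars <- rep("-", length(master))
    chars[match(st$cols, master)] <- st$bases
    paste(chars, collapse = "")
  }, character(1))
  seqs <- vapply(rows[seq_len(n_tips)], function(st)
    paste(st$bases, collapse = ""), character(1))

  list(sequences = seqs, alignment = aln,
       details = list(master = master,
                      root_cols = root_state$cols,
                      rows = lapply(rows, function(st)
                        list(cols = st$cols, bases = st$bases))))
}

#' Brownian-motion copy-number trait
#'
#' Brownian motion from the root value along the branches, then rounded
#' and clamped to the copy-number range.
#'
#' @param tree `ape::phylo` tree.
#' @param root_value Trait value at the root.
#' @param sigma Brownian standard deviation per unit sqrt(branch length).
#' @param bounds Clamp range (copies/genome).
#' @param seed Integer seed.
#' @return Named numeric vector of integer tip values.
#' @export
gcn_brownian <- function(tree, root_value = 5, sigma = 1, bounds = c(1, 21),
                         seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_nodes <- max(tree$edge)
  po <- ape::reorder.phylo(tree, "postorder")
  val <- numeric(n_nodes)
  val[po$edge[nrow(po$edge), 1]] <- root_value
  for (e in rev(seq_len(nrow(po$edge)))) {
    val[po$edge[e, 2]] <- val[po$edge[e, 1]] +
      stats::rnorm(1L, sd = sigma * sqrt(po$edge.length[e]))
  }
  tips <- val[seq_along(tree$tip.label)]
  out <- pmin(pmax(round(tips), bounds[1]), bounds[2])
  stats::setNames(out, tree$tip.label)
}

#' Motif-determined copy-number trait
#'
#' The trait is a linear function of motif presence in each (evolved)
#' sequence plus Gaussian noise: `base + sum(effect_m * present_m) +
#' N(0, noise_sd)`, clamped to the copy-number range. Because motif
#' presence is inherited and destroyed along the tree, the trait is both
#' sequence-determined (learnable from k-mers, with known Bayes error
#' `noise_sd`) and phylogenetically conserved.
#'
#' @param seqs Named character vector of sequences.
#' @param motifs Character vector of motif strings.
#' @param effects Numeric effects, one per motif.
#' @param base Baseline copy number.
#' @param noise_sd Gaussian noise standard deviation.
#' @param bounds Clamp range.
#' @param seed Integer seed.
#' @return Named numeric vector of tip values (not rounded).
#' @export
gcn_from_motifs <- function(seqs, motifs, effects, base = 4,
                            noise_sd = 0.25, bounds = c(1, 21), seed = 1L) {
  stopifnot(length(motifs) == length(effects))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  present <- vapply(motifs, function(m) grepl(m, seqs, fixed = TRUE),
                    logical(length(seqs)))
  present <- matrix(present, ncol = length(motifs))
  y <- base + drop(present %*% effects) +
    stats::rnorm(length(seqs), sd = noise_sd)
  stats::setNames(pmin(pmax(y, bounds[1]), bounds[2]), names(seqs))
}

#' Derive nested lineages by cutting the tree at depth thresholds
#'
#' For each of the `ranks - 1` upper ranks, the taxon of a tip is the
#' clade whose stem edge crosses the corresponding depth threshold
#' (thresholds evenly spaced over the tree height); the final rank is the
#' tip itself. Every named taxon is a clade by construction.
#'
#' @param tree `ape::phylo` tree (ultrametric, as from [simulate_tree()]).
#' @param ranks Number of ranks (7 mirrors domain..species).
#' @return Data frame: `id` plus one column per rank (`rank1..rankN`,
#'   the last holding the tip label).
#' @export
derive_lineages <- function(tree, ranks = 7L) {
  n_tips <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  height <- max(depth[seq_len(n_tips)])
  thresholds <- height * seq_len(ranks - 1L) / ranks
  par <- .parents(tree)
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])

  out <- matrix(NA_character_, n_tips, ranks)
  for (i in seq_len(n_tips)) {
    # path from root to tip
    path <- i; v <- i
    while (v != root) { v <- par[v]; path <- c(v, path) }
    for (r in seq_len(ranks - 1L)) {
      crossing <- path[which(depth[path] >= thresholds[r])[1]]
      out[i, r] <- paste0("R", r, "N", crossing)
    }
    out[i, ranks] <- tree$tip.label[i]
  }
  df <- data.frame(id = tree$tip.label, out, stringsAsFactors = FALSE)
  names(df) <- c("id", paste0("rank", seq_len(ranks)))
  df
}

#' Construct a mock community profile
#'
#' An "even" preset (equal cell fractions) and a "staggered" preset
#' (log-spaced, strictly decreasing fractions spanning about four orders
#' of magnitude over ten strains), scaled to a fixed total cell count.
#'
#' @param preset "even" or "staggered".
#' @param n Number of strains.
#' @param gcn True copy numbers per strain; by default drawn (seeded) as
#'   integers from a right-skewed copy-number distribution.
#' @param total_cells Total cell count of the community.
#' @param seed Integer seed.
#' @return Data frame: taxon, cell_count, cell_fraction, gcn,
#'   read_fraction.
#' @export
make_mock_community <- function(preset = c("even", "staggered"), n = 10L,
                                gcn = NULL, total_cells = 1e5, seed = 1L) {
  preset <- match.arg(preset)
  if (n < 2L) stop("need at least 2 strains")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  frac <- switch(preset,
    even = rep(1 / n, n),
    staggered = { f <- 10^(-(seq_len(n) - 1L) / 2.25); f / sum(f) })
  if (is.null(gcn))
    gcn <- pmin(1L + stats::rpois(n, 4), 21L)
  stopifnot(length(gcn) == n, all(gcn >= 1))
  cells <- frac * total_cells
  data.frame(taxon = paste0("strain", seq_len(n)),
             cell_count = cells,
             cell_fraction = frac,
             gcn = gcn,
             read_fraction = reads_from_cells(cells, gcn),
             stringsAsFactors = FALSE)
}

#' Simulate a complete benchmark data set
#'
#' One call producing the internally consistent tuple every estimator
#' consumes: tree, evolved sequences with true alignment, motif-determined
#' copy-number trait, nested lineages. Defaults emulate an amplicon-scale
#' (V4-length, 250 nt) data set with the conserved-backbone /
#' hypervariable-island rate mosaic characteristic of rRNA genes: the
#' background evolves slowly while windows around the planted motifs are
#' hypervariable, so motif presence varies across the tree while the
#' backbone stays alignable. The trait is a linear function of motif
#' presence plus noise, giving the regressors a learnable signal with
#' known Bayes error (`noise_sd`) and the phylogenetic methods a heritable
#' trait.
#'
#' @param n_tips Number of tips.
#' @param seed Integer seed driving every stage.
#' @param root_length,sub_rate,indel_rate Passed to [evolve_sequences()];
#'   `sub_rate` is the conserved-background rate.
#' @param hv_factor,hv_width Rate multiplier and width of the
#'   hypervariable window centred on each motif site.
#' @param n_motifs,motif_length Number and length of planted motifs.
#' @param effects Motif effects (copies/genome); default
#'   `c(2, -1.5, 1, 2.5, -2)` recycled to `n_motifs`.
#' @param base,noise_sd Trait baseline and noise (see [gcn_from_motifs()]).
#' @return List: `tree`, `sequences`, `alignment`, `details`, `labels`,
#'   `lineages`, `motifs`, `effects`.
#' @export
simulate_gcn_dataset <- function(n_tips = 300L, seed = 1L,
                                 root_length = 250L, sub_rate = 0.003,
                                 indel_rate = 5e-4, hv_factor = 6,
                                 hv_width = 30L, n_motifs = 5L,
                                 motif_length = 6L,
                                 effects = c(2, -1.5, 1, 2.5, -2),
                                 base = 4, noise_sd = 0.25) {
  tree <- simulate_tree(n_tips, seed = seed)
  # a throw-away draw of the root sequence fixes the motif sites; the
  # real evolution run then uses the hypervariable-window rate mosaic
  root_probe <- evolve_sequences(tree, root_length = root_length,
                                 sub_rate = 0, indel_rate = 0,
                                 seed = seed + 1L)
  root_str <- paste(root_probe$details$rows$root$bases, collapse = "")
  L <- root_length
  zones <- floor(seq(L * 0.12, L * 0.88, length.out = n_motifs))
  motifs <- character(n_motifs)
  sites <- integer(n_motifs)
  occurrences <- function(m) length(gregexpr(m, root_str, fixed = TRUE)[[1]])
  for (j in seq_len(n_motifs)) {
    for (s in zones[j] + c(0L, seq_len(100L))) {
      m <- substr(root_str, s, s + motif_length - 1L)
      if (nchar(m) == motif_length && occurrences(m) == 1L &&
          !m %in% motifs) { motifs[j] <- m; sites[j] <- s; break }
    }
    if (motifs[j] == "") stop("could not place a unique motif")
  }
  rate_factors <- rep(1, L)
  half <- hv_width %/% 2L
  for (s in sites) {
    win <- max(1L, s + motif_length %/% 2L - half):
           min(L, s + motif_length %/% 2L + half)
    rate_factors[win] <- hv_factor
  }
  ev <- evolve_sequences(tree, root_length = root_length,
                         sub_rate = sub_rate, indel_rate = indel_rate,
                         rate_factors = rate_factors, seed = seed + 1L)
  effects <- rep_len(effects, n_motifs)
  labels <- gcn_from_motifs(ev$sequences, motifs, effects, base = base,
                            noise_sd = noise_sd, seed = seed + 3L)
  lineages <- derive_lineages(tree)
  list(tree = tree, sequences = ev$sequences, alignment = ev$alignment,
       details = ev$details, labels = labels, lineages = lineages,
       motifs = motifs, effects = effects, motif_sites = sites,
       rate_factors = rate_factors)
}
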