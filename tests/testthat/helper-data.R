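# shared fixture builders; everything is generated in code, seeded

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_iupac <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(setdiff(names(gcn16:::IUPAC_SETS), "U"), n,
               replace = TRUE), collapse = "")
}

# a small random tree with positive branch lengths and named tips
rand_tree <- function(n_tips, seed) {
  set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  tr$tip.label <- paste0("t", seq_len(n_tips))
  tr$edge.length <- tr$edge.length + 0.05
  tr
}

# Brownian-motion GLS interpolator: the ML estimate of an unobserved tip
# state given the known tips, used as the independent oracle for WSCP/PIC
gls_bm_oracle <- function(tree, known, query) {
  C <- ape::vcv(tree)
  kn <- names(known)
  Ck <- C[kn, kn, drop = FALSE]
  cq <- C[query, kn]
  Ci <- solve(Ck)
  one <- rep(1, length(kn))
  mu <- drop(one %*% Ci %*% known) / drop(one %*% Ci %*% one)
  drop(mu + cq %*% Ci %*% (known - mu))
}

# minimal total parsimony cost by exhaustive enumeration over all
# unknown-node state assignments
brute_force_parsimony_cost <- function(tree, known, s_max) {
  ntip <- length(tree$tip.label)
  nn <- max(tree$edge)
  fixed <- rep(NA_integer_, nn)
  fixed[match(names(known), tree$tip.label)] <- as.integer(known)
  unknown <- which(is.na(fixed))
  grid <- as.matrix(expand.grid(rep(list(seq_len(s_max)), length(unknown))))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    st <- fixed
    st[unknown] <- grid[r, ]
    cost <- sum(st[tree$edge[, 1]] != st[tree$edge[, 2]])
    if (cost < best) best <- cost
  }
  best
}
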