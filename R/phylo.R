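## Phylogeny-based copy-number baselines: hidden-state prediction of tip
## traits on a tree with known values at some tips. Five classical
## algorithms: subtree averaging (SA), empirical probabilities (EP),
## Sankoff maximum parsimony (MPR), weighted-squared-change parsimony
## (WSCP) and independent contrasts (PIC). Trees are `ape::phylo` objects;
## known values are a named numeric vector keyed by tip label, and
## predictions are returned for the remaining (query) tips.

#' Parse a Newick string or file into a phylo tree
#'
#' Thin wrapper over `ape::read.tree` adding the dialect decisions used
#' throughout: duplicate tip labels are an error, and missing branch
#' lengths default to 0 with a warning.
#'
#' @param text Newick string (used when `file` is missing).
#' @param file Path to a Newick file.
#' @return An `ape::phylo` tree.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  tree <- if (!is.null(file)) ape::read.tree(file)
          else ape::read.tree(text = text)
  if (is.null(tree)) stop("Newick parse error")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("missing branch lengths defaulted to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch length")
  tree
}

#' Write a phylo tree to Newick
#' @param tree An `ape::phylo` object.
#' @param file Optional output path; if `NULL` the string is returned.
#' @return Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(file)) ape::write.tree(tree)
  else { ape::write.tree(tree, file = file); invisible(file) }
}

# ---- shared helpers -----------------------------------------------------

.check_hsp_input <- function(tree, known, queries) {
  stopifnot(inherits(tree, "phylo"))
  if (!length(known)) stop("need at least one known tip value")
  if (is.null(names(known)) || !all(names(known) %in% tree$tip.label))
    stop("known values must be named by tip labels present in the tree")
  if (is.null(queries)) queries <- setdiff(tree$tip.label, names(known))
  if (!all(queries %in% tree$tip.label))
    stop("query tips absent from the tree: ",
         paste(setdiff(queries, tree$tip.label), collapse = ", "))
  queries
}

.parents <- function(tree) {
  n_nodes <- max(tree$edge)
  par <- integer(n_nodes)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  par
}

# ---- subtree averaging --------------------------------------------------

#' Hidden-state prediction by subtree averaging
#'
#' Every node's value is the arithmetic mean of the known tips descending
#' from it; a query tip takes the value of its nearest ancestor with at
#' least one known descendant.
#'
#' @param tree `ape::phylo` tree.
#' @param known Named numeric vector of known tip values.
#' @param queries Tip labels to predict (default: all unlabeled tips).
#' @return Named numeric vector of predictions.
#' @export
hsp_subtree_averaging <- function(tree, known, queries = NULL) {
  queries <- .check_hsp_input(tree, known, queries)
  ntip <- length(tree$tip.label)
  n_nodes <- max(tree$edge)
  s <- numeric(n_nodes); cnt <- numeric(n_nodes)
  ki <- match(names(known), tree$tip.label)
  s[ki] <- known; cnt[ki] <- 1
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(po))) {
    s[po[e, 1]] <- s[po[e, 1]] + s[po[e, 2]]
    cnt[po[e, 1]] <- cnt[po[e, 1]] + cnt[po[e, 2]]
  }
  par <- .parents(tree)
  vapply(stats::setNames(queries, queries), function(q) {
    v <- match(q, tree$tip.label)
    while (cnt[v] == 0) v <- par[v]
    s[v] / cnt[v]
  }, numeric(1))
}

# ---- empirical probabilities -------------------------------------------

#' Hidden-state prediction by empirical probabilities
#'
#' Discrete-state analogue of subtree averaging: each node carries the
#' empirical frequency vector of the integer states among its known
#' descendant tips, and a query inherits the vector of its nearest
#' informative ancestor. The point prediction is the expectation of that
#' distribution (set `point = "argmax"` for the modal state, ties to the
#' smallest).
#'
#' @inheritParams hsp_subtree_averaging
#' @param s_max Number of states (states are integers `1..s_max`);
#'   defaults to the largest known state.
#' @param point "expectation" or "argmax".
#' @return List: `pred` (named numeric), `probs` (queries x states matrix).
#' @export
hsp_empirical_probabilities <- function(tree, known, queries = NULL,
                                        s_max = NULL,
                                        point = c("expectation", "argmax")) {
  point <- match.arg(point)
  queries <- .check_hsp_input(tree, known, queries)
  if (any(known != round(known)) || any(known < 1))
    stop("known states must be positive integers")
  s_max <- as.integer(s_max %||% max(known))
  if (any(known > s_max)) stop("known state exceeds s_max")
  n_nodes <- max(tree$edge)
  cntm <- matrix(0, n_nodes, s_max)
  ki <- match(names(known), tree$tip.label)
  cntm[cbind(ki, as.integer(known))] <- 1
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(po)))
    cntm[po[e, 1], ] <- cntm[po[e, 1], ] + cntm[po[e, 2], ]
  par <- .parents(tree)
  probs <- matrix(NA_real_, length(queries), s_max,
                  dimnames = list(queries, seq_len(s_max)))
  for (i in seq_along(queries)) {
    v <- match(queries[i], tree$tip.label)
    while (sum(cntm[v, ]) == 0) v <- par[v]
    probs[i, ] <- cntm[v, ] / sum(cntm[v, ])
  }
  pred <- if (point == "expectation") drop(probs %*% seq_len(s_max))
          else apply(probs, 1L, which.max)
  list(pred = stats::setNames(as.numeric(pred), queries), probs = probs)
}

# ---- Sankoff maximum parsimony -----------------------------------------

#' Hidden-state prediction by Sankoff maximum parsimony
#'
#' Dynamic program over integer states: tips cost 0 at their observed
#' state and infinity elsewhere (query tips cost 0 everywhere), and each
#' node's cost per state is the sum over children of the cheapest
#' state-transition-plus-subtree cost. An up-pass (equivalent to rerooting
#' at each node) yields the total cost per state at every node; a query's
#' prediction is the expectation over its minimum-cost states (ties
#' averaged; `point = "argmax"` takes the smallest tied state).
#'
#' @inheritParams hsp_empirical_probabilities
#' @param cost `s_max` x `s_max` transition cost matrix, non-negative with
#'   a zero diagonal; default all-equal (0/1).
#' @return List: `pred` (named numeric), `total_cost` (the tree-wide
#'   minimal parsimony cost), `state_costs` (queries x states matrix).
#' @export
hsp_max_parsimony <- function(tree, known, queries = NULL, s_max = NULL,
                              cost = NULL, point = c("expectation", "argmax")) {
  point <- match.arg(point)
  queries <- .check_hsp_input(tree, known, queries)
  if (any(known != round(known)) || any(known < 1))
    stop("known states must be positive integers")
  s_max <- as.integer(s_max %||% max(known))
  if (is.null(cost)) cost <- 1 - diag(s_max)
  cost <- as.matrix(cost)
  if (any(cost < 0)) stop("negative transition costs")
  if (any(diag(cost) != 0)) stop("cost matrix diagonal must be zero")
  ntip <- length(tree$tip.label)
  n_nodes <- max(tree$edge)

  down <- matrix(0, n_nodes, s_max)
  ki <- match(names(known), tree$tip.label)
  down[ki, ] <- Inf
  down[cbind(ki, as.integer(known))] <- 0

  po <- ape::reorder.phylo(tree, "postorder")$edge
  # contribution of child c to its parent: min_s'(cost[s, s'] + down[c, s'])
  contrib <- matrix(0, n_nodes, s_max)
  for (e in seq_len(nrow(po))) {
    ch <- po[e, 2]
    contrib[ch, ] <- apply(cost, 1L, function(row) min(row + down[ch, ]))
    down[po[e, 1], ] <- down[po[e, 1], ] + contrib[ch, ]
  }
  root <- po[nrow(po), 1]
  total_cost <- min(down[root, ])

  # up-pass: preorder over edges (reverse postorder)
  up <- matrix(0, n_nodes, s_max)
  kids <- split(po[, 2], po[, 1])
  for (e in rev(seq_len(nrow(po)))) {
    v <- po[e, 1]; ch <- po[e, 2]
    sib_sum <- down[v, ] - contrib[ch, ]  # other children's contributions
    A <- up[v, ] + sib_sum
    up[ch, ] <- vapply(seq_len(s_max), function(sp) min(A + cost[, sp]),
                       numeric(1))
  }
  total <- down + up
  state_costs <- total[match(queries, tree$tip.label), , drop = FALSE]
  dimnames(state_costs) <- list(queries, seq_len(s_max))
  pred <- vapply(seq_along(queries), function(i) {
    tc <- state_costs[i, ]
    best <- which(tc <= min(tc) + 1e-9)
    if (point == "expectation") mean(best) else min(best)
  }, numeric(1))
  list(pred = stats::setNames(pred, queries), total_cost = total_cost,
       state_costs = state_costs)
}

# ---- weighted-squared-change parsimony ---------------------------------

#' Hidden-state prediction by weighted-squared-change parsimony
#'
#' Assigns values to all unlabeled nodes (internal nodes and query tips)
#' minimizing `sum over edges of (delta value)^2 / branch length`. The
#' stationarity conditions make each unknown the inverse-branch-length
#' weighted mean of its neighbours, a sparse linear system solved exactly.
#' Zero-length branches are collapsed (their endpoints share one value);
#' `zero_branch = "epsilon"` floors them at 1e-9 instead.
#'
#' @inheritParams hsp_subtree_averaging
#' @param zero_branch "collapse" or "epsilon".
#' @return Named numeric vector of query predictions.
#' @export
hsp_squared_change_parsimony <- function(tree, known, queries = NULL,
                                         zero_branch = c("collapse",
                                                         "epsilon")) {
  zero_branch <- match.arg(zero_branch)
  queries <- .check_hsp_input(tree, known, queries)
  n_nodes <- max(tree$edge)
  len <- tree$edge.length
  if (zero_branch == "epsilon") len <- pmax(len, 1e-9)

  # union-find over zero-length edges -> super-nodes
  group <- seq_len(n_nodes)
  find <- function(i) { while (group[i] != i) i <- group[i]; i }
  if (zero_branch == "collapse") {
    for (e in which(len == 0)) {
      a <- find(tree$edge[e, 1]); b <- find(tree$edge[e, 2])
      if (a != b) group[b] <- a
    }
    group <- vapply(seq_len(n_nodes), find, integer(1))
  }

  ki <- match(names(known), tree$tip.label)
  fixed_val <- rep(NA_real_, n_nodes)
  for (i in seq_along(ki)) {
    g <- group[ki[i]]
    if (!is.na(fixed_val[g]) && fixed_val[g] != known[i]) {
      warning("known tips at zero distance disagree; averaging")
      fixed_val[g] <- mean(c(fixed_val[g], known[i]))
    } else fixed_val[g] <- known[i]
  }

  nodes <- sort(unique(group))
  unknown <- nodes[is.na(fixed_val[nodes])]
  if (length(unknown)) {
    L <- matrix(0, length(unknown), length(unknown))
    rhs <- numeric(length(unknown))
    pos <- stats::setNames(seq_along(unknown), unknown)
    for (e in seq_len(nrow(tree$edge))) {
      if (len[e] == 0) next
      a <- group[tree$edge[e, 1]]; b <- group[tree$edge[e, 2]]
      if (a == b) next
      w <- 1 / len[e]
      a_unk <- is.na(fixed_val[a]); b_unk <- is.na(fixed_val[b])
      if (a_unk) L[pos[[as.character(a)]], pos[[as.character(a)]]] <-
          L[pos[[as.character(a)]], pos[[as.character(a)]]] + w
      if (b_unk) L[pos[[as.character(b)]], pos[[as.character(b)]]] <-
          L[pos[[as.character(b)]], pos[[as.character(b)]]] + w
      if (a_unk && b_unk) {
        i <- pos[[as.character(a)]]; j <- pos[[as.character(b)]]
        L[i, j] <- L[i, j] - w; L[j, i] <- L[j, i] - w
      } else if (a_unk) {
        rhs[pos[[as.character(a)]]] <- rhs[pos[[as.character(a)]]] +
          w * fixed_val[b]
      } else if (b_unk) {
        rhs[pos[[as.character(b)]]] <- rhs[pos[[as.character(b)]]] +
          w * fixed_val[a]
      }
    }
    if (any(diag(L) == 0)) stop("unknown node disconnected from known tips")
    sol <- solve(L, rhs)
    fixed_val[unknown] <- sol
  }
  qi <- match(queries, tree$tip.label)
  stats::setNames(fixed_val[group[qi]], queries)
}

# ---- independent contrasts ---------------------------------------------

#' Hidden-state prediction by phylogenetic independent contrasts
#'
#' Felsenstein's pruning pass, rerooted at each query: subtree estimates
#' are combined with inverse effective-branch-length weights, where each
#' combined subtree inflates its stem branch by the harmonic term
#' `b' = b + prod(b_i') / sum(b_i')`. The estimate delivered at a query
#' tip is the Brownian-motion maximum-likelihood estimate of its state.
#'
#' @inheritParams hsp_subtree_averaging
#' @return Named numeric vector of query predictions.
#' @export
hsp_independent_contrasts <- function(tree, known, queries = NULL) {
  queries <- .check_hsp_input(tree, known, queries)
  n_nodes <- max(tree$edge)
  known_idx <- match(names(known), tree$tip.label)
  val <- rep(NA_real_, n_nodes)
  val[known_idx] <- known

  # adjacency with branch lengths (tree viewed as an unrooted graph)
  adj <- vector("list", n_nodes)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; l <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, l))
    adj[[b]] <- rbind(adj[[b]], c(a, l))
  }

  # message from node v, entered from `from`: ML estimate of v's state
  # using only the part of the tree behind v, plus the extra variance
  est <- function(v, from) {
    if (!is.na(val[v])) return(c(val[v], 0))
    nb <- adj[[v]]
    xs <- numeric(0); ds <- numeric(0)
    for (r in seq_len(nrow(nb))) {
      n <- nb[r, 1]
      if (n == from) next
      m <- est(n, v)
      if (is.null(m)) next
      xs <- c(xs, m[1]); ds <- c(ds, nb[r, 2] + m[2])
    }
    if (!length(xs)) return(NULL)
    if (any(ds < 1e-12)) {
      # zero effective distance: exact interpolation
      return(c(xs[which(ds < 1e-12)[1]], 0))
    }
    w <- 1 / ds
    c(sum(w * xs) / sum(w), 1 / sum(w))
  }

  vapply(stats::setNames(queries, queries), function(q) {
    v <- match(q, tree$tip.label)
    nb <- adj[[v]]
    xs <- numeric(0); ds <- numeric(0)
    for (r in seq_len(nrow(nb))) {
      m <- est(nb[r, 1], v)
      if (is.null(m)) next
      xs <- c(xs, m[1]); ds <- c(ds, nb[r, 2] + m[2])
    }
    if (!length(xs)) stop("query '", q, "' disconnected from known tips")
    if (any(ds < 1e-12)) return(xs[which(ds < 1e-12)[1]])
    w <- 1 / ds
    sum(w * xs) / sum(w)
  }, numeric(1))
}

#' Run all five phylogenetic estimators on one query set
#'
#' Continuous methods (SA, WSCP, PIC) see the values as given; the
#' discrete-state methods (EP, MPR) see them rounded to integer states.
#'
#' @inheritParams hsp_subtree_averaging
#' @return Data frame, one row per query, one column per method.
#' @export
hsp_all_methods <- function(tree, known, queries = NULL) {
  queries <- .check_hsp_input(tree, known, queries)
  ks <- round(known)
  ks[ks < 1] <- 1
  data.frame(
    ep = hsp_empirical_probabilities(tree, ks, queries)$pred,
    sa = hsp_subtree_averaging(tree, known, queries),
    mpr = hsp_max_parsimony(tree, ks, queries)$pred,
    wscp = hsp_squared_change_parsimony(tree, known, queries),
    pic = hsp_independent_contrasts(tree, known, queries),
    row.names = queries)
}
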