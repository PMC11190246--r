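test_that("Newick parsing round-trips and enforces the dialect", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  expect_identical(ape::Ntip(tr), 3L)
  expect_identical(tr$Nnode, 2L)
  expect_warning(t2 <- parse_newick("((A,B),C);"), "branch lengths")
  expect_true(all(t2$edge.length == 0))
  expect_error(parse_newick("((A:1,A:1):1,C:2);"), "duplicate")
  set.seed(14)
  for (i in 1:20) {
    t0 <- rand_tree(sample(4:12, 1), seed = i)
    back <- parse_newick(write_newick(t0))
    expect_identical(sort(back$tip.label), sort(t0$tip.label))
    d0 <- ape::cophenetic.phylo(t0); d1 <- ape::cophenetic.phylo(back)
    expect_equal(d1[rownames(d0), colnames(d0)], d0, tolerance = 1e-8)
  }
})

test_that("subtree averaging matches symmetry cases and brute force", {
  st <- parse_newick("(A:1,B:1,C:1,Q:1);")
  expect_equal(unname(hsp_subtree_averaging(st, c(A = 2, B = 4), "Q")), 3)
  ch <- parse_newick("((K:1,Q:1):1,(X:1,Y:1):1);")
  expect_equal(unname(hsp_subtree_averaging(ch, c(K = 7, X = 1, Y = 2),
                                            "Q")), 7)
  # brute force: walk up from the query, average known descendants
  set.seed(15)
  for (i in 1:50) {
    tr <- rand_tree(10, seed = 100 + i)
    known <- stats::setNames(rnorm(7, 5), paste0("t", 1:7))
    pred <- hsp_subtree_averaging(tr, known)
    par <- gcn16:::.parents(tr)
    desc_known_mean <- function(v) {
      tips <- ape::extract.clade(tr, v)$tip.label
      vals <- known[intersect(tips, names(known))]
      if (length(vals)) mean(vals) else NULL
    }
    for (q in c("t8", "t9", "t10")) {
      v <- match(q, tr$tip.label)
      repeat {
        v <- par[v]
        m <- desc_known_mean(v)
        if (!is.null(m)) break
      }
      expect_equal(unname(pred[q]), m, tolerance = 1e-12)
    }
  }
})

test_that("empirical probabilities count states at the informative ancestor", {
  st <- parse_newick("(A:1,B:1,C:1,Q:1);")
  ep <- hsp_empirical_probabilities(st, c(A = 2, B = 2, C = 4), "Q")
  expect_equal(unname(ep$probs[1, ]), c(0, 2/3, 0, 1/3))
  expect_equal(unname(ep$pred), 8/3)
  # all tips one state: probability one, prediction that state
  ep2 <- hsp_empirical_probabilities(st, c(A = 3, B = 3, C = 3), "Q")
  expect_equal(unname(ep2$pred), 3)
  expect_equal(max(ep2$probs), 1)
  # distributions always sum to one
  set.seed(16)
  for (i in 1:10) {
    tr <- rand_tree(8, seed = 200 + i)
    known <- stats::setNames(sample(1:4, 5, TRUE), paste0("t", 1:5))
    ep3 <- hsp_empirical_probabilities(tr, known, s_max = 4)
    expect_equal(unname(rowSums(ep3$probs)), rep(1, nrow(ep3$probs)))
  }
  # argmax mode returns a modal state
  epm <- hsp_empirical_probabilities(st, c(A = 2, B = 2, C = 4), "Q",
                                     point = "argmax")
  expect_equal(unname(epm$pred), 2)
})

test_that("Sankoff parsimony handles unanimous tips and symmetric ties", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,Q:1):1);")
  mp <- hsp_max_parsimony(tr, c(A = 5, B = 5, C = 5), "Q", s_max = 6)
  expect_equal(unname(mp$pred), 5)
  expect_identical(mp$total_cost, 0)
  tie <- parse_newick("((A:1,B:1):1,Q:1);")
  mp2 <- hsp_max_parsimony(tie, c(A = 1, B = 2), "Q")
  expect_equal(unname(mp2$pred), 1.5)   # tie between states 1 and 2
  expect_identical(mp2$total_cost, 1)
  expect_error(hsp_max_parsimony(tie, c(A = 1, B = 2), "Q",
                                 cost = matrix(-1, 2, 2)), "negative")
})

test_that("weighted-squared-change parsimony solves hand-checkable systems", {
  st <- parse_newick("(A:1,B:1,Q:1);")
  expect_equal(unname(hsp_squared_change_parsimony(st, c(A = 1, B = 5),
                                                   "Q")), 3)
  # one unknown joining tips at distances 1 and 3 valued 0 and 4:
  # x = (0/1 + 4/3) / (1 + 1/3) = 1
  t2 <- parse_newick("(A:1,B:3,Q:0.0000001);")
  expect_equal(unname(hsp_squared_change_parsimony(t2, c(A = 0, B = 4),
                                                   "Q")), 1,
               tolerance = 1e-6)
  # numerical minimizer oracle on random trees: same objective value
  set.seed(17)
  for (i in 1:5) {
    tr <- rand_tree(8, seed = 300 + i)
    known <- stats::setNames(rnorm(6, 5), paste0("t", 1:6))
    pred <- hsp_squared_change_parsimony(tr, known)
    # objective as a function of all unknown node values
    ntip <- 8; nn <- max(tr$edge)
    unknown <- c(7:8, (ntip + 1):nn)
    obj <- function(p) {
      val <- numeric(nn)
      val[1:6] <- known
      val[unknown] <- p
      sum((val[tr$edge[, 1]] - val[tr$edge[, 2]])^2 / tr$edge.length)
    }
    opt <- optim(rep(mean(known), length(unknown)), obj, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-15))
    expect_equal(unname(pred[c("t7", "t8")]), opt$par[1:2],
                 tolerance = 1e-5)
  }
})

test_that("independent contrasts reduce to known closed forms", {
  # ultrametric symmetric quartet: prediction is the unweighted tip mean
  sym <- parse_newick("((A:1,B:1):1,(C:1,Q:1):1);")
  known <- c(A = 2, B = 4, C = 9)
  # by pruning: AB ancestor = 3 with inflated branch 1.5; combine with C
  p <- hsp_independent_contrasts(sym, known, "Q")
  w <- hsp_squared_change_parsimony(sym, known, "Q")
  expect_equal(unname(p), unname(w), tolerance = 1e-9)
  # 2-tip case equals the inverse-branch-length weighted mean
  t2 <- parse_newick("(A:1,B:3,Q:0.0000001);")
  expect_equal(unname(hsp_independent_contrasts(t2, c(A = 0, B = 4), "Q")),
               1, tolerance = 1e-6)
  star <- parse_newick("(A:2,B:2,C:2,Q:2);")
  expect_equal(unname(hsp_independent_contrasts(star,
                                                c(A = 1, B = 2, C = 6),
                                                "Q")), 3, tolerance = 1e-9)
})

test_that("distance-aware methods interpolate a zero-distance query", {
  # maximum parsimony is excluded: its cost objective ignores branch
  # lengths, so a zero-length cherry is invisible to it
  tr <- parse_newick("((A:0.0,Q:0.0):1,(B:1,C:2):1);")
  known <- c(A = 7, B = 1, C = 3)
  expect_equal(unname(hsp_subtree_averaging(tr, known, "Q")), 7)
  expect_equal(unname(hsp_squared_change_parsimony(tr, known, "Q")), 7,
               tolerance = 1e-9)
  expect_equal(unname(hsp_independent_contrasts(tr, known, "Q")), 7,
               tolerance = 1e-9)
  ep <- hsp_empirical_probabilities(tr, known, "Q")
  expect_equal(unname(ep$pred), 7)
})

test_that("predictions stay within the convex hull of known values", {
  set.seed(18)
  for (i in 1:10) {
    tr <- rand_tree(12, seed = 400 + i)
    known <- stats::setNames(runif(8, 1, 9), paste0("t", 1:8))
    q <- paste0("t", 9:12)
    lo <- min(known) - 1e-9; hi <- max(known) + 1e-9
    for (v in list(hsp_subtree_averaging(tr, known, q),
                   hsp_squared_change_parsimony(tr, known, q),
                   hsp_independent_contrasts(tr, known, q))) {
      expect_true(all(v >= lo & v <= hi))
    }
    ki <- round(known); ki[ki < 1] <- 1
    ep <- hsp_empirical_probabilities(tr, ki, q)$pred
    mp <- hsp_max_parsimony(tr, ki, q)$pred
    expect_true(all(ep >= min(ki) & ep <= max(ki)))
    expect_true(all(mp >= min(ki) & mp <= max(ki)))
  }
})

test_that("input order of known tips and queries does not matter", {
  set.seed(19)
  tr <- rand_tree(10, seed = 500)
  known <- stats::setNames(rnorm(7, 5), paste0("t", 1:7))
  q <- paste0("t", 8:10)
  p1 <- hsp_all_methods(tr, known, q)
  perm <- sample(7)
  p2 <- hsp_all_methods(tr, known[perm], rev(q))
  expect_equal(p2[q, ], p1[q, ], tolerance = 1e-12)
})

test_that("zero-length branch collapsing equals the epsilon-floor limit", {
  tr <- parse_newick("((A:0,B:1):1,(Q:1,C:2):0.5);")
  known <- c(A = 2, B = 6, C = 3)
  col <- hsp_squared_change_parsimony(tr, known, "Q",
                                      zero_branch = "collapse")
  eps <- hsp_squared_change_parsimony(tr, known, "Q",
                                      zero_branch = "epsilon")
  expect_equal(unname(col), unname(eps), tolerance = 1e-6)
})
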