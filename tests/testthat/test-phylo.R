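test_that("pairwise distances match closed forms and cap saturated pairs", {
  aln <- ungapped_alignment(c(a = "AAAA", b = "AAAV"))
  expect_equal(unname(pairwise_distances(aln, "p_distance")["a", "b"]), 0.25)
  expect_equal(unname(pairwise_distances(aln, "poisson")["a", "b"]),
               -log(0.75), tolerance = 1e-12)
  expect_equal(unname(pairwise_distances(aln, "kimura_protein")["a", "b"]),
               -log(1 - 0.25 - 0.25^2 / 5), tolerance = 1e-12)
  ident <- ungapped_alignment(c(a = "MKLV", b = "MKLV"))
  expect_equal(unname(pairwise_distances(ident)["a", "b"]), 0)
  ## saturation: p = 0.9 -> capped at 10 with warning
  sat <- ungapped_alignment(c(a = "AAAAAAAAAA", b = "VVVVVVVVVA"))
  expect_warning(D <- pairwise_distances(sat), "capped")
  expect_equal(unname(D["a", "b"]), 10)
  ## gaps/X are pairwise-deleted; a pair with no comparable columns errors
  gap <- ungapped_alignment(c(a = "AA--", b = "--AA", c = "AAAA"))
  expect_error(pairwise_distances(gap), "no comparable columns.*a.*b")
})

test_that("neighbor joining recovers additive trees exactly", {
  set.seed(71)
  for (r in 1:10) {
    tr <- ape::rtree(6)
    D <- ape::cophenetic.phylo(tr)
    nj <- neighbor_joining(D[tr$tip.label, tr$tip.label])
    expect_setequal(bipartitions(nj), bipartitions(tr))
  }
  expect_error(neighbor_joining(matrix(0, 2, 2,
                                       dimnames = list(c("a", "b"),
                                                       c("a", "b")))),
               "at least 3")
})

test_that("three leaves resolve by the three-point formulas", {
  D <- matrix(c(0, 5, 7, 5, 0, 8, 7, 8, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  pend <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                          tr$tip.label)
  expect_equal(unname(pend[c("a", "b", "c")]), c(2, 3, 5))
})

test_that("leaf input order does not change the inferred topology", {
  set.seed(72)
  tr <- ape::rtree(7)
  D <- ape::cophenetic.phylo(tr)
  ids <- rownames(D)
  perm <- sample(ids)
  t1 <- neighbor_joining(D[ids, ids])
  t2 <- neighbor_joining(D[perm, perm])
  expect_setequal(bipartitions(t1), bipartitions(t2))
})

test_that("negative NJ branch lengths are clamped to zero", {
  ## non-additive matrix known to push NJ lengths negative
  D <- matrix(c(0, 1, 6, 6, 1, 0, 6, 6, 6, 6, 0, 1, 6, 6, 1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  D["a", "b"] <- D["b", "a"] <- 5.9  # break symmetry of the split slightly
  tr <- neighbor_joining(D)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports are reproducible and bounded by n_reps", {
  bundle <- cached_mini_bundle()
  aln <- bundle$alignments[["Rae1"]]
  t1 <- bootstrap_supports(aln, n_reps = 30, seed = 5)
  t2 <- bootstrap_supports(aln, n_reps = 30, seed = 5)
  expect_identical(write_newick(t1), write_newick(t2))
  s <- node_supports(t1)
  expect_true(all(stats::na.omit(s) >= 0 & stats::na.omit(s) <= 100))
  one <- bootstrap_supports(aln, n_reps = 1, seed = 5)
  expect_true(all(stats::na.omit(node_supports(one)) %in% c(0L, 100L)))
  small <- aa_alignment("s", c(a = "MKL", b = "MKL", c = "MLL"), taxa = "T")
  expect_warning(bootstrap_supports(small, n_reps = 5, seed = 1),
                 "fewer than 4")
})

test_that("clearly separated clades earn high support across seeds", {
  ## two clades split by a long internal edge
  sp <- ape::read.tree(text = "((a:0.05,b:0.05,c:0.05):0.5,(d:0.05,e:0.05,f:0.05):0.5);")
  fam <- evolve_family(sp, root_length = 300, rate = 0.6, seed = 77)
  aln <- aa_alignment("sep", fam$tips, taxa = "T")
  good <- 0
  for (s in 1:10) {
    tr <- bootstrap_supports(aln, n_reps = 100, seed = s)
    sup <- bipartition_support(tr, c("a", "b", "c"))
    if (!is.na(sup) && sup >= 95) good <- good + 1
  }
  expect_gte(good, 9)
})

test_that("midpoint rooting splits the longest leaf path in half", {
  ## symmetric quartet: root lands on the central edge
  q <- read_newick("((a:1,b:1):1,(c:1,d:1):1);")
  r <- midpoint_root(ape::unroot(q))
  d <- ape::dist.nodes(r)
  root <- length(r$tip.label) + 1L
  depths <- d[root, 1:4]
  expect_equal(max(depths), min(depths))
  ## pendant arithmetic: path a-b of length 10, a's pendant edge 9
  t2 <- midpoint_root(read_newick("(a:9,(b:0.6,c:0.4):0.4);"))
  d2 <- ape::dist.nodes(t2)
  root2 <- length(t2$tip.label) + 1L
  expect_equal(unname(d2[root2, match("a", t2$tip.label)]), 5)
  expect_equal(unname(d2[root2, match("b", t2$tip.label)]), 5)
  expect_error(midpoint_root(read_newick("(a,b,c);")), "zero")
})

test_that("the two farthest leaves are equidistant from the midpoint root", {
  set.seed(73)
  for (r in 1:20) {
    tr <- ape::unroot(ape::rtree(sample(5:10, 1)))
    rooted <- midpoint_root(tr)
    d <- ape::cophenetic.phylo(rooted)
    far <- which(d == max(d), arr.ind = TRUE)[1, ]
    dn <- ape::dist.nodes(rooted)
    root <- length(rooted$tip.label) + 1L
    expect_lt(abs(dn[root, far[1]] - dn[root, far[2]]), 1e-9)
  }
})

test_that("re-rooting preserves bipartitions, length, and supports", {
  bundle <- cached_mini_bundle()
  tr <- bootstrap_supports(bundle$alignments[["Sec13"]], n_reps = 25,
                           seed = 9)
  rooted <- midpoint_root(tr)
  expect_setequal(bipartitions(rooted), bipartitions(tr))
  expect_equal(sum(rooted$edge.length), sum(tr$edge.length),
               tolerance = 1e-9)
  ## every supported bipartition keeps its value across the re-rooting
  idx <- egtscreen:::tree_index(tr)
  sup <- node_supports(tr)
  ntip <- idx$ntip
  for (node in (ntip + 1L):(ntip + idx$nnode)) {
    s <- sup[node - ntip]
    if (is.na(s)) next
    side <- tr$tip.label[idx$leafsets[[node]]]
    expect_equal(bipartition_support(rooted, side), s)
  }
})

test_that("long-branch leaves are flagged against the median pendant", {
  tr <- read_newick("((a:0.1,b:0.1):0.1,(c:0.1,weird:2.0):0.1);")
  expect_equal(flag_long_branches(tr, k = 5), "weird")
  expect_equal(length(flag_long_branches(tr, k = 25)), 0L)
})
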