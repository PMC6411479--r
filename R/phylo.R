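## phylo: corrected-distance neighbor-joining trees with nonparametric
## column-bootstrap supports and midpoint rooting. These are the desk-scale
## machinery behind the provenance classifier; externally computed Newick
## trees can be imported through read_newick() instead.

## Per-pair mismatch / comparable-column counts over a character matrix.
## Pairwise deletion: a column is comparable for a pair when both residues
## are canonical amino acids (gaps and X are dropped for that pair).
pair_indicator_matrices <- function(mat) {
  n <- nrow(mat)
  valid <- matrix(mat %in% AA20, nrow = n)
  pairs <- utils::combn(n, 2)
  np <- ncol(pairs)
  comp <- matrix(FALSE, nrow = np, ncol = ncol(mat))
  mism <- matrix(FALSE, nrow = np, ncol = ncol(mat))
  for (p in seq_len(np)) {
    i <- pairs[1, p]; j <- pairs[2, p]
    comp[p, ] <- valid[i, ] & valid[j, ]
    mism[p, ] <- comp[p, ] & (mat[i, ] != mat[j, ])
  }
  list(pairs = pairs, comp = comp, mism = mism)
}

## Apply a distance correction to a p-distance, with saturation capping.
correct_distance <- function(p, correction, p_cap = 0.85, max_dist = 10.0) {
  capped <- p >= p_cap
  d <- switch(correction,
              p_distance = p,
              poisson = -log(1 - pmin(p, 1 - 1e-12)),
              kimura_protein = {
                arg <- 1 - p - p^2 / 5
                -log(pmax(arg, 1e-12))
              })
  d[capped] <- max_dist
  list(d = d, n_capped = sum(capped))
}

#' Pairwise corrected distances from an alignment
#'
#' The mismatch fraction p is computed per pair over pairwise-deleted
#' columns (both residues canonical). Corrections: `p_distance` (none),
#' `poisson` (`-ln(1 - p)`), `kimura_protein` (`-ln(1 - p - p^2/5)`,
#' the default). Pairs at or beyond the saturation cap (`p >= 0.85`) are set
#' to the maximum distance 10 with a warning.
#'
#' @param alignment An [aa_alignment()] with at least 2 rows.
#' @param correction Distance correction.
#' @param p_cap Saturation cap on p.
#' @param max_dist Distance assigned to saturated pairs.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = row ids.
#' @export
pairwise_distances <- function(alignment,
                               correction = c("kimura_protein", "poisson",
                                              "p_distance"),
                               p_cap = 0.85, max_dist = 10.0) {
  correction <- match.arg(correction)
  stopifnot(length(alignment$seqs) >= 2L)
  mat <- alignment_matrix(alignment)
  ind <- pair_indicator_matrices(mat)
  ncomp <- rowSums(ind$comp)
  if (any(ncomp == 0L)) {
    p0 <- which(ncomp == 0L)[1L]
    stop(sprintf("no comparable columns between '%s' and '%s'",
                 rownames(mat)[ind$pairs[1, p0]],
                 rownames(mat)[ind$pairs[2, p0]]))
  }
  p <- rowSums(ind$mism) / ncomp
  corr <- correct_distance(p, correction, p_cap, max_dist)
  if (corr$n_capped > 0L) {
    warning(sprintf("%d pair(s) at p >= %.2f capped to distance %.1f",
                    corr$n_capped, p_cap, max_dist))
  }
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (pidx in seq_len(ncol(ind$pairs))) {
    i <- ind$pairs[1, pidx]; j <- ind$pairs[2, pidx]
    D[i, j] <- D[j, i] <- corr$d[pidx]
  }
  D
}

## Clamp negative NJ branch lengths to zero, moving each deficit onto a
## sibling edge so the inter-subtree path length through the parent is
## preserved. A sibling pushed negative in turn is clamped without further
## propagation.
clamp_negative_branches <- function(tree) {
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    parent <- tree$edge[e, 1]
    sibs <- which(tree$edge[, 1] == parent)
    sibs <- setdiff(sibs, e)
    if (length(sibs) > 0L) {
      s <- sibs[1L]
      tree$edge.length[s] <- tree$edge.length[s] + deficit
    }
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Q-criterion neighbor joining (via [ape::nj()]), post-processed so
#' branch lengths are nonnegative: a negative length is clamped to zero and
#' the deficit moved to a sibling edge. Deterministic: the pair-selection
#' scan always takes the first minimum.
#'
#' @param D Symmetric distance matrix with dimnames (at least 3 leaves).
#' @return Unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(D) {
  if (nrow(D) < 3L) stop("neighbor joining needs at least 3 leaves")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric")
  tree <- ape::nj(stats::as.dist(D))
  clamp_negative_branches(tree)
}

## Distance matrix from precomputed pair indicators restricted to a column
## sample (used by the bootstrap); saturated/zero-comparable pairs get the
## maximum distance.
distances_from_indicators <- function(ind, ids, cols, correction,
                                      p_cap = 0.85, max_dist = 10.0) {
  ncomp <- rowSums(ind$comp[, cols, drop = FALSE])
  nmism <- rowSums(ind$mism[, cols, drop = FALSE])
  p <- ifelse(ncomp == 0L, 1, nmism / pmax(ncomp, 1L))
  d <- correct_distance(p, correction, p_cap, max_dist)$d
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (pidx in seq_len(ncol(ind$pairs))) {
    i <- ind$pairs[1, pidx]; j <- ind$pairs[2, pidx]
    D[i, j] <- D[j, i] <- d[pidx]
  }
  D
}

#' Neighbor-joining tree with nonparametric bootstrap supports
#'
#' Builds the point-estimate NJ tree from the full alignment, then resamples
#' alignment columns with replacement `n_reps` times, rebuilds a tree per
#' replicate, and annotates each internal edge of the point tree with the
#' percentage of replicates containing the same bipartition
#' (`node.label`, integer 0-100). Reproducible given `seed`.
#'
#' @param alignment An [aa_alignment()].
#' @param n_reps Number of bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @param correction Distance correction (see [pairwise_distances()]).
#' @return Unrooted [ape::phylo] with supports in `node.label`.
#' @export
bootstrap_supports <- function(alignment, n_reps = 100L, seed,
                               correction = "kimura_protein") {
  stopifnot(n_reps >= 1L)
  if (length(alignment$seqs) < 4L) {
    warning("fewer than 4 rows: bootstrap supports are undefined")
    D <- pairwise_distances(alignment, correction)
    tree <- neighbor_joining(D)
    tree$node.label <- rep("", tree$Nnode)
    return(tree)
  }
  mat <- alignment_matrix(alignment)
  ids <- rownames(mat)
  ind <- pair_indicator_matrices(mat)
  all_cols <- seq_len(ncol(mat))
  D0 <- distances_from_indicators(ind, ids, all_cols, correction)
  point <- neighbor_joining(D0)
  reps <- withr::with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(ncol(mat), replace = TRUE)
      neighbor_joining(distances_from_indicators(ind, ids, cols, correction))
    })
  })
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- as.integer(round(100 * counts / n_reps))
  point$node.label <- as.character(support)
  ## the root "node" of an unrooted tree carries no meaningful bipartition
  point$node.label[1L] <- ""
  point
}

#' Midpoint-root a tree
#'
#' Places the root halfway along the longest leaf-to-leaf path
#' (via [phangorn::midpoint()]); support labels stay attached to the same
#' bipartitions across the re-rooting.
#'
#' @param tree Unrooted [ape::phylo] with branch lengths.
#' @return Rooted [ape::phylo].
#' @export
midpoint_root <- function(tree) {
  if (length(tree$tip.label) < 2L) stop("need at least 2 leaves")
  if (is.null(tree$edge.length) || all(tree$edge.length == 0)) {
    stop("all branch lengths are zero; midpoint undefined ",
         "(root arbitrarily instead, e.g. ape::root)")
  }
  has_support <- !is.null(tree$node.label)
  rooted <- phangorn::midpoint(tree,
                               node.labels = if (has_support) "support"
                                             else "label")
  rooted
}

#' Unrooted bipartition set of a tree
#'
#' Each internal edge contributes the lexicographically smaller side of its
#' leaf split, as a sorted, collapsed string. Used for isomorphism checks.
#'
#' @param tree An [ape::phylo].
#' @return Character vector (sorted) of bipartition keys.
#' @export
bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  keys <- vapply(parts, function(idx) {
    side <- sort(labs[idx])
    other <- setdiff(tips, side)
    a <- paste(side, collapse = ",")
    b <- paste(other, collapse = ",")
    if (a < b) a else b
  }, "")
  ## drop trivial splits (singleton or near-complete sides)
  k <- vapply(strsplit(keys, ","), length, 1L)
  keys <- keys[k >= 2L & k <= length(tips) - 2L]
  sort(unique(keys))
}

#' Flag long-branch leaves
#'
#' Reference taxa on conspicuously long pendant branches (typically fast
#' evolving parasites) distort distance trees. This flags leaves whose
#' pendant edge exceeds `k` times the median pendant length; the filter is
#' advisory and off by default in the pipeline — the original curation was
#' done by eye and no objective criterion is recorded.
#'
#' @param tree An [ape::phylo].
#' @param k Multiplier on the median pendant branch length (default 5).
#' @return Character vector of leaf labels exceeding the threshold.
#' @export
flag_long_branches <- function(tree, k = 5) {
  ntip <- length(tree$tip.label)
  pend <- tree$edge.length[match(seq_len(ntip), tree$edge[, 2])]
  med <- stats::median(pend)
  if (med == 0) return(character(0))
  tree$tip.label[pend > k * med]
}
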