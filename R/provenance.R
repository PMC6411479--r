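## provenance: iterative paralog purging on support-annotated gene trees and
## host-vs-algal affinity classification of accepted query proteins.

## Per-node tip index sets, parents, and a root id for an ape phylo.
tree_index <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  total <- ntip + nnode
  kids <- vector("list", total)
  parent <- rep(NA_integer_, total)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
    kids[[p]] <- c(kids[[p]], c)
    parent[c] <- p
  }
  leafsets <- vector("list", total)
  for (t in seq_len(ntip)) leafsets[[t]] <- t
  ## accumulate in edge postorder so children precede parents
  po <- ape::postorder(tree)
  for (e in po) {
    p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
    leafsets[[p]] <- c(leafsets[[p]], leafsets[[c]])
  }
  root <- which(is.na(parent))[1]
  list(ntip = ntip, nnode = nnode, kids = kids, parent = parent,
       leafsets = leafsets, root = root)
}

## Support value of the clade below an internal node (NA for tips/root).
clade_support <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(NA_integer_)
  sup <- node_supports(tree)
  sup[node - ntip]
}

## Resolve each tip's role from a taxon->role map plus a tip->taxon map.
tip_roles <- function(tree, roles, leaf_taxa) {
  missing <- setdiff(tree$tip.label, names(leaf_taxa))
  if (length(missing) > 0L) {
    stop("no taxon known for leaf/leaves: ", paste(missing, collapse = ", "))
  }
  taxa <- leaf_taxa[tree$tip.label]
  unknown <- setdiff(unique(taxa), names(roles))
  if (length(unknown) > 0L) {
    stop("no role assigned for taxon/taxa: ", paste(unknown, collapse = ", "))
  }
  stats::setNames(unname(roles[taxa]), tree$tip.label)
}

## Walk from a query tip to its maximal all-query clade, then to the parent
## joining that unit to the rest of the tree. Returns NULL when the whole
## tree is query-only.
query_unit_context <- function(idx, tip, is_query_node) {
  u <- tip
  while (!is.na(idx$parent[u]) && is_query_node[idx$parent[u]]) {
    u <- idx$parent[u]
  }
  a <- idx$parent[u]
  if (is.na(a)) return(NULL)
  sister_tips <- setdiff(idx$leafsets[[a]], idx$leafsets[[u]])
  list(unit = u, anc = a, sister_tips = sister_tips)
}

#' Classify the phylogenetic provenance of query proteins
#'
#' For each query-lineage leaf of a rooted, support-annotated gene tree, the
#' maximal clade of query leaves containing it is collapsed into a unit and
#' joined to the rest of the tree at its parent node. The reference leaves
#' on the other side of that node form the sister composition; the call is
#' `host_related` when at least `purity` of them are host-outgroup taxa,
#' `algal_related` when at least `purity` are endosymbiont-algal taxa, and
#' `ambiguous` otherwise. Any host/algal label is demoted to `ambiguous`
#' unless the support of the joining clade is strictly greater than
#' `support_threshold`. Leaves in a tree without reference leaves are
#' `unclassifiable`.
#'
#' @param tree Rooted [ape::phylo] (midpoint-root first), supports in
#'   `node.label`.
#' @param roles Named character vector taxon -> role (see [taxon_roles()]).
#' @param leaf_taxa Named character vector leaf id -> taxon.
#' @param family Family name recorded on the calls.
#' @param support_threshold Calls require support strictly over this
#'   (default 70).
#' @param purity Minimum sister-composition fraction for a host/algal call
#'   (default 0.8).
#' @return `data.frame` with one row per query leaf: `protein`, `taxon`,
#'   `family`, `label`, `support`, `sister_host`, `sister_algal`,
#'   `sister_other`.
#' @export
classify_affinity <- function(tree, roles, leaf_taxa, family = NA_character_,
                              support_threshold = 70L, purity = 0.8) {
  if (!ape::is.rooted(tree)) {
    stop("tree must be rooted; run midpoint_root() first")
  }
  rbt <- tip_roles(tree, roles, leaf_taxa)
  idx <- tree_index(tree)
  ntip <- idx$ntip
  is_query_tip <- rbt == "query_host_lineage"
  ## per-node: does the subtree contain only query leaves?
  is_query_node <- vapply(idx$leafsets, function(ls) {
    all(is_query_tip[ls])
  }, TRUE)
  sup <- node_supports(tree)
  query_tips <- sort(tree$tip.label[is_query_tip[tree$tip.label]])
  rows <- lapply(query_tips, function(lab) {
    tip <- match(lab, tree$tip.label)
    ctx <- query_unit_context(idx, tip, is_query_node)
    if (is.null(ctx)) {
      return(data.frame(protein = lab, taxon = unname(leaf_taxa[lab]),
                        family = family, label = "unclassifiable",
                        support = NA_integer_, sister_host = 0L,
                        sister_algal = 0L, sister_other = 0L,
                        stringsAsFactors = FALSE))
    }
    sis_roles <- rbt[tree$tip.label[ctx$sister_tips]]
    refs <- sis_roles[sis_roles != "query_host_lineage"]
    n_host <- sum(refs == "host_outgroup")
    n_algal <- sum(refs == "endosymbiont_algal")
    n_other <- sum(refs == "other_reference")
    n_ref <- length(refs)
    if (n_ref == 0L) {
      label <- "unclassifiable"
      support <- NA_integer_
    } else {
      ## support of the clade joining the query unit to its sister; at the
      ## root that clade is trivial, so fall back to the equivalent
      ## unit-vs-rest bipartition (other root child, else the unit itself)
      if (ctx$anc != idx$root) {
        support <- sup[ctx$anc - ntip]
      } else {
        others <- setdiff(idx$kids[[idx$root]], ctx$unit)
        cand <- c(others[others > ntip], if (ctx$unit > ntip) ctx$unit)
        support <- if (length(cand) > 0L) sup[cand[1L] - ntip] else NA_integer_
      }
      label <- if (n_host / n_ref >= purity) "host_related"
               else if (n_algal / n_ref >= purity) "algal_related"
               else "ambiguous"
      if (label != "ambiguous" &&
          (is.na(support) || support <= support_threshold)) {
        label <- "ambiguous"
      }
    }
    data.frame(protein = lab, taxon = unname(leaf_taxa[lab]), family = family,
               label = label, support = support, sister_host = n_host,
               sister_algal = n_algal, sister_other = n_other,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Accept true orthologs after paralog purging
#'
#' A query leaf is retained if (a) the sister context of its query unit
#' contains at least one reference leaf of this family — in a single-family
#' gene tree every reference leaf qualifies — or (b) its best-profile
#' assignment matches this family with a margin of at least `margin_min`
#' bits over the runner-up.
#'
#' @param tree Rooted gene tree.
#' @param roles Taxon -> role map.
#' @param leaf_taxa Leaf id -> taxon map.
#' @param annotations `data.frame` with columns `protein`,
#'   `assigned_family`, `margin` for the query leaves.
#' @param family The family under analysis.
#' @param margin_min Minimum assignment margin in bits for rule (b).
#' @return Character vector of retained query protein ids.
#' @export
accept_orthologs <- function(tree, roles, leaf_taxa, annotations, family,
                             margin_min = 2.0) {
  rbt <- tip_roles(tree, roles, leaf_taxa)
  idx <- tree_index(tree)
  is_query_tip <- rbt == "query_host_lineage"
  is_query_node <- vapply(idx$leafsets, function(ls) all(is_query_tip[ls]),
                          TRUE)
  keep <- character(0)
  for (lab in tree$tip.label[is_query_tip[tree$tip.label]]) {
    tip <- match(lab, tree$tip.label)
    ctx <- query_unit_context(idx, tip, is_query_node)
    rule_a <- FALSE
    if (!is.null(ctx)) {
      sis_roles <- rbt[tree$tip.label[ctx$sister_tips]]
      rule_a <- any(sis_roles != "query_host_lineage")
    }
    ann <- annotations[annotations$protein == lab, , drop = FALSE]
    rule_b <- nrow(ann) > 0L && !is.na(ann$assigned_family[1L]) &&
      ann$assigned_family[1L] == family && ann$margin[1L] >= margin_min
    if (rule_a || rule_b) keep <- c(keep, lab)
  }
  sort(keep)
}

#' Iteratively purge paralogous hits from a family alignment
#'
#' Mirrors tree-based cleaning cycles: per cycle the augmented alignment
#' (references plus surviving hits) is turned into a midpoint-rooted,
#' bootstrap-supported NJ tree; every maximal clade whose support exceeds
#' `support_threshold` and in which more than half of the annotated query
#' leaves are assigned to a different family is treated as a paralog clade,
#' and its query leaves are removed. Survivors are re-inserted via
#' [align_to_profile()] and the cycle repeats until nothing is removed or
#' `max_cycles` is reached (default 3, a hard cap).
#'
#' @param alignment Reference [aa_alignment()] for the family.
#' @param profile Calibrated or uncalibrated `profile_hmm` of the family.
#' @param hits `data.frame` of query hits: `id`, `taxon`, `sequence`,
#'   `nterm`, `assigned_family`, `margin`.
#' @param roles Taxon -> role map.
#' @param max_cycles Maximum number of clean-rebuild cycles.
#' @param support_threshold Clade removal requires support strictly over
#'   this.
#' @param n_boot Bootstrap replicates per cycle.
#' @param seed Integer seed.
#' @return List: `alignment` (clean augmented alignment), `survivors`
#'   (query ids kept), `tree` (final rooted tree when the run converged,
#'   else `NULL`), `report` (per-cycle removals, `cycles_run`, `converged`).
#' @export
purge_paralogs <- function(alignment, profile, hits, roles, max_cycles = 3L,
                           support_threshold = 70L, n_boot = 100L, seed = 1L) {
  family <- alignment$family
  survivors <- hits
  cycles <- list()
  converged <- FALSE
  final_tree <- NULL
  aug <- augment_family_alignment(alignment, profile, survivors)
  cycles_run <- 0L
  for (cyc in seq_len(max_cycles)) {
    cycles_run <- cyc
    tree <- bootstrap_supports(aug, n_reps = n_boot,
                               seed = stage_seed(seed, paste0("purge", cyc)))
    rooted <- midpoint_root(tree)
    leaf_taxa <- stats::setNames(
      c(alignment$taxa, survivors$taxon),
      c(names(alignment$seqs), survivors$id))[rooted$tip.label]
    idx <- tree_index(rooted)
    sup <- node_supports(rooted)
    ntip <- idx$ntip
    ann <- stats::setNames(survivors$assigned_family, survivors$id)
    qualifying <- integer(0)
    for (node in (ntip + 1L):(ntip + idx$nnode)) {
      s <- sup[node - ntip]
      if (is.na(s) || s <= support_threshold) next
      leaves <- rooted$tip.label[idx$leafsets[[node]]]
      annotated <- leaves[leaves %in% names(ann) & !is.na(ann[leaves])]
      if (length(annotated) == 0L) next
      if (mean(ann[annotated] != family) > 0.5) {
        qualifying <- c(qualifying, node)
      }
    }
    ## keep only maximal qualifying clades
    maximal <- qualifying[vapply(qualifying, function(node) {
      p <- idx$parent[node]
      while (!is.na(p)) {
        if (p %in% qualifying) return(FALSE)
        p <- idx$parent[p]
      }
      TRUE
    }, TRUE)]
    removed <- character(0)
    reasons <- character(0)
    for (node in maximal) {
      leaves <- rooted$tip.label[idx$leafsets[[node]]]
      q <- leaves[leaves %in% survivors$id]
      annotated <- q[!is.na(ann[q])]
      maj <- names(sort(table(ann[annotated]), decreasing = TRUE))[1L]
      removed <- c(removed, q)
      reasons <- c(reasons,
                   rep(sprintf("clade of %d leaves grouped with '%s' (support %d)",
                               length(leaves), maj, sup[node - ntip]),
                       length(q)))
    }
    cycles[[cyc]] <- data.frame(protein = removed, reason = reasons,
                                stringsAsFactors = FALSE)
    if (length(removed) == 0L) {
      converged <- TRUE
      final_tree <- rooted
      break
    }
    survivors <- survivors[!survivors$id %in% removed, , drop = FALSE]
    aug <- augment_family_alignment(alignment, profile, survivors)
  }
  list(alignment = aug, survivors = survivors$id, tree = final_tree,
       report = list(family = family, cycles = cycles,
                     cycles_run = cycles_run, converged = converged))
}
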