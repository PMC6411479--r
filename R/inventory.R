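## inventory: the per-family x per-taxon copy-number/affinity/targeting
## matrix (the machine-readable form of a circle-grid nucleoporin figure),
## the completeness proxy replacing an external single-copy-ortholog scan,
## absence corroboration across related taxa, and the subcomplex summary.

#' Assemble the family-by-taxon inventory matrix
#'
#' One cell per (registry family, query taxon); the cell's copies carry the
#' affinity call and the targeting evidence of each retained protein.
#' Ordering is deterministic: registry order for families, name order within
#' role for taxa.
#'
#' @param calls Affinity calls restricted to retained orthologs
#'   (see [classify_affinity()]).
#' @param evidence Targeting evidence (see [targeting_evidence()]).
#' @param registry Family registry `data.frame`.
#' @param roles Taxon -> role map.
#' @return An `npc_inventory`: list with `cells` (long `data.frame`:
#'   `family`, `taxon`, `copy_index`, `protein`, `affinity`, `sp`, `nterm`),
#'   `families`, `taxa`, `completeness` (NA until
#'   [completeness_proxy()] fills it), `absences`.
#' @export
build_matrix <- function(calls, evidence, registry, roles) {
  bad <- setdiff(unique(calls$family), registry$family)
  if (length(bad) > 0L) {
    stop("call(s) reference unregistered family/families: ",
         paste(bad, collapse = ", "))
  }
  taxa <- sort(names(roles)[roles == "query_host_lineage"])
  families <- registry$family
  ## deterministic cell ordering regardless of call input order
  calls <- calls[order(match(calls$family, families), calls$taxon,
                       calls$protein), , drop = FALSE]
  ev <- evidence[match(calls$protein, evidence$protein), , drop = FALSE]
  cells <- data.frame(family = character(0), taxon = character(0),
                      copy_index = integer(0), protein = character(0),
                      affinity = character(0), sp = logical(0),
                      nterm = logical(0), stringsAsFactors = FALSE)
  for (f in families) {
    for (tx in taxa) {
      sel <- which(calls$family == f & calls$taxon == tx)
      if (length(sel) == 0L) {
        cells <- rbind(cells, data.frame(
          family = f, taxon = tx, copy_index = 0L, protein = NA_character_,
          affinity = NA_character_, sp = NA, nterm = NA,
          stringsAsFactors = FALSE))
      } else {
        for (j in seq_along(sel)) {
          i <- sel[j]
          cells <- rbind(cells, data.frame(
            family = f, taxon = tx, copy_index = j,
            protein = calls$protein[i], affinity = calls$label[i],
            sp = ev$sp_predicted[i], nterm = ev$nterm_complete[i],
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  structure(list(cells = cells, families = families, taxa = taxa,
                 completeness = stats::setNames(rep(NA_real_, length(taxa)),
                                                taxa),
                 absences = NULL),
            class = "npc_inventory")
}

#' @export
print.npc_inventory <- function(x, ...) {
  found <- x$cells[x$cells$copy_index > 0L, , drop = FALSE]
  cat(sprintf("npc_inventory: %d families x %d taxa, %d protein copies\n",
              length(x$families), length(x$taxa), nrow(found)))
  invisible(x)
}

#' Copy counts of an inventory
#' @param matrix An `npc_inventory`.
#' @return Integer matrix family x taxon.
#' @export
copy_counts <- function(matrix) {
  out <- base::matrix(0L, nrow = length(matrix$families),
                      ncol = length(matrix$taxa),
                      dimnames = list(matrix$families, matrix$taxa))
  found <- matrix$cells[matrix$cells$copy_index > 0L, , drop = FALSE]
  if (nrow(found) > 0L) {
    tab <- table(found$family, found$taxon)
    out[rownames(tab), colnames(tab)] <- as.integer(tab)
  }
  out
}

#' Per-taxon completeness proxy
#'
#' The fraction of control families with at least one retained hit in the
#' taxon, standing in for an external universal-single-copy-ortholog scan.
#' The default control set is every registry family whose reference
#' alignment covers at least 80% of the reference taxa.
#'
#' @param matrix An `npc_inventory`.
#' @param control_families Character vector of control families (nonempty).
#' @return The inventory with `completeness` filled (fractions in `[0, 1]`).
#' @export
completeness_proxy <- function(matrix, control_families) {
  if (length(control_families) == 0L) {
    stop("control family set is empty")
  }
  counts <- copy_counts(matrix)
  ctrl <- intersect(control_families, rownames(counts))
  if (length(ctrl) == 0L) stop("no control family is in the registry")
  matrix$completeness <- colMeans(counts[ctrl, , drop = FALSE] > 0L)
  matrix
}

#' Default control families from reference alignments
#'
#' @param alignments Named list of reference [aa_alignment()]s.
#' @param roles Taxon -> role map.
#' @param min_ref_fraction Minimum fraction of reference taxa a family's
#'   alignment must cover (default 0.8).
#' @return Character vector of family names.
#' @export
control_families <- function(alignments, roles, min_ref_fraction = 0.8) {
  ref_taxa <- names(roles)[roles != "query_host_lineage"]
  keep <- vapply(alignments, function(aln) {
    cov <- length(intersect(unique(aln$taxa[aln$is_ref]), ref_taxa))
    cov >= min_ref_fraction * length(ref_taxa)
  }, TRUE)
  names(alignments)[keep]
}

#' Corroborate absences across related taxa
#'
#' An absence is corroborated when at least `min_taxa` taxa of the same role
#' group, each with completeness proxy at least `min_completeness`, all lack
#' the family. Consistent absences in multiple adequately sampled taxa are
#' evidence of genuine loss rather than missing data.
#'
#' @param matrix An `npc_inventory` with completeness filled.
#' @param min_taxa Minimum number of corroborating taxa (default 3).
#' @param min_completeness Completeness floor (default 0.5).
#' @return The inventory with `absences`: `data.frame` of `family`,
#'   `corroborated`, `n_absent_complete`.
#' @export
corroborate_absences <- function(matrix, min_taxa = 3L,
                                 min_completeness = 0.5) {
  if (all(is.na(matrix$completeness))) {
    stop("completeness proxies not computed; run completeness_proxy() first")
  }
  counts <- copy_counts(matrix)
  ok_taxa <- names(matrix$completeness)[
    !is.na(matrix$completeness) & matrix$completeness >= min_completeness]
  rows <- lapply(matrix$families, function(f) {
    absent <- colnames(counts)[counts[f, ] == 0L]
    n <- length(intersect(absent, ok_taxa))
    all_absent <- length(absent) == ncol(counts)
    data.frame(family = f, corroborated = n >= min_taxa,
               n_absent_complete = n, stringsAsFactors = FALSE)
  })
  matrix$absences <- do.call(rbind, rows)
  matrix
}

#' Subcomplex presence summary
#'
#' For each group, a subcomplex is present when at least one of its families
#' has at least one copy in at least one taxon. Two groups are summarised:
#' the host lineage (all retained copies) and the pseudo-nucleomorph group
#' (algal-related copies only), which shows what an endosymbiont-derived
#' pore could still be built from.
#'
#' @param matrix An `npc_inventory`.
#' @param registry Family registry.
#' @return `data.frame`: `group`, `subcomplex`, `present`.
#' @export
subcomplex_summary <- function(matrix, registry) {
  found <- matrix$cells[matrix$cells$copy_index > 0L, , drop = FALSE]
  sub_of <- stats::setNames(registry$subcomplex, registry$family)
  groups <- list(
    host_lineage = found,
    nucleomorph_derived = found[!is.na(found$affinity) &
                                  found$affinity == "algal_related", ,
                                drop = FALSE])
  rows <- lapply(names(groups), function(g) {
    present_subs <- unique(unname(sub_of[groups[[g]]$family]))
    data.frame(group = g, subcomplex = SUBCOMPLEX_LEVELS,
               present = SUBCOMPLEX_LEVELS %in% present_subs,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Inventory as a long-form table
#'
#' @param matrix An `npc_inventory`.
#' @return The `cells` `data.frame` with per-taxon completeness appended as
#'   an attribute-free `completeness` column.
#' @export
inventory_table <- function(matrix) {
  out <- matrix$cells
  out$completeness <- unname(matrix$completeness[out$taxon])
  out
}
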