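## synthetic_data: ground-truth scenarios for the whole pipeline — a fixed
## host/outgroup/algal species tree, per-family sequence evolution under a
## background-frequency jump model, endosymbiotic gene transfer with
## signal-peptide gain, losses, duplications, decoy paralog families, and
## N-terminal truncation — all emitted with a truth table.

#' Default species tree of the synthetic scenarios
#'
#' Twenty taxa: a query host lineage (Q1-Q6) with its nonphotosynthetic
#' outgroup (H1-H4) on one side of the root, and the algal donor lineage
#' (A1-A6) with distant other-reference taxa (O1-O4) on the other. Branch
#' lengths give roughly 70% within-host and 50% cross-clade sequence
#' identity at the default substitution rate.
#'
#' @return Rooted [ape::phylo] with 20 tips.
#' @export
default_species_tree <- function() {
  txt <- paste0(
    "(((((((Q1:0.08,Q2:0.08):0.04,Q3:0.10):0.04,Q4:0.12):0.04,",
    "Q5:0.14):0.04,Q6:0.16):0.15,",
    "(((H1:0.10,H2:0.10):0.05,H3:0.13):0.05,H4:0.15):0.15):0.25,",
    "((((((A1:0.08,A2:0.08):0.04,A3:0.10):0.04,A4:0.12):0.04,",
    "A5:0.14):0.04,A6:0.16):0.20,",
    "(((O1:0.12,O2:0.12):0.06,O3:0.15):0.06,O4:0.18):0.25):0.25);")
  ape::read.tree(text = txt)
}

#' Default taxon roles of the synthetic scenarios
#' @return Named character vector taxon -> role.
#' @export
default_scenario_roles <- function() {
  taxon_roles(c(
    stats::setNames(rep("query_host_lineage", 6), paste0("Q", 1:6)),
    stats::setNames(rep("host_outgroup", 4), paste0("H", 1:4)),
    stats::setNames(rep("endosymbiont_algal", 6), paste0("A", 1:6)),
    stats::setNames(rep("other_reference", 4), paste0("O", 1:4))))
}

## Families used by the default scenario, spanning all six subcomplexes.
DEFAULT_SCENARIO_FAMILIES <- c("Nup214", "Rae1", "Nup107", "Sec13",
                               "Nup93", "Nup155", "Ndc1", "Pom152",
                               "Nup62", "Nup98", "Tpr", "Nup50")

#' Scenario configuration
#'
#' Collects every knob of the generator with validated defaults. The
#' defaults describe the clean headline scenario: 12 families over 20 taxa,
#' two of them transferred from the algal endosymbiont into every query
#' taxon with a signal-peptide prefix, and no losses, duplications, decoys,
#' or truncation unless requested.
#'
#' @param seed Integer seed (mandatory).
#' @param families Family names.
#' @param egt_families Families transferred from the endosymbiont into the
#'   query taxa (subset of `families`).
#' @param sp_on_egt Prepend a signal-peptide prefix to transferred copies.
#' @param length_range Family length range, residues.
#' @param rate Substitution rate per site per unit branch length.
#' @param gamma_shape Optional gamma shape for across-site rate variation.
#' @param egt_donor Algal taxon donating the transferred copies.
#' @param egt_divergence Extra branch length on each transferred copy.
#' @param loss_rate Per-(family, query taxon) probability of losing the
#'   host copy.
#' @param loss_events Explicit list of `c(family, taxon)` losses.
#' @param duplication_rate Per-(family, query taxon) probability of an
#'   extra within-taxon host copy.
#' @param dup_divergence Branch length of duplicated copies.
#' @param decoy_families Families that get a paralogous decoy family
#'   (named `<family>_paralog`) grafted as a high-divergence sister.
#' @param decoy_divergence Stem branch length of decoy families.
#' @param truncation_fraction Fraction of query-taxon transcripts with an
#'   N-terminal truncation (uniform 10-50% of the length removed,
#'   `nterm=incomplete` metadata set).
#' @param tree Species tree (rooted, with branch lengths).
#' @param roles Taxon -> role map matching the tree's tips.
#' @return A validated `scenario_config` list.
#' @export
scenario_config <- function(seed,
                            families = DEFAULT_SCENARIO_FAMILIES,
                            egt_families = c("Nup98", "Rae1"),
                            sp_on_egt = TRUE,
                            length_range = c(200L, 600L),
                            rate = 0.6,
                            gamma_shape = NULL,
                            egt_donor = "A1",
                            egt_divergence = 0.1,
                            loss_rate = 0,
                            loss_events = NULL,
                            duplication_rate = 0,
                            dup_divergence = 0.05,
                            decoy_families = character(0),
                            decoy_divergence = 0.4,
                            truncation_fraction = 0,
                            tree = default_species_tree(),
                            roles = default_scenario_roles()) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (!all(egt_families %in% families)) {
    stop("egt_families must be a subset of families")
  }
  if (!all(decoy_families %in% families)) {
    stop("decoy_families must be a subset of families")
  }
  stopifnot(rate >= 0, egt_divergence >= 0, loss_rate >= 0,
            duplication_rate >= 0, decoy_divergence >= 0,
            truncation_fraction >= 0, truncation_fraction <= 1,
            length_range[1] >= 1, length_range[2] >= length_range[1])
  missing_taxa <- setdiff(tree$tip.label, names(roles))
  if (length(missing_taxa) > 0L) {
    stop("tree tips without a role: ", paste(missing_taxa, collapse = ", "))
  }
  if (!(egt_donor %in% tree$tip.label) ||
      roles[[egt_donor]] != "endosymbiont_algal") {
    stop("egt_donor must be an endosymbiont_algal tip of the tree")
  }
  if (!is.null(loss_events)) {
    for (ev in loss_events) {
      if (!(ev[1] %in% families) || !(ev[2] %in% names(roles))) {
        stop("loss event references unknown family or taxon: ",
             paste(ev, collapse = "/"))
      }
    }
  }
  structure(list(seed = as.integer(seed), families = families,
                 egt_families = egt_families, sp_on_egt = sp_on_egt,
                 length_range = as.integer(length_range), rate = rate,
                 gamma_shape = gamma_shape, egt_donor = egt_donor,
                 egt_divergence = egt_divergence, loss_rate = loss_rate,
                 loss_events = loss_events,
                 duplication_rate = duplication_rate,
                 dup_divergence = dup_divergence,
                 decoy_families = decoy_families,
                 decoy_divergence = decoy_divergence,
                 truncation_fraction = truncation_fraction,
                 tree = tree, roles = roles),
            class = "scenario_config")
}

## Evolve a sequence along one branch: each site substitutes with
## probability 1 - exp(-rate * t * site_rate); the replacement is drawn from
## the background excluding the current residue. Site 1 is the invariant
## initiator methionine.
evolve_branch <- function(chars, t, rate, site_rates, invariant_first,
                          avoid_sp = TRUE) {
  L <- length(chars)
  p_sub <- 1 - exp(-rate * t * site_rates)
  ## vertical copies are signal-peptide-free by definition (the truth table
  ## says so), so lineages evolve under purifying selection against
  ## acquiring the generator's SP pattern: branch outcomes whose N-terminus
  ## would read as a signal peptide are redrawn
  for (attempt in 1:50) {
    out <- chars
    hit <- runif(L) < p_sub
    if (invariant_first) hit[1L] <- FALSE
    for (i in which(hit)) {
      w <- .aa_background
      w[out[i]] <- 0
      out[i] <- sample(AA20, 1L, prob = w)
    }
    if (!avoid_sp || L < 25L) break
    sp <- predict_signal_peptide(paste(out[seq_len(min(40L, L))],
                                       collapse = ""))
    if (!isTRUE(sp$sp)) break
  }
  out
}

#' Evolve a protein family along a species tree
#'
#' The root sequence is drawn i.i.d. from the residue background (with an
#' invariant initiator methionine at site 1); along each branch of length t
#' a site substitutes with probability `1 - exp(-rate * t)` (times an
#' optional gamma site-rate multiplier), the replacement drawn from the
#' background excluding the current residue. Reproducible given the seed.
#'
#' @param tree Rooted [ape::phylo] with branch lengths.
#' @param root_length Sequence length at the root (at least 1).
#' @param rate Substitution rate.
#' @param seed Integer seed.
#' @param gamma_shape Optional gamma shape for site-rate variation.
#' @return List: `tips` (named character vector of tip sequences), `root`
#'   (root sequence), `site_rates`.
#' @export
evolve_family <- function(tree, root_length, rate, seed, gamma_shape = NULL) {
  if (root_length < 1L) stop("root sequence length must be at least 1")
  withr::with_seed(seed, {
    evolve_family_impl(tree, root_length, rate, gamma_shape)
  })
}

## RNG-stream version used inside generate_scenario (already seeded).
evolve_family_impl <- function(tree, root_length, rate, gamma_shape = NULL,
                               root_chars = NULL, site_rates = NULL) {
  if (is.null(root_chars)) {
    ## the truth table marks vertical copies as signal-peptide-free, so the
    ## emitted roots must not match the generator's own SP pattern model:
    ## resample N-termini that would read as signal peptides
    for (attempt in 1:100) {
      root_chars <- sample(AA20, root_length, replace = TRUE,
                           prob = .aa_background)
      root_chars[1L] <- "M"
      sp <- predict_signal_peptide(paste(root_chars, collapse = ""))
      if (!isTRUE(sp$sp)) break
    }
  }
  L <- length(root_chars)
  if (is.null(site_rates)) {
    site_rates <- if (is.null(gamma_shape)) rep(1, L)
                  else rgamma(L, shape = gamma_shape, rate = gamma_shape)
  }
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- root_chars
  ## preorder edge walk: ape edge rows are parent-before-child in cladewise
  ## order for read.tree output
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1]; ch <- edges[e, 2]
    seqs[[ch]] <- evolve_branch(seqs[[p]], lens[e], rate, site_rates,
                                invariant_first = TRUE)
  }
  tips <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                 "")
  names(tips) <- tree$tip.label
  list(tips = tips, root = paste(root_chars, collapse = ""),
       site_rates = site_rates)
}

## Signal-peptide prefix: Met, two basic residues, 8-10 hydrophobics, then
## the A-X-A cleavage motif. Co-designed with predict_signal_peptide().
sp_prefix <- function() {
  h <- sample(8:10, 1L)
  paste(c("M", sample(c("K", "R"), 2L, replace = TRUE),
          sample(c("L", "V", "A", "F", "I"), h, replace = TRUE),
          "A", sample(AA20, 1L, prob = .aa_background), "A"),
        collapse = "")
}

## Truncate 10-50% of the N-terminus.
truncate_nterm <- function(seq) {
  cut <- floor(nchar(seq) * runif(1, 0.1, 0.5))
  substr(seq, cut + 1L, nchar(seq))
}

#' Apply evolutionary events to evolved family sequences
#'
#' Starting from vertical descent (every taxon owns its tip copy of every
#' family), applies endosymbiotic gene transfer (the donor's copy enters
#' each query proteome, optionally with a signal-peptide prefix), losses,
#' within-taxon duplications, and N-terminal truncation with
#' `nterm=incomplete` metadata. Returns the final proteomes and the truth
#' table.
#'
#' @param family_seqs Named list family -> output of [evolve_family()].
#' @param config A `scenario_config`.
#' @return List: `proteomes` (named list taxon -> protein record
#'   `data.frame`), `truth` (`data.frame`: `protein`, `taxon`, `family`,
#'   `provenance`, `has_sp`, `is_decoy_paralog`, `truncated`).
#' @note Called inside an already-seeded RNG stream by
#'   [generate_scenario()]; seed it yourself for standalone use.
#' @export
apply_events <- function(family_seqs, config) {
  roles <- config$roles
  taxa <- names(roles)
  query_taxa <- taxa[roles == "query_host_lineage"]
  rec <- list()
  add <- function(id, taxon, family, sequence, provenance, has_sp = FALSE,
                  is_decoy = FALSE, nterm = "unknown") {
    rec[[length(rec) + 1L]] <<- list(id = id, taxon = taxon, family = family,
                                     sequence = sequence,
                                     provenance = provenance,
                                     has_sp = has_sp, is_decoy = is_decoy,
                                     nterm = nterm)
  }
  algal_taxa <- taxa[roles == "endosymbiont_algal"]
  for (fam in names(family_seqs)) {
    tips <- family_seqs[[fam]]$tips
    site_rates <- family_seqs[[fam]]$site_rates
    is_decoy_fam <- grepl("_paralog$", fam)
    base_fam <- sub("_paralog$", "", fam)
    for (tx in taxa) {
      lost <- FALSE
      if (tx %in% query_taxa && !is_decoy_fam) {
        if (config$loss_rate > 0 && runif(1) < config$loss_rate) lost <- TRUE
        for (ev in config$loss_events) {
          if (ev[1] == fam && ev[2] == tx) lost <- TRUE
        }
      }
      if (!lost) {
        add(paste(tx, fam, sep = "_"), tx, fam, tips[[tx]],
            provenance = if (tx %in% algal_taxa) "algal" else "host",
            is_decoy = is_decoy_fam && tx %in% query_taxa)
      }
      ## within-taxon duplication of the host copy
      if (!lost && tx %in% query_taxa && !is_decoy_fam &&
          config$duplication_rate > 0 &&
          runif(1) < config$duplication_rate) {
        dup <- paste(evolve_branch(strsplit(tips[[tx]], "")[[1]],
                                   config$dup_divergence, config$rate,
                                   site_rates, TRUE), collapse = "")
        add(paste(tx, fam, "dup", sep = "_"), tx, fam, dup,
            provenance = "host")
      }
    }
    ## endosymbiotic gene transfer: one event on the query stem (the donor
    ## copy diverges by egt_divergence), then vertical descent along the
    ## query subtree of the species tree
    if (fam %in% config$egt_families) {
      donor_chars <- strsplit(tips[[config$egt_donor]], "")[[1]]
      stem <- evolve_branch(donor_chars, config$egt_divergence, config$rate,
                            site_rates, TRUE)
      qtree <- ape::keep.tip(config$tree, query_taxa)
      egt_tips <- evolve_family_impl(qtree, length(stem), config$rate,
                                     root_chars = stem,
                                     site_rates = site_rates)$tips
      for (tx in query_taxa) {
        egt <- egt_tips[[tx]]
        has_sp <- isTRUE(config$sp_on_egt)
        if (has_sp) egt <- paste0(sp_prefix(), egt)
        add(paste(tx, fam, "nm", sep = "_"), tx, fam, egt,
            provenance = "algal", has_sp = has_sp)
      }
    }
  }
  ## N-terminal truncation of query-taxon transcripts
  if (config$truncation_fraction > 0) {
    for (i in seq_along(rec)) {
      if (rec[[i]]$taxon %in% query_taxa &&
          runif(1) < config$truncation_fraction) {
        rec[[i]]$sequence <- truncate_nterm(rec[[i]]$sequence)
        rec[[i]]$nterm <- "incomplete"
        rec[[i]]$has_sp <- FALSE
        rec[[i]]$truncated <- TRUE
      }
    }
  }
  truth <- data.frame(
    protein = vapply(rec, `[[`, "", "id"),
    taxon = vapply(rec, `[[`, "", "taxon"),
    family = vapply(rec, `[[`, "", "family"),
    provenance = vapply(rec, `[[`, "", "provenance"),
    has_sp = vapply(rec, `[[`, TRUE, "has_sp"),
    is_decoy_paralog = vapply(rec, `[[`, TRUE, "is_decoy"),
    truncated = vapply(rec, function(r) isTRUE(r$truncated), TRUE),
    stringsAsFactors = FALSE)
  proteomes <- lapply(stats::setNames(taxa, taxa), function(tx) {
    sel <- which(truth$taxon == tx)
    protein_records(
      id = truth$protein[sel], taxon = tx,
      sequence = vapply(rec[sel], `[[`, "", "sequence"),
      nterm = vapply(rec[sel], `[[`, "", "nterm"))
  })
  list(proteomes = proteomes, truth = truth)
}

#' Generate a complete ground-truth scenario bundle
#'
#' Evolves every family (plus any decoy paralog families) along the species
#' tree, applies the configured events, and assembles reference alignments
#' (reference-role taxa rows; the generator knows site homology, so
#' reference alignments are exact and ungapped), the taxon-role table, the
#' scenario registry, and the truth table. With `out_dir` the bundle is
#' written to disk in the layout the pipeline consumes; identical configs
#' give byte-identical bundles.
#'
#' @param config A `scenario_config`.
#' @param out_dir Optional output directory.
#' @return List: `proteomes`, `alignments`, `roles`, `registry`, `truth`,
#'   `config`.
#' @export
generate_scenario <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  bundle <- withr::with_seed(config$seed, {
    all_fams <- config$families
    family_seqs <- list()
    for (fam in all_fams) {
      L <- sample(seq(config$length_range[1], config$length_range[2]), 1L)
      family_seqs[[fam]] <- evolve_family_impl(config$tree, L, config$rate,
                                               config$gamma_shape)
      if (fam %in% config$decoy_families) {
        ## decoy paralog family: high-divergence sister evolved from the
        ## same root, then down the same species tree
        root_chars <- strsplit(family_seqs[[fam]]$root, "")[[1]]
        decoy_root <- evolve_branch(root_chars, config$decoy_divergence,
                                    config$rate,
                                    family_seqs[[fam]]$site_rates, TRUE)
        family_seqs[[paste0(fam, "_paralog")]] <-
          evolve_family_impl(config$tree, length(decoy_root), config$rate,
                             config$gamma_shape, root_chars = decoy_root)
      }
    }
    ev <- apply_events(family_seqs, config)
    ref_taxa <- names(config$roles)[config$roles != "query_host_lineage"]
    alignments <- lapply(stats::setNames(names(family_seqs),
                                         names(family_seqs)), function(fam) {
      tips <- family_seqs[[fam]]$tips[ref_taxa]
      aa_alignment(fam, stats::setNames(unname(tips),
                                        paste(ref_taxa, fam, sep = "_")),
                   taxa = ref_taxa)
    })
    base_reg <- default_registry()
    sub_of <- stats::setNames(base_reg$subcomplex, base_reg$family)
    fam_names <- names(family_seqs)
    base_names <- sub("_paralog$", "", fam_names)
    registry <- family_registry(data.frame(
      family = fam_names,
      display = fam_names,
      subcomplex = ifelse(base_names %in% names(sub_of),
                          unname(sub_of[base_names]), "outer ring"),
      notes = ifelse(grepl("_paralog$", fam_names),
                     "synthetic paralog decoy family", ""),
      stringsAsFactors = FALSE))
    list(proteomes = ev$proteomes, alignments = alignments,
         roles = config$roles, registry = registry, truth = ev$truth,
         config = config)
  })
  if (!is.null(out_dir)) write_scenario_bundle(bundle, out_dir)
  bundle
}

#' Write a scenario bundle to disk
#'
#' Layout: `proteomes/<taxon>.fasta`, `alignments/<family>.fasta`,
#' `roles.tsv`, `registry.tsv`, `truth.tsv`.
#'
#' @param bundle Output of [generate_scenario()].
#' @param out_dir Output directory (created if needed).
#' @export
write_scenario_bundle <- function(bundle, out_dir) {
  dir.create(file.path(out_dir, "proteomes"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "alignments"), showWarnings = FALSE)
  for (tx in names(bundle$proteomes)) {
    write_fasta(bundle$proteomes[[tx]],
                file.path(out_dir, "proteomes", paste0(tx, ".fasta")))
  }
  for (fam in names(bundle$alignments)) {
    write_alignment(bundle$alignments[[fam]],
                    file.path(out_dir, "alignments", paste0(fam, ".fasta")))
  }
  write_taxon_roles(bundle$roles, file.path(out_dir, "roles.tsv"))
  write_registry(bundle$registry, file.path(out_dir, "registry.tsv"))
  utils::write.table(bundle$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
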