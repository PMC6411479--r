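## pipeline: orchestrate simulate -> profiles -> search -> purge/classify ->
## targeting -> inventory, with provenance-stamped outputs and end-to-end
## determinism from a single seed (fanned out to per-stage seeds through a
## stage-name hash, so toggling one stage never perturbs another).

#' Pipeline run configuration
#'
#' @param seed Integer master seed.
#' @param input_dir Scenario bundle directory (see
#'   [write_scenario_bundle()]); alternatively pass `bundle`.
#' @param bundle In-memory bundle from [generate_scenario()].
#' @param out_dir Optional output directory for the result tables.
#' @param evalue_threshold Hit retention threshold (default `1e-5`).
#' @param top_n Per-family best-hit cap (default 200).
#' @param per_taxon_cap Apply `top_n` per taxon instead of pooled.
#' @param support_threshold Bootstrap support that provenance calls and
#'   paralog removals must strictly exceed (default 70).
#' @param purity Sister-composition purity for host/algal calls.
#' @param max_cycles Paralog-purge cycle cap (default 3).
#' @param n_boot Bootstrap replicates per tree (default 100).
#' @param margin_min Assignment margin for ortholog acceptance rule (b).
#' @param n_decoys Calibration decoys per profile.
#' @param occupancy_threshold Profile match-column rule.
#' @param external_trees Optional directory of per-family Newick trees that
#'   replace internal tree building (files `<family>.nwk`).
#' @param external_sp Optional TSV of signal-peptide predictions (see
#'   [import_sp_predictions()]).
#' @param external_completeness Optional named completeness values replacing
#'   the control-family proxy.
#' @return A validated `run_config` list.
#' @export
run_config <- function(seed, input_dir = NULL, bundle = NULL, out_dir = NULL,
                       evalue_threshold = 1e-5, top_n = 200L,
                       per_taxon_cap = FALSE, support_threshold = 70L,
                       purity = 0.8, max_cycles = 3L, n_boot = 100L,
                       margin_min = 2.0, n_decoys = 200L,
                       occupancy_threshold = 0.5, external_trees = NULL,
                       external_sp = NULL, external_completeness = NULL) {
  stopifnot(evalue_threshold > 0, top_n >= 1, support_threshold >= 0,
            support_threshold <= 100, purity > 0, purity <= 1,
            max_cycles >= 1, n_boot >= 1, n_decoys >= 50,
            occupancy_threshold > 0, occupancy_threshold <= 1)
  if (is.null(input_dir) && is.null(bundle)) {
    stop("provide input_dir or an in-memory bundle")
  }
  structure(list(seed = as.integer(seed), input_dir = input_dir,
                 bundle = bundle, out_dir = out_dir,
                 evalue_threshold = evalue_threshold,
                 top_n = as.integer(top_n), per_taxon_cap = per_taxon_cap,
                 support_threshold = as.integer(support_threshold),
                 purity = purity, max_cycles = as.integer(max_cycles),
                 n_boot = as.integer(n_boot), margin_min = margin_min,
                 n_decoys = as.integer(n_decoys),
                 occupancy_threshold = occupancy_threshold,
                 external_trees = external_trees, external_sp = external_sp,
                 external_completeness = external_completeness),
            class = "run_config")
}

#' Load a scenario bundle from disk
#'
#' @param dir Bundle directory written by [write_scenario_bundle()].
#' @return List with `proteomes`, `alignments`, `roles`, `registry`, and
#'   `truth` when present.
#' @export
read_scenario_bundle <- function(dir) {
  roles <- read_taxon_roles(file.path(dir, "roles.tsv"))
  registry <- read_registry(file.path(dir, "registry.tsv"))
  pfiles <- list.files(file.path(dir, "proteomes"), full.names = TRUE)
  proteomes <- lapply(pfiles, read_fasta)
  names(proteomes) <- vapply(proteomes, function(p) p$taxon[1], "")
  afiles <- list.files(file.path(dir, "alignments"), full.names = TRUE)
  alignments <- lapply(afiles, function(f) {
    read_alignment(f, sub("\\.[^.]*$", "", basename(f)))
  })
  names(alignments) <- vapply(alignments, function(a) a$family, "")
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    utils::read.delim(truth_path, stringsAsFactors = FALSE)
  } else NULL
  list(proteomes = proteomes, alignments = alignments, roles = roles,
       registry = registry, truth = truth)
}

## Provenance-stamped TSV writer with stable numeric formatting so
## identical runs are byte-identical.
write_stamped_tsv <- function(df, path, stamp) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  for (j in which(num)) {
    v <- sprintf("%.6g", df[[j]])
    v[is.na(df[[j]])] <- "NA"
    df[[j]] <- v
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stamp, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full screening pipeline
#'
#' Stages, in order: load inputs, build and calibrate one profile per
#' reference alignment, screen the query-role proteomes, triage hits,
#' assign each hit protein its best family, purge paralogs per family over
#' iterative tree-cleaning cycles, accept orthologs, classify provenance on
#' the final midpoint-rooted trees, collect targeting evidence, and
#' assemble the inventory matrix with completeness proxies, corroborated
#' absences, and the subcomplex summary. Re-running with an identical
#' configuration reproduces identical outputs.
#'
#' @param config A [run_config()].
#' @return List: `hits`, `annotations`, `calls` (all query leaves, with
#'   `retained` flag), `evidence`, `inventory`, `subcomplex`,
#'   `purge_reports`, `trees`, `profiles`, `roles`, `registry`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  bundle <- if (!is.null(config$bundle)) config$bundle
            else read_scenario_bundle(config$input_dir)
  roles <- bundle$roles
  registry <- bundle$registry
  alignments <- bundle$alignments
  seed <- config$seed
  query_taxa <- names(roles)[roles == "query_host_lineage"]
  query_prot <- do.call(rbind, bundle$proteomes[
    names(bundle$proteomes) %in% query_taxa])
  target_lens <- nchar(query_prot$sequence)
  decoy_len <- max(1L, as.integer(stats::median(target_lens)))

  ## stage: profiles
  profiles <- lapply(alignments, function(aln) {
    p <- build_profile(aln, occupancy_threshold = config$occupancy_threshold)
    calibrate(p, n_decoys = config$n_decoys, decoy_length = decoy_len,
              seed = stage_seed(seed, paste0("calibrate:", aln$family)))
  })

  ## stage: search + triage + assignment
  hits <- search_proteomes(profiles, query_prot,
                           e_threshold = config$evalue_threshold)
  hits <- triage_top_n(hits, top_n = config$top_n,
                       per_taxon = config$per_taxon_cap)
  hit_prot <- query_prot[query_prot$id %in% unique(hits$protein), ,
                         drop = FALSE]
  annotations <- assign_families(hit_prot, profiles,
                                 prefilter = min(2L, length(profiles)))

  ## stage: per-family purge, acceptance, classification
  calls <- list()
  purge_reports <- list()
  trees <- list()
  evidence <- list()
  for (fam in names(alignments)) {
    fam_hits <- hits[hits$family == fam, , drop = FALSE]
    recs <- query_prot[match(fam_hits$protein, query_prot$id), , drop = FALSE]
    if (nrow(recs) > 0L) {
      ann_idx <- match(recs$id, annotations$protein)
      recs$assigned_family <- annotations$assigned_family[ann_idx]
      recs$margin <- annotations$margin[ann_idx]
    } else {
      recs$assigned_family <- character(0)
      recs$margin <- numeric(0)
    }
    external_tree_file <- if (!is.null(config$external_trees)) {
      f <- file.path(config$external_trees, paste0(fam, ".nwk"))
      if (file.exists(f)) f else NULL
    } else NULL
    if (!is.null(external_tree_file)) {
      aug <- augment_family_alignment(alignments[[fam]], profiles[[fam]],
                                      recs)
      tree <- midpoint_root(read_newick(external_tree_file, is_file = TRUE))
      survivors <- recs$id
      purge_reports[[fam]] <- list(family = fam, cycles = list(),
                                   cycles_run = 0L, converged = TRUE,
                                   external_tree = TRUE)
    } else {
      purged <- purge_paralogs(alignments[[fam]], profiles[[fam]], recs,
                               roles, max_cycles = config$max_cycles,
                               support_threshold = config$support_threshold,
                               n_boot = config$n_boot,
                               seed = stage_seed(seed, paste0("purge:", fam)))
      aug <- purged$alignment
      survivors <- purged$survivors
      purge_reports[[fam]] <- purged$report
      tree <- purged$tree
      if (is.null(tree)) {
        tree <- midpoint_root(bootstrap_supports(
          aug, n_reps = config$n_boot,
          seed = stage_seed(seed, paste0("tree:", fam))))
      }
      recs <- recs[recs$id %in% survivors, , drop = FALSE]
    }
    trees[[fam]] <- tree
    if (nrow(recs) == 0L) next
    leaf_taxa <- stats::setNames(
      c(alignments[[fam]]$taxa, recs$taxon),
      c(names(alignments[[fam]]$seqs), recs$id))
    retained <- accept_orthologs(tree, roles, leaf_taxa,
                                 data.frame(protein = recs$id,
                                            assigned_family = recs$assigned_family,
                                            margin = recs$margin,
                                            stringsAsFactors = FALSE),
                                 fam, margin_min = config$margin_min)
    fam_calls <- classify_affinity(tree, roles, leaf_taxa, family = fam,
                                   support_threshold = config$support_threshold,
                                   purity = config$purity)
    fam_calls$retained <- fam_calls$protein %in% retained
    calls[[fam]] <- fam_calls
    kept <- recs[recs$id %in% retained, , drop = FALSE]
    if (nrow(kept) > 0L) {
      evidence[[fam]] <- targeting_evidence(kept, aug)
    }
  }
  calls <- if (length(calls) > 0L) do.call(rbind, c(calls, list(make.row.names = FALSE)))
           else data.frame(protein = character(0), taxon = character(0),
                           family = character(0), label = character(0),
                           support = integer(0), sister_host = integer(0),
                           sister_algal = integer(0), sister_other = integer(0),
                           retained = logical(0), stringsAsFactors = FALSE)
  evidence <- if (length(evidence) > 0L) {
    do.call(rbind, c(evidence, list(make.row.names = FALSE)))
  } else data.frame(protein = character(0), sp_predicted = logical(0),
                    sp_score = numeric(0), sp_cleavage = integer(0),
                    sp_basis = character(0), nterm_complete = logical(0),
                    nterm_basis = character(0), fg_count = integer(0),
                    fg_density = numeric(0), fg_flag = logical(0),
                    stringsAsFactors = FALSE)
  if (!is.null(config$external_sp) && nrow(evidence) > 0L) {
    evidence <- import_sp_predictions(evidence, config$external_sp)
  }

  ## stage: inventory
  retained_calls <- calls[calls$retained, , drop = FALSE]
  inventory <- build_matrix(retained_calls, evidence, registry, roles)
  if (!is.null(config$external_completeness)) {
    inventory$completeness[names(config$external_completeness)] <-
      config$external_completeness
  } else {
    ctrl <- control_families(alignments, roles)
    inventory <- completeness_proxy(inventory, ctrl)
  }
  inventory <- corroborate_absences(inventory)
  subcomplex <- subcomplex_summary(inventory, registry)

  result <- list(hits = hits, annotations = annotations, calls = calls,
                 evidence = evidence, inventory = inventory,
                 subcomplex = subcomplex, purge_reports = purge_reports,
                 trees = trees, profiles = profiles, roles = roles,
                 registry = registry)
  if (!is.null(config$out_dir)) write_run_outputs(result, config)
  result
}

## Write the result tables with a provenance stamp.
write_run_outputs <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- fnv1a(paste(
    config$seed, config$evalue_threshold, config$top_n,
    config$support_threshold, config$purity, config$max_cycles,
    config$n_boot, config$margin_min, config$n_decoys,
    config$occupancy_threshold, collapse = ":"))
  stamp <- sprintf("# egtscreen %s | seed=%d | config=%d",
                   as.character(utils::packageVersion("egtscreen")),
                   config$seed, cfg_hash)
  out <- function(name) file.path(config$out_dir, name)
  write_stamped_tsv(result$hits, out("hits.tsv"), stamp)
  write_stamped_tsv(result$calls, out("calls.tsv"), stamp)
  write_stamped_tsv(result$evidence, out("evidence.tsv"), stamp)
  write_stamped_tsv(inventory_table(result$inventory), out("inventory.tsv"),
                    stamp)
  write_stamped_tsv(result$subcomplex, out("subcomplex_summary.tsv"), stamp)
  if (!is.null(result$inventory$absences)) {
    write_stamped_tsv(result$inventory$absences, out("absences.tsv"), stamp)
  }
  jsonlite::write_json(result$purge_reports,
                       out("purge_reports.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  for (fam in names(result$trees)) {
    write_newick(result$trees[[fam]],
                 out(paste0("tree_", fam, ".nwk")))
  }
  invisible(config$out_dir)
}

#' Read a run configuration from YAML or JSON
#'
#' Accepts a file holding any subset of [run_config()]'s arguments (by the
#' same names); unlisted arguments keep their defaults. The format is
#' chosen by extension: `.yaml`/`.yml` or `.json`.
#'
#' @param path Config file path.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  vals <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be a .yaml/.yml or .json file")
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals)
}
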