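# Handcrafted role maps: Q* = query host lineage, H* = host outgroup,
# A* = endosymbiont algal, O* = other reference (default scenario roles).

test_that("affinity follows the sister clade when support clears 70", {
  roles <- default_scenario_roles()
  leaf_taxa <- c(q1 = "Q1", q2 = "Q2", a1 = "A1", a2 = "A2",
                 h1 = "H1", h2 = "H2")
  algal_sister <- paste0("(((q1:1,q2:1)99:1,(a1:1,a2:1)98:1)85:1,",
                         "(h1:1,h2:1)97:2);")
  calls <- classify_affinity(read_newick(algal_sister), roles, leaf_taxa,
                             family = "Nup98")
  expect_equal(calls$label, rep("algal_related", 2))
  expect_equal(calls$support, rep(85L, 2))
  expect_equal(calls$sister_algal, rep(2L, 2))
  ## identical topology at support 60: strictly-over-70 rule demotes
  weak <- sub("\\)85:", ")60:", algal_sister)
  calls60 <- classify_affinity(read_newick(weak), roles, leaf_taxa,
                               family = "Nup98")
  expect_equal(calls60$label, rep("ambiguous", 2))
  ## support exactly 70 is not enough; 71 is
  expect_equal(classify_affinity(read_newick(sub("\\)85:", ")70:",
                                                 algal_sister)),
                                 roles, leaf_taxa)$label[1], "ambiguous")
  expect_equal(classify_affinity(read_newick(sub("\\)85:", ")71:",
                                                 algal_sister)),
                                 roles, leaf_taxa)$label[1], "algal_related")
  ## host sister instead
  host_sister <- paste0("(((q1:1,q2:1)99:1,(h1:1,h2:1)98:1)85:1,",
                        "(a1:1,a2:1)97:2);")
  expect_equal(classify_affinity(read_newick(host_sister), roles,
                                 leaf_taxa)$label, rep("host_related", 2))
})

test_that("mixed sisters below the purity threshold stay ambiguous", {
  roles <- default_scenario_roles()
  leaf_taxa <- c(q1 = "Q1", a1 = "A1", a2 = "A2", h1 = "H1", o1 = "O1")
  ## sister = 2 algal + 1 host: 2/3 < 0.8 purity
  mixed <- "((q1:1,((a1:1,a2:1)99:1,h1:1)95:1)90:1,o1:3);"
  calls <- classify_affinity(read_newick(mixed), roles, leaf_taxa)
  expect_equal(calls$label, "ambiguous")
  expect_equal(calls[, c("sister_algal", "sister_host")],
               data.frame(sister_algal = 2L, sister_host = 1L))
})

test_that("trees without reference leaves are unclassifiable", {
  roles <- default_scenario_roles()
  leaf_taxa <- c(q1 = "Q1", q2 = "Q2", q3 = "Q3")
  calls <- classify_affinity(read_newick("((q1:1,q2:1)90:1,q3:1);"),
                             roles, leaf_taxa)
  expect_equal(calls$label, rep("unclassifiable", 3))
  expect_error(classify_affinity(ape::unroot(ape::rtree(4)), roles,
                                 c(t1 = "Q1", t2 = "Q2", t3 = "Q3",
                                   t4 = "Q4")),
               "midpoint_root")
})

test_that("calls are deterministic under clade rotation of the input", {
  roles <- default_scenario_roles()
  leaf_taxa <- c(q1 = "Q1", q2 = "Q2", a1 = "A1", a2 = "A2",
                 h1 = "H1", h2 = "H2")
  t1 <- "(((q1:1,q2:1)99:1,(a1:1,a2:1)98:1)85:1,(h1:1,h2:1)97:2);"
  t2 <- "((h2:1,h1:1)97:2,((a2:1,a1:1)98:1,(q2:1,q1:1)99:1)85:1);"
  c1 <- classify_affinity(read_newick(t1), roles, leaf_taxa)
  c2 <- classify_affinity(read_newick(t2), roles, leaf_taxa)
  expect_equal(c1, c2)
})

test_that("ortholog acceptance honors the sister-or-assignment disjunction", {
  roles <- default_scenario_roles()
  leaf_taxa <- c(q1 = "Q1", a1 = "A1", h1 = "H1", h2 = "H2")
  tr <- read_newick("((q1:1,a1:1)90:1,(h1:1,h2:1)95:1);")
  ## (a) sister holds a reference leaf: retained despite a mismatched
  ## assignment
  ann_bad <- data.frame(protein = "q1", assigned_family = "Other",
                        margin = 10, stringsAsFactors = FALSE)
  expect_equal(accept_orthologs(tr, roles, leaf_taxa, ann_bad, "Nup98"),
               "q1")
  ## (b) isolated query leaf, matched assignment with a wide margin
  iso_taxa <- c(q1 = "Q1", q2 = "Q2", q3 = "Q3")
  iso <- read_newick("((q1:9,q2:1)90:1,q3:1);")
  ann_good <- data.frame(protein = c("q1", "q2", "q3"),
                         assigned_family = c("Nup98", "Other", "Other"),
                         margin = c(10, 10, 10), stringsAsFactors = FALSE)
  expect_equal(accept_orthologs(iso, roles, iso_taxa, ann_good, "Nup98"),
               "q1")
  ## neither rule: dropped
  ann_none <- data.frame(protein = c("q1", "q2", "q3"),
                         assigned_family = "Other", margin = 10,
                         stringsAsFactors = FALSE)
  expect_equal(length(accept_orthologs(iso, roles, iso_taxa, ann_none,
                                       "Nup98")), 0L)
  ## margin below margin_min fails rule (b)
  ann_thin <- data.frame(protein = "q1", assigned_family = "Nup98",
                         margin = 1, stringsAsFactors = FALSE)
  expect_equal(length(accept_orthologs(iso, roles, iso_taxa, ann_thin,
                                       "Nup98", margin_min = 2)), 0L)
})

test_that("planted decoy clades are purged within three cycles", {
  cfg <- mini_scenario_config(31, egt_families = character(0),
                              decoy_families = "Sec13")
  bundle <- cached("purge_bundle", generate_scenario(cfg))
  qp <- do.call(rbind, bundle$proteomes[paste0("Q", 1:6)])
  prof <- cached("purge_profile", calibrate(
    build_profile(bundle$alignments[["Sec13"]]), n_decoys = 200,
    decoy_length = 200, seed = 8))
  profiles <- list(Sec13 = prof,
                   Sec13_paralog = calibrate(
                     build_profile(bundle$alignments[["Sec13_paralog"]]),
                     n_decoys = 200, decoy_length = 200, seed = 9))
  hits <- search_proteomes(profiles["Sec13"], qp)
  recs <- qp[match(hits$protein, qp$id), ]
  ann <- assign_families(recs, profiles)
  recs$assigned_family <- ann$assigned_family
  recs$margin <- ann$margin
  decoy_ids <- bundle$truth$protein[bundle$truth$is_decoy_paralog]
  expect_gte(sum(recs$id %in% decoy_ids), 4)  # decoys really are hits
  out <- purge_paralogs(bundle$alignments[["Sec13"]], prof, recs,
                        bundle$roles, max_cycles = 3, seed = 41)
  expect_true(out$report$converged)
  expect_lte(out$report$cycles_run, 3L)
  removed <- unlist(lapply(out$report$cycles, function(cc) cc$protein))
  expect_true(all(intersect(recs$id, decoy_ids) %in% removed))
  expect_false(any(out$survivors %in% decoy_ids))
  ## no true ortholog lost
  expect_true(all(recs$id[!recs$id %in% decoy_ids] %in% out$survivors))
  ## removed sets are disjoint across cycles
  expect_equal(anyDuplicated(removed), 0L)
  ## idempotence: re-running the purge on the cleaned set removes nothing
  again <- purge_paralogs(bundle$alignments[["Sec13"]], prof,
                          recs[recs$id %in% out$survivors, ],
                          bundle$roles, max_cycles = 3, seed = 42)
  expect_true(again$report$converged)
  expect_equal(nrow(again$report$cycles[[1]]), 0L)
  ## the cycle cap is a hard stop: with max_cycles = 1 and removals in that
  ## cycle, the run reports non-convergence
  capped <- purge_paralogs(bundle$alignments[["Sec13"]], prof, recs,
                           bundle$roles, max_cycles = 1, seed = 41)
  expect_equal(capped$report$cycles_run, 1L)
  expect_false(capped$report$converged)
})

test_that("a clean family converges in one cycle with no removals", {
  bundle <- cached_mini_bundle()
  profiles <- cached_mini_profiles()
  qp <- do.call(rbind, bundle$proteomes[paste0("Q", 1:6)])
  hits <- search_proteomes(profiles["Tpr"], qp)
  recs <- qp[match(hits$protein, qp$id), ]
  recs$assigned_family <- "Tpr"
  recs$margin <- 10
  out <- purge_paralogs(bundle$alignments[["Tpr"]], profiles[["Tpr"]],
                        recs, bundle$roles, seed = 4)
  expect_true(out$report$converged)
  expect_equal(out$report$cycles_run, 1L)
  expect_equal(nrow(out$report$cycles[[1]]), 0L)
  expect_setequal(out$survivors, recs$id)
  expect_s3_class(out$tree, "phylo")
})

test_that("host and algal labels always carry support over the threshold", {
  run <- cached_default_run(1)
  calls <- run$result$calls
  labelled <- calls[calls$label %in% c("host_related", "algal_related"), ]
  expect_true(all(!is.na(labelled$support)))
  expect_true(all(labelled$support > 70))
})
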