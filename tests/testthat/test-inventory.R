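make_calls <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  df$support <- 99L
  df$sister_host <- 1L
  df$sister_algal <- 0L
  df$sister_other <- 0L
  df
}

toy_registry <- function() {
  family_registry(data.frame(
    family = c("Nup98", "Rae1", "Tpr"),
    subcomplex = c("central channel", "cytoplasmic complex",
                   "nuclear basket"),
    stringsAsFactors = FALSE))
}

toy_roles <- function() {
  taxon_roles(c(Q1 = "query_host_lineage", Q2 = "query_host_lineage",
                A1 = "endosymbiont_algal", H1 = "host_outgroup"))
}

toy_evidence <- function(proteins, sp = FALSE) {
  data.frame(protein = proteins, sp_predicted = sp, sp_score = 1,
             sp_cleavage = NA_integer_, sp_basis = "heuristic",
             nterm_complete = TRUE, nterm_basis = "metadata",
             fg_count = 0L, fg_density = 0, fg_flag = FALSE,
             stringsAsFactors = FALSE)
}

test_that("the matrix holds one cell per family-taxon with copy detail", {
  calls <- make_calls(protein = c("q1_n98", "q1_n98b", "q2_rae"),
                      taxon = c("Q1", "Q1", "Q2"),
                      family = c("Nup98", "Nup98", "Rae1"),
                      label = c("algal_related", "host_related",
                                "host_related"))
  ev <- toy_evidence(calls$protein, sp = c(TRUE, FALSE, FALSE))
  m <- build_matrix(calls, ev, toy_registry(), toy_roles())
  counts <- copy_counts(m)
  expect_equal(unname(counts["Nup98", ]), c(2L, 0L))
  expect_equal(unname(counts["Rae1", ]), c(0L, 1L))
  expect_equal(unname(counts["Tpr", ]), c(0L, 0L))  # zero-call family row
  two <- m$cells[m$cells$family == "Nup98" & m$cells$taxon == "Q1", ]
  expect_setequal(two$affinity, c("algal_related", "host_related"))
  expect_equal(sum(two$sp), 1L)
  ## conservation: total copies equal retained calls
  expect_equal(sum(counts), nrow(calls))
  ## unregistered family -> error
  bad <- make_calls(protein = "x", taxon = "Q1", family = "NupX",
                    label = "host_related")
  expect_error(build_matrix(bad, toy_evidence("x"), toy_registry(),
                            toy_roles()),
               "unregistered")
})

test_that("cell ordering is invariant to the order of the input calls", {
  calls <- make_calls(protein = c("a", "b", "c", "d"),
                      taxon = c("Q1", "Q2", "Q1", "Q2"),
                      family = c("Nup98", "Nup98", "Rae1", "Tpr"),
                      label = "host_related")
  ev <- toy_evidence(calls$protein)
  m1 <- build_matrix(calls, ev, toy_registry(), toy_roles())
  perm <- c(4, 2, 3, 1)
  m2 <- build_matrix(calls[perm, ], ev[perm, ], toy_registry(), toy_roles())
  expect_identical(m1$cells, m2$cells)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  egtscreen:::write_stamped_tsv(inventory_table(m1), f1, "# stamp")
  egtscreen:::write_stamped_tsv(inventory_table(m2), f2, "# stamp")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the completeness proxy is the control-family detection fraction", {
  calls <- make_calls(protein = c("a", "b", "c"),
                      taxon = c("Q1", "Q1", "Q1"),
                      family = c("Nup98", "Rae1", "Tpr"),
                      label = "host_related")
  ev <- toy_evidence(calls$protein)
  m <- build_matrix(calls, ev, toy_registry(), toy_roles())
  m <- completeness_proxy(m, c("Nup98", "Rae1", "Tpr"))
  expect_equal(unname(m$completeness), c(1, 0))  # all controls vs none
  expect_error(completeness_proxy(m, character(0)), "empty")
})

test_that("simulated transcript dropout shows up in the proxy", {
  cfg <- scenario_config(81, families = egtscreen:::DEFAULT_SCENARIO_FAMILIES[1:8],
                         egt_families = character(0),
                         length_range = c(150L, 250L), loss_rate = 0.2)
  b <- generate_scenario(cfg)
  res <- run_all(run_config(seed = 81, bundle = b))
  comp <- res$inventory$completeness
  ## mean detection should sit near 1 - loss_rate, within binomial noise
  ## (8 families x 6 taxa draws)
  expect_gt(mean(comp), 0.8 - 3 * sqrt(0.8 * 0.2 / 48))
  expect_lt(mean(comp), 0.8 + 3 * sqrt(0.8 * 0.2 / 48))
})

test_that("absences corroborate only across enough complete taxa", {
  calls <- make_calls(protein = c("a", "b"), taxon = c("Q1", "Q2"),
                      family = c("Nup98", "Nup98"), label = "host_related")
  roles <- taxon_roles(stats::setNames(
    c(rep("query_host_lineage", 5), "host_outgroup"),
    c(paste0("Q", 1:5), "H1")))
  ev <- toy_evidence(calls$protein)
  m <- build_matrix(calls, ev, toy_registry(), roles)
  ## Rae1 and Tpr absent in all five taxa
  m$completeness[] <- c(0.9, 0.9, 0.9, 0.9, 0.9)
  m <- corroborate_absences(m, min_taxa = 3, min_completeness = 0.5)
  ab <- m$absences
  expect_true(ab$corroborated[ab$family == "Rae1"])
  ## absent in too few taxa: Nup98 missing only in Q3..Q5 = 3 taxa, still
  ## corroborated; drop completeness of two of them below the floor
  m$completeness[] <- c(0.9, 0.9, 0.2, 0.2, 0.9)
  m2 <- corroborate_absences(m, min_taxa = 3, min_completeness = 0.5)
  expect_false(m2$absences$corroborated[m2$absences$family == "Nup98"])
  ## all corroborating taxa below the completeness floor
  m$completeness[] <- 0.2
  m3 <- corroborate_absences(m, min_taxa = 3, min_completeness = 0.5)
  expect_true(all(!m3$absences$corroborated))
})

test_that("subcomplex presence needs a single found protein", {
  calls <- make_calls(protein = c("a", "b"), taxon = c("Q1", "Q1"),
                      family = c("Nup98", "Rae1"),
                      label = c("algal_related", "host_related"))
  ev <- toy_evidence(calls$protein, sp = c(TRUE, FALSE))
  m <- build_matrix(calls, ev, toy_registry(), toy_roles())
  s <- subcomplex_summary(m, toy_registry())
  host <- s[s$group == "host_lineage", ]
  expect_true(host$present[host$subcomplex == "central channel"])
  expect_true(host$present[host$subcomplex == "cytoplasmic complex"])
  expect_false(host$present[host$subcomplex == "nuclear basket"])
  nm <- s[s$group == "nucleomorph_derived", ]
  expect_true(nm$present[nm$subcomplex == "central channel"])
  expect_false(nm$present[nm$subcomplex == "cytoplasmic complex"])
})
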