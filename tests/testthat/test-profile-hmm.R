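test_that("profile construction matches hand-computed smoothed estimates", {
  ## 3 rows x 4 columns; col 2 and 3 each 1/3 gapped, all columns match
  aln <- ungapped_alignment(c(r1 = "MK-L", r2 = "M-AL", r3 = "MKAL"))
  p <- build_profile(aln)
  bg <- aa_background()
  expect_equal(p$M, 4L)
  ## emissions: (counts + 1 * background) / (n_observed + 1)
  expect_equal(unname(p$match_emissions[1, "M"]), (3 + bg[["M"]]) / 4)
  expect_equal(unname(p$match_emissions[2, "K"]), (2 + bg[["K"]]) / 3)
  expect_equal(unname(p$match_emissions[2, "A"]), bg[["A"]] / 3)
  ## transitions, Laplace-smoothed over allowed moves:
  ## begin: all three rows go B->M1
  expect_equal(unname(p$transitions[1, "MM"]), (3 + 1) / (3 + 3))
  ## from M2 (present in r1, r3): one M->M (r3), one M->D (r1)
  expect_equal(unname(p$transitions[3, c("MM", "MI", "MD")]),
               c(2, 1, 2) / 5)
  ## from D2 (r2): one D->M
  expect_equal(unname(p$transitions[3, c("DM", "DD", "DI")]),
               c(2, 1, 1) / 4)
  ## stochastic invariants hold to 1e-9
  expect_true(all(abs(rowSums(p$match_emissions) - 1) < 1e-9))
})

test_that("profiles from identical rows peak on the source residues", {
  aln <- ungapped_alignment(c(a = "MKL", b = "MKL", c = "MKL", d = "MKL"))
  p <- build_profile(aln)
  expect_equal(p$M, 3L)
  expect_equal(unname(which.max(p$match_emissions[2, ])),
               match("K", colnames(p$match_emissions)))
})

test_that("all-gap columns never become match states", {
  aln <- ungapped_alignment(c(r1 = "M--K", r2 = "M--K", r3 = "M--K"))
  p <- build_profile(aln)
  expect_equal(p$M, 2L)
  expect_equal(p$col_map, c(1L, 4L))
  aln2 <- ungapped_alignment(c(r1 = "--", r2 = "--", r3 = "A-"))
  expect_error(build_profile(aln2), "occupancy")
})

test_that("Viterbi and forward equal brute-force path enumeration", {
  set.seed(97)
  n_checked <- 0
  for (rep in 1:25) {
    aln <- random_tiny_alignment(sample(3:5, 1), sample(3:5, 1))
    p <- build_profile(aln)
    if (p$M > 4) next
    for (mode in c("local", "glocal")) {
      s <- random_seq(sample(1:5, 1), egtscreen:::AA20[1:8])
      expect_equal(viterbi_score(p, s, mode)$bits, enum_viterbi(p, s, mode),
                   tolerance = 1e-9)
      expect_equal(forward_score(p, s, mode), enum_forward(p, s, mode),
                   tolerance = 1e-9)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 20)
})

test_that("forward never falls below Viterbi (sum over paths >= best path)", {
  set.seed(13)
  for (rep in 1:100) {
    aln <- random_tiny_alignment(sample(3:6, 1), sample(3:6, 1))
    p <- build_profile(aln)
    mode <- sample(c("local", "glocal"), 1)
    s <- random_seq(sample(2:8, 1))
    expect_gte(forward_score(p, s, mode) + 1e-9, viterbi_score(p, s, mode)$bits)
  }
})

test_that("the consensus outscores every single-residue substitution", {
  set.seed(23)
  for (rep in 1:4) {
    S <- random_seq(sample(3:6, 1))
    aln <- ungapped_alignment(stats::setNames(rep(S, 4), paste0("r", 1:4)))
    p <- build_profile(aln)
    s0 <- viterbi_score(p, S, "local")$bits
    chars <- strsplit(S, "")[[1]]
    for (i in seq_along(chars)) {
      for (a in setdiff(egtscreen:::AA20, chars[i])) {
        mut <- chars
        mut[i] <- a
        expect_gte(s0, viterbi_score(p, paste(mut, collapse = ""),
                                     "local")$bits)
      }
    }
  }
})

test_that("glocal scoring of impossible lengths yields the -Inf sentinel", {
  ## insert-free profile cannot emit more residues than match states
  p <- conservation_profile(M = 2)
  expect_identical(forward_score(p, "AAA", "glocal"), -Inf)
  expect_identical(viterbi_score(p, "AAA", "glocal")$bits, -Inf)
  ## but shorter sequences reach the end through delete states
  expect_true(is.finite(forward_score(p, "A", "glocal")))
})

test_that("glocal forward probability is conserved over the sequence space", {
  ## exhaustive enumeration on a 2-symbol alphabet: an insert-free profile
  ## with M = 4 puts all its mass on sequences of length <= 4
  p <- conservation_profile(M = 4)
  total <- 0
  for (L in 0:4) {
    seqs <- if (L == 0) "" else {
      apply(expand.grid(rep(list(c("A", "C")), L)), 1, paste, collapse = "")
    }
    for (s in seqs) {
      lp <- forward_score(p, s, "glocal", odds = FALSE)
      if (is.finite(lp)) total <- total + 2^lp
    }
  }
  expect_equal(total, 1, tolerance = 1e-9)
})

test_that("calibration is reproducible and produces a positive rate", {
  p <- build_profile(ungapped_alignment(stats::setNames(
    replicate(6, random_seq(40)), paste0("r", 1:6))))
  c1 <- calibrate(p, n_decoys = 60, decoy_length = 40, seed = 7)
  c2 <- calibrate(p, n_decoys = 60, decoy_length = 40, seed = 7)
  expect_identical(c1$calibration, c2$calibration)
  expect_gt(c1$calibration[["lambda"]], 0)
  c3 <- calibrate(p, n_decoys = 60, decoy_length = 40, seed = 8)
  expect_false(identical(c1$calibration, c3$calibration))
  expect_error(calibrate(p, n_decoys = 10, decoy_length = 40, seed = 1),
               "at least 50")
})

test_that("E-values are monotone, linear in database size, and self-consistent", {
  set.seed(55)
  p <- build_profile(ungapped_alignment(stats::setNames(
    replicate(6, random_seq(60)), paste0("r", 1:6))))
  expect_error(evalue(p, 10, 100), "not calibrated")
  p <- calibrate(p, n_decoys = 200, decoy_length = 60, seed = 3)
  s <- seq(0, 40, by = 5)
  ev <- evalue(p, s, 100)
  expect_true(all(diff(ev) < 0))                       # strictly decreasing
  expect_equal(evalue(p, 12, 200), 2 * evalue(p, 12, 100))
  ## E of the median decoy score ~ n/2 within a factor of 2
  decoys <- withr::with_seed(3, replicate(
    200, paste(sample(egtscreen:::AA20, 60, TRUE, prob = aa_background()),
               collapse = "")))
  med <- stats::median(egtscreen:::score_sequences(p, decoys, "local",
                                                   "viterbi"))
  e_med <- evalue(p, med, 200)
  expect_gt(e_med, 50)
  expect_lt(e_med, 200)
})

test_that("profile rows survive a JSON round-trip", {
  aln <- ungapped_alignment(c(r1 = "MK-L", r2 = "M-AL", r3 = "MKAL"))
  p <- calibrate(build_profile(aln), n_decoys = 60, decoy_length = 10,
                 seed = 2)
  f <- withr::local_tempfile(fileext = ".json")
  write_profile_json(p, f)
  q <- read_profile_json(f)
  expect_equal(q$match_emissions, p$match_emissions, tolerance = 1e-12)
  expect_equal(q$transitions, p$transitions, tolerance = 1e-12)
  expect_equal(q$calibration, p$calibration, tolerance = 1e-12)
  expect_equal(q$col_map, p$col_map)
  s <- random_seq(8)
  expect_equal(forward_score(q, s), forward_score(p, s), tolerance = 1e-9)
})

test_that("align_to_profile reproduces reference rows and places inserts", {
  rows <- c(r1 = "MKLVAG", r2 = "MKLVAG", r3 = "MKLVAG")
  aln <- ungapped_alignment(rows)
  p <- build_profile(aln)
  ## identical sequence -> identical gapped row after augmentation
  aug <- augment_family_alignment(aln, p, protein_records("h1", "Q1", "MKLVAG"))
  expect_equal(unname(aug$seqs[["h1"]]), "MKLVAG")
  expect_equal(unname(aug$seqs[["r1"]]), "MKLVAG")
  ## one extra residue between two match columns -> one inserted column,
  ## and every reference row gains a gap there
  aug2 <- augment_family_alignment(aln, p, protein_records("h2", "Q1", "MKLWVAG"))
  expect_equal(aug2$n_columns, 7L)
  expect_equal(unname(degap(aug2$seqs[["h2"]])), "MKLWVAG")
  expect_equal(sum(strsplit(aug2$seqs[["r1"]], "")[[1]] == "-"), 1L)
  ## adding zero hits is the identity
  expect_identical(augment_family_alignment(aln, p,
                                            protein_records(character(0),
                                                            character(0),
                                                            character(0))),
                   aln)
})

test_that("rebuilding from an augmented alignment never lowers the hit score", {
  set.seed(5)
  for (r in 1:20) {
    L <- sample(30, 1) + 29
    base <- replicate(5, random_seq(L))
    hit <- strsplit(base[1], "")[[1]]
    idx <- sample(L, round(L * 0.3))
    hit[idx] <- sample(egtscreen:::AA20, length(idx), TRUE)
    hit <- paste(hit, collapse = "")
    aln <- ungapped_alignment(stats::setNames(base, paste0("r", 1:5)))
    p1 <- build_profile(aln)
    aug <- augment_family_alignment(aln, p1, protein_records("h", "Q", hit))
    p2 <- build_profile(aug)
    expect_gte(forward_score(p2, hit), forward_score(p1, hit) - 1e-9)
  }
})
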