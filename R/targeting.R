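## targeting: evidence that a protein could be trafficked to the
## nucleomorph — a signal-peptide heuristic over the N-terminal 40 residues,
## N-terminus completeness read from metadata or from aligned start
## positions, and FG-repeat scanning for central-channel nucleoporins.

#' N-terminus completeness of an aligned protein
#'
#' Upstream ORF-caller metadata wins when present (`basis = "metadata"`).
#' Otherwise the record is complete when its sequence starts with methionine
#' and its first residue sits in an alignment column no more than
#' `tolerance_cols` past the modal start column of the reference rows
#' (`basis = "aligned_methionine"`).
#'
#' @param id Protein id (must be a row of `alignment`).
#' @param alignment Augmented [aa_alignment()] containing the record.
#' @param tolerance_cols Allowed start-column lag behind the references.
#' @return List with `complete` (logical) and `basis`.
#' @export
check_nterm_complete <- function(id, alignment, tolerance_cols = 15L) {
  i <- match(id, names(alignment$seqs))
  if (is.na(i)) stop("record '", id, "' is not a row of the alignment")
  flag <- alignment$nterm[i]
  if (flag %in% c("complete", "incomplete")) {
    return(list(complete = flag == "complete", basis = "metadata"))
  }
  first_col <- function(s) regexpr("[^-]", s)[[1]]
  ref_starts <- vapply(alignment$seqs[alignment$is_ref], first_col, 0L)
  if (length(ref_starts) == 0L) {
    return(list(complete = NA, basis = "unknown"))
  }
  tab <- table(ref_starts)
  modal <- as.integer(names(tab)[which.max(tab)])
  start <- first_col(alignment$seqs[[i]])
  seqres <- degap(alignment$seqs[[i]])
  complete <- startsWith(seqres, "M") && start <= modal + tolerance_cols
  list(complete = complete, basis = "aligned_methionine")
}

#' Signal-peptide heuristic
#'
#' A documented stand-in for a dedicated predictor (import real predictions
#' with [import_sp_predictions()]). Examining the first 40 residues, a
#' positive call requires (a) a non-negative net charge over residues 2-6
#' (K/R = +1, D/E = -1), (b) a hydrophobic core: some 8-residue window
#' inside positions 4-21 with mean Kyte-Doolittle hydropathy >= `min_kd`,
#' and (c) a cleavage motif: a first mature residue at 1-based position p in
#' `[15, 35)` with residues p-1 and p-3 in {A, G, S, C, T}. The score is
#' the maximum window hydropathy; the cleavage position is the smallest
#' qualifying p. Sequences shorter than 25 residues are inconclusive.
#'
#' @param seq Residue string.
#' @param min_kd Hydrophobic-core threshold (default 1.6).
#' @return List: `sp` (logical, `NA` = inconclusive), `score`,
#'   `cleavage` (1-based first mature residue, `NA` if none).
#' @export
predict_signal_peptide <- function(seq, min_kd = 1.6) {
  if (nchar(seq) < 25L) {
    return(list(sp = NA, score = NA_real_, cleavage = NA_integer_))
  }
  chars <- strsplit(substr(seq, 1L, 40L), "", fixed = TRUE)[[1]]
  charge_of <- c(K = 1, R = 1, D = -1, E = -1)
  n_region <- chars[2:6]
  net_charge <- sum(charge_of[n_region], na.rm = TRUE)
  kd <- unname(.kd_scale[chars])
  kd[is.na(kd)] <- 0
  win_means <- vapply(4:14, function(s) mean(kd[s:(s + 7L)]), 0.0)
  score <- max(win_means)
  ok_core <- score >= min_kd
  small <- c("A", "G", "S", "C", "T")
  ps <- 15:34
  ps <- ps[ps <= nchar(seq)]
  qual <- ps[vapply(ps, function(p) {
    chars[p - 1L] %in% small && chars[p - 3L] %in% small
  }, TRUE)]
  cleavage <- if (length(qual) > 0L) qual[1L] else NA_integer_
  sp <- (net_charge >= 0) && ok_core && !is.na(cleavage)
  list(sp = sp, score = score,
       cleavage = if (sp) cleavage else NA_integer_)
}

#' Import external signal-peptide predictions
#'
#' Overrides heuristic values with predictor output. TSV columns: `protein`,
#' `sp_flag` (logical or 0/1), `score`, `cleavage`. Unknown proteins are
#' skipped with a warning; duplicated proteins keep the last row, with a
#' warning.
#'
#' @param evidence Targeting-evidence `data.frame` (see
#'   [targeting_evidence()]).
#' @param path TSV path.
#' @return Updated evidence `data.frame` with `sp_basis = "imported"` on
#'   overridden rows.
#' @export
import_sp_predictions <- function(evidence, path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(df) == 0L) return(evidence)
  if (!all(c("protein", "sp_flag") %in% names(df))) {
    stop("SP prediction table needs columns: protein, sp_flag")
  }
  dup <- duplicated(df$protein, fromLast = TRUE)
  if (any(dup)) {
    warning("duplicate SP prediction rows; keeping the last for: ",
            paste(unique(df$protein[dup]), collapse = ", "))
    df <- df[!dup, , drop = FALSE]
  }
  unknown <- setdiff(df$protein, evidence$protein)
  if (length(unknown) > 0L) {
    warning("SP predictions for unknown protein(s) skipped: ",
            paste(unknown, collapse = ", "))
    df <- df[df$protein %in% evidence$protein, , drop = FALSE]
  }
  for (r in seq_len(nrow(df))) {
    i <- match(df$protein[r], evidence$protein)
    evidence$sp_predicted[i] <- as.logical(df$sp_flag[r])
    if (!is.null(df$score)) evidence$sp_score[i] <- df$score[r]
    if (!is.null(df$cleavage)) evidence$sp_cleavage[i] <- df$cleavage[r]
    evidence$sp_basis[i] <- "imported"
  }
  evidence
}

#' Scan a sequence for FG repeats
#'
#' Counts (possibly overlapping) `FG` dimers in the densest window of length
#' at most `window`; density is per 100 residues of that window. The flag is
#' raised when both the count and density thresholds are met. `FXFG` and
#' `GLFG` motif counts over the whole sequence are reported separately.
#'
#' @param seq Residue string.
#' @param window Window length (default 200).
#' @param min_count Minimum dimer count for the flag (default 5).
#' @param min_density Minimum density per 100 residues (default 1.5).
#' @return List: `count`, `density`, `flag`, `fxfg`, `glfg`.
#' @export
scan_fg_repeats <- function(seq, window = 200L, min_count = 5L,
                            min_density = 1.5) {
  stopifnot(nzchar(seq))
  L <- nchar(seq)
  wlen <- min(window, L)
  pos <- gregexpr("(?=FG)", seq, perl = TRUE)[[1]]
  pos <- pos[pos > 0L]
  count <- 0L
  if (length(pos) > 0L) {
    ## densest window: two-pointer over sorted dimer start positions
    j <- 1L
    for (i in seq_along(pos)) {
      while (pos[i] - pos[j] + 2L > wlen) j <- j + 1L
      count <- max(count, i - j + 1L)
    }
  }
  density <- 100 * count / wlen
  n_motif <- function(pat) {
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    sum(m > 0L)
  }
  list(count = count, density = density,
       flag = count >= min_count && density >= min_density,
       fxfg = n_motif("(?=F.FG)"), glfg = n_motif("(?=GLFG)"))
}

#' Targeting evidence for retained proteins
#'
#' Combines N-terminus completeness, the signal-peptide heuristic, and the
#' FG-repeat scan into one evidence row per protein. The signal-peptide
#' verdict is only evaluated on records with complete N-termini; truncated
#' records get `NA` (predictors misfire on incomplete N-terminal ends).
#'
#' @param records Protein record `data.frame`.
#' @param alignment Augmented family alignment containing the records.
#' @param tolerance_cols Passed to [check_nterm_complete()].
#' @return `data.frame`: `protein`, `sp_predicted`, `sp_score`,
#'   `sp_cleavage`, `sp_basis`, `nterm_complete`, `nterm_basis`,
#'   `fg_count`, `fg_density`, `fg_flag`.
#' @export
targeting_evidence <- function(records, alignment, tolerance_cols = 15L) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    id <- records$id[i]
    seq <- records$sequence[i]
    nt <- check_nterm_complete(id, alignment, tolerance_cols)
    if (isTRUE(nt$complete)) {
      sp <- predict_signal_peptide(seq)
      sp_basis <- "heuristic"
    } else {
      sp <- list(sp = NA, score = NA_real_, cleavage = NA_integer_)
      sp_basis <- "not_evaluated"
    }
    fg <- scan_fg_repeats(seq)
    data.frame(protein = id, sp_predicted = sp$sp, sp_score = sp$score,
               sp_cleavage = sp$cleavage, sp_basis = sp_basis,
               nterm_complete = nt$complete, nterm_basis = nt$basis,
               fg_count = fg$count, fg_density = fg$density,
               fg_flag = fg$flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
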