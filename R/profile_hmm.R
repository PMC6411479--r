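## profile_hmm: build, calibrate, and score profile hidden Markov models
## from reference alignments. The scoring core lives in src/hmm.cpp; this
## file owns parameter estimation, the extreme-value calibration, E-values,
## and mapping Viterbi paths back onto alignment columns.

TRANS_COLS <- c("MM", "MI", "MD", "IM", "II", "ID", "DM", "DD", "DI")

## Moves allowed from each source state at column k (0 = begin, M = last).
## At k = M the "next" state is End; D/I targets past the last column are
## invalid, as are delete-state rows at k = 0.
allowed_moves <- function(M) {
  allow <- matrix(TRUE, nrow = M + 1, ncol = 9,
                  dimnames = list(NULL, TRANS_COLS))
  allow[M + 1, c("MD", "ID", "DD")] <- FALSE  # nothing beyond column M
  allow[1, c("DM", "DD", "DI")] <- FALSE      # no delete state at begin
  allow
}

new_profile_hmm <- function(family, match_emissions, insert_emissions,
                            transitions, background, col_map = NULL,
                            calibration = NULL, source_hash = NA_integer_) {
  M <- nrow(match_emissions)
  stopifnot(M >= 1, ncol(match_emissions) == 20,
            length(insert_emissions) == 20, length(background) == 20,
            nrow(transitions) == M + 1, ncol(transitions) == 9)
  colnames(match_emissions) <- AA20
  colnames(transitions) <- TRANS_COLS
  if (is.null(col_map)) col_map <- seq_len(M)
  tol <- 1e-9
  if (any(abs(rowSums(match_emissions) - 1) > tol)) {
    stop("match emission vectors must each sum to 1")
  }
  if (abs(sum(insert_emissions) - 1) > tol || abs(sum(background) - 1) > tol) {
    stop("insert emissions and background must sum to 1")
  }
  sums <- cbind(rowSums(transitions[, c("MM", "MI", "MD"), drop = FALSE]),
                rowSums(transitions[, c("IM", "II", "ID"), drop = FALSE]),
                rowSums(transitions[, c("DM", "DD", "DI"), drop = FALSE]))
  ok <- abs(sums - 1) <= tol
  ok[1, 3] <- TRUE  # no delete state at the begin column
  if (!all(ok)) stop("each outgoing-transition set must sum to 1")
  if (!is.null(calibration)) {
    if (!(is.numeric(calibration) && all(c("mu", "lambda") %in% names(calibration)) &&
          calibration[["lambda"]] > 0)) {
      stop("calibration must be c(mu = ..., lambda = ...) with lambda > 0")
    }
  }
  structure(list(family = family, M = M,
                 match_emissions = match_emissions,
                 insert_emissions = insert_emissions,
                 transitions = transitions, background = background,
                 col_map = as.integer(col_map), calibration = calibration,
                 source_hash = source_hash),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile_hmm '%s': %d match states%s\n", x$family, x$M,
              if (is.null(x$calibration)) " (uncalibrated)"
              else sprintf(" (mu = %.2f, lambda = %.3f)",
                           x$calibration[["mu"]], x$calibration[["lambda"]])))
  invisible(x)
}

#' Build a profile HMM from a reference alignment
#'
#' Columns whose gap fraction is below `occupancy_threshold` become match
#' states. Match emissions are observed residue counts plus
#' background-proportional pseudocounts, normalised; transitions are counted
#' from the gap structure of the alignment rows and Laplace-smoothed (+1 on
#' every allowed move). Deterministic for fixed inputs.
#'
#' @param alignment An [aa_alignment()].
#' @param occupancy_threshold Columns with gap fraction `<` this become
#'   match states (default 0.5).
#' @param pseudocount_weight Total weight of the background pseudocount added
#'   to each match-emission vector (default 1).
#' @return A `profile_hmm`.
#' @export
build_profile <- function(alignment, occupancy_threshold = 0.5,
                          pseudocount_weight = 1.0) {
  stopifnot(inherits(alignment, "aa_alignment"))
  mat <- alignment_matrix(alignment)
  gap_frac <- colMeans(mat == "-")
  match_cols <- which(gap_frac < occupancy_threshold)
  if (length(match_cols) == 0L) {
    stop("no alignment column passes the occupancy threshold; ",
         "lower occupancy_threshold")
  }
  M <- length(match_cols)
  bg <- .aa_background
  ## emissions
  em <- matrix(0, nrow = M, ncol = 20, dimnames = list(NULL, AA20))
  for (k in seq_len(M)) {
    col <- mat[, match_cols[k]]
    cnt <- table(factor(col[col %in% AA20], levels = AA20))
    v <- as.numeric(cnt) + pseudocount_weight * bg
    em[k, ] <- v / sum(v)
  }
  ## transitions from gap structure
  allow <- allowed_moves(M)
  counts <- matrix(0, nrow = M + 1, ncol = 9,
                   dimnames = list(NULL, TRANS_COLS))
  is_match <- logical(ncol(mat))
  is_match[match_cols] <- TRUE
  col_rank <- cumsum(is_match)  # match index at/before each column
  for (r in seq_len(nrow(mat))) {
    row <- mat[r, ]
    states <- character(0)
    ks <- integer(0)
    for (j in seq_along(row)) {
      if (is_match[j]) {
        states <- c(states, if (row[j] == "-") "D" else "M")
        ks <- c(ks, col_rank[j])
      } else if (row[j] != "-") {
        states <- c(states, "I")
        ks <- c(ks, col_rank[j])
      }
    }
    states <- c("M", states, "M")       # begin and end as M_0 / M_{M+1}
    ks <- c(0L, ks, M + 1L)
    for (t in seq_len(length(states) - 1L)) {
      from <- states[t]; to <- states[t + 1L]
      k <- ks[t]
      ## in a column walk the target is always at column k (insert) or
      ## k+1 (match/delete), so the move label is just the state pair
      move <- paste0(from, to)
      counts[k + 1L, move] <- counts[k + 1L, move] + 1
    }
  }
  counts <- counts + 1  # Laplace smoothing on allowed moves
  counts[!allow] <- 0
  trans <- counts
  for (src in c("M", "I", "D")) {
    cols <- paste0(src, c("M", "I", "D"))
    s <- rowSums(trans[, cols, drop = FALSE])
    s[s == 0] <- 1
    trans[, cols] <- trans[, cols, drop = FALSE] / s
  }
  new_profile_hmm(alignment$family, em, bg, trans, bg,
                  col_map = match_cols,
                  source_hash = fnv1a(unname(alignment$seqs)))
}

## Encode a residue string as 0-based integer indices (X and any ambiguity
## code -> 20, scored at background).
encode_seq <- function(seq) {
  idx <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], AA20)
  idx[is.na(idx)] <- 21L
  as.integer(idx - 1L)
}

## log2 emission matrices handed to the DP. `odds = TRUE` gives log-odds
## against the background (X column 0); `odds = FALSE` gives raw log2
## probabilities for probability-conservation checks.
profile_log_matrices <- function(profile, odds = TRUE) {
  if (odds) {
    mlo <- log2(profile$match_emissions) -
      matrix(log2(profile$background), nrow = profile$M, ncol = 20,
             byrow = TRUE)
    mlo <- cbind(mlo, 0)
    ilo <- rep(0, 21)
  } else {
    mlo <- cbind(log2(profile$match_emissions), -Inf)
    ilo <- c(log2(profile$insert_emissions), -Inf)
  }
  tlo <- log2(profile$transitions)
  tlo[profile$transitions == 0] <- -Inf
  list(mlo = mlo, ilo = ilo, tlo = tlo)
}

#' Viterbi score of a sequence against a profile
#'
#' Log-odds score in bits of the single best state path versus the residue
#' background. In `local` mode (the search default) the path may enter and
#' exit the model at any match state, with flanking residues scored at
#' background odds; `glocal` mode forces a begin-to-end traversal of the
#' model. Residue `X` emits at background (log-odds 0). When no legal path
#' exists the score is `-Inf`.
#'
#' @param profile A `profile_hmm`.
#' @param seq Residue string.
#' @param mode `"local"` or `"glocal"`.
#' @return List with `bits`, `path` (data.frame of `state`, `col`, `pos`;
#'   `pos` is the 1-based consumed residue, 0 for deletes), and `interval`
#'   (0-based half-open consumed interval).
#' @export
viterbi_score <- function(profile, seq, mode = c("local", "glocal")) {
  mode <- match.arg(mode)
  stopifnot(nzchar(seq))
  lm <- profile_log_matrices(profile)
  res <- hmm_viterbi_path(lm$mlo, lm$ilo, lm$tlo, encode_seq(seq),
                          as.integer(mode == "local"))
  path <- res$path
  df <- data.frame(state = c("M", "I", "D")[path[, 1] + 1L],
                   col = path[, 2], pos = path[, 3])
  list(bits = res$score, path = df,
       interval = c(start = res$start, end = res$end))
}

#' Forward score of a sequence against a profile
#'
#' Log-sum over all legal state paths, in bits versus background; always at
#' least the Viterbi score of the same instance. With `odds = FALSE` the raw
#' log2 sequence probability under the model is returned instead (glocal
#' only; used for probability bookkeeping, not search).
#'
#' @inheritParams viterbi_score
#' @param odds Score against the background (default) or return raw log2
#'   probability.
#' @return Bit score (scalar).
#' @export
forward_score <- function(profile, seq, mode = c("local", "glocal"),
                          odds = TRUE) {
  mode <- match.arg(mode)
  lm <- profile_log_matrices(profile, odds = odds)
  hmm_score(lm$mlo, lm$ilo, lm$tlo, encode_seq(seq),
            as.integer(mode == "local"), 0L)
}

## Batch scorer used by search and calibration.
score_sequences <- function(profile, seqs, mode = "local",
                            algorithm = c("viterbi", "forward")) {
  algorithm <- match.arg(algorithm)
  lm <- profile_log_matrices(profile)
  enc <- lapply(seqs, encode_seq)
  hmm_score_many(lm$mlo, lm$ilo, lm$tlo, enc,
                 as.integer(mode == "local"),
                 as.integer(algorithm == "viterbi"))
}

## Maximum-likelihood Gumbel fit (location mu, rate lambda) to a score
## sample. Standard profile-likelihood solve for lambda, then mu in closed
## form.
gumbel_fit_ml <- function(x) {
  if (length(unique(x)) == 1L) {
    stop("degenerate score distribution: all decoy scores equal")
  }
  sx <- stats::sd(x)
  xc <- x - mean(x)
  g <- function(lambda) {
    z <- -lambda * xc
    z <- z - max(z)                 # overflow-safe weights
    w <- exp(z)
    ## ML estimating equation: 1/lambda = mean(x) - sum(x w)/sum(w)
    1 / lambda + sum(xc * w) / sum(w)
  }
  lo <- 1e-4 / sx
  hi <- 50 / sx
  while (g(hi) > 0) hi <- hi * 2
  lambda <- stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
  z <- -lambda * xc
  zmax <- max(z)
  mu <- mean(x) - (zmax + log(mean(exp(z - zmax)))) / lambda
  c(mu = mu, lambda = lambda)
}

#' Calibrate a profile's extreme-value parameters
#'
#' Scores `n_decoys` i.i.d. background sequences with the local Viterbi
#' algorithm and fits a Gumbel distribution to the decoy bit scores by
#' maximum likelihood. The fitted `(mu, lambda)` are stored on the profile
#' and drive [evalue()].
#'
#' @param profile A `profile_hmm`.
#' @param n_decoys Number of decoys (at least 50).
#' @param decoy_length Decoy length; a sensible choice is the median length
#'   of the target database.
#' @param seed Integer seed; identical seeds give identical calibrations.
#' @return The profile with `calibration` set.
#' @export
calibrate <- function(profile, n_decoys = 200L, decoy_length, seed) {
  if (n_decoys < 50L) stop("n_decoys must be at least 50")
  stopifnot(decoy_length >= 1L)
  decoys <- withr::with_seed(seed, {
    replicate(n_decoys, paste(sample(AA20, decoy_length, replace = TRUE,
                                     prob = .aa_background), collapse = ""))
  })
  scores <- score_sequences(profile, decoys, mode = "local",
                            algorithm = "viterbi")
  fit <- gumbel_fit_ml(scores)
  profile$calibration <- fit
  profile
}

#' E-value of a bit score
#'
#' `database_size` times the Gumbel upper-tail probability of the score
#' under the profile's calibration; strictly decreasing in the score and
#' linear in the database size.
#'
#' @param profile A calibrated `profile_hmm`.
#' @param bit_score Bit score(s).
#' @param database_size Number of sequences searched.
#' @return E-value(s).
#' @export
evalue <- function(profile, bit_score, database_size) {
  if (is.null(profile$calibration)) {
    stop("profile '", profile$family,
         "' is not calibrated; run calibrate() first")
  }
  mu <- profile$calibration[["mu"]]
  lambda <- profile$calibration[["lambda"]]
  database_size * (-expm1(-exp(-lambda * (bit_score - mu))))
}

#' Align a sequence to a profile's column frame
#'
#' Runs local Viterbi and maps the path onto the profile's source alignment
#' columns: match residues land in their columns, insert and flanking
#' residues go to insert blocks keyed by the preceding match column. The
#' result is the raw material [augment_family_alignment()] uses to expand an
#' alignment; degapping the expanded row always recovers the input sequence.
#'
#' @param profile A `profile_hmm`.
#' @param seq Residue string.
#' @return List with `match` (character vector over match states, `NA` where
#'   deleted/uncovered), `inserts` (named list: block position `"k"` holds
#'   residues between match columns k and k+1; `"0"` is N-terminal), `bits`,
#'   and `interval`.
#' @export
align_to_profile <- function(profile, seq) {
  vit <- viterbi_score(profile, seq, mode = "local")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  match_res <- rep(NA_character_, profile$M)
  inserts <- list()
  add_ins <- function(k, res) {
    key <- as.character(k)
    inserts[[key]] <<- c(inserts[[key]], res)
  }
  p <- vit$path
  if (nrow(p) > 0L && is.finite(vit$bits)) {
    entry_col <- p$col[p$state != "I"][1L]
    if (is.na(entry_col)) entry_col <- p$col[1L]
    exit_col <- rev(p$col[p$state == "M"])[1L]
    ## leading flank
    if (vit$interval[["start"]] > 0) {
      for (i in seq_len(vit$interval[["start"]])) {
        add_ins(entry_col - 1L, chars[i])
      }
    }
    for (j in seq_len(nrow(p))) {
      if (p$state[j] == "M") match_res[p$col[j]] <- chars[p$pos[j]]
      if (p$state[j] == "I") add_ins(p$col[j], chars[p$pos[j]])
    }
    ## trailing flank
    if (vit$interval[["end"]] < length(chars)) {
      for (i in seq.int(vit$interval[["end"]] + 1L, length(chars))) {
        add_ins(exit_col, chars[i])
      }
    }
  } else {
    ## no alignable segment: the whole sequence is an N-terminal block
    for (ch in chars) add_ins(0L, ch)
  }
  list(match = match_res, inserts = inserts, bits = vit$bits,
       interval = vit$interval)
}

#' Serialize a profile to JSON
#'
#' @param profile A `profile_hmm`.
#' @param path Output path.
#' @export
write_profile_json <- function(profile, path) {
  obj <- list(family = profile$family, M = profile$M,
              match_emissions = unname(apply(profile$match_emissions, 1,
                                             function(r) as.list(stats::setNames(r, AA20)))),
              insert_emissions = as.list(stats::setNames(profile$insert_emissions, AA20)),
              transitions = as.data.frame(profile$transitions),
              background = as.list(stats::setNames(profile$background, AA20)),
              col_map = profile$col_map,
              calibration = if (is.null(profile$calibration)) NULL
                            else as.list(profile$calibration),
              source_hash = profile$source_hash)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a profile from JSON
#' @param path JSON path written by [write_profile_json()].
#' @return A `profile_hmm`.
#' @export
read_profile_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  em <- as.matrix(obj$match_emissions)[, AA20, drop = FALSE]
  trans <- as.matrix(obj$transitions)[, TRANS_COLS, drop = FALSE]
  rownames(em) <- NULL
  rownames(trans) <- NULL
  cal <- if (is.null(obj$calibration)) NULL else unlist(obj$calibration)
  new_profile_hmm(obj$family, em,
                  unlist(obj$insert_emissions)[AA20],
                  trans, unlist(obj$background)[AA20],
                  col_map = obj$col_map, calibration = cal,
                  source_hash = obj$source_hash)
}
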