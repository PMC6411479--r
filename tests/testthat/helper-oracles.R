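# Independent oracles used across the suite. These are deliberately naive
# (path/sequence enumeration, transition-matrix products) and never call the
# package's DP code.

# Enumerate every legal state path of a profile HMM over a sequence and
# return all path scores (log2). Mirrors the model definition: glocal runs
# begin -> column M exit; local enters any match state with log2(1/M), exits
# any match state freely, flanks at odds 0.
enum_path_scores <- function(profile, seq, mode = c("local", "glocal"),
                             odds = TRUE) {
  mode <- match.arg(mode)
  M <- profile$M
  x <- egtscreen:::encode_seq(seq) + 1L  # 1-based, 21 = X
  L <- length(x)
  lt <- log2(profile$transitions)
  lt[profile$transitions == 0] <- -Inf
  if (odds) {
    em <- log2(profile$match_emissions) -
      matrix(log2(profile$background), nrow = M, ncol = 20, byrow = TRUE)
    em <- cbind(em, 0)
    ie <- rep(0, 21)
  } else {
    em <- cbind(log2(profile$match_emissions), -Inf)
    ie <- c(log2(profile$insert_emissions), -Inf)
  }
  scores <- numeric(0)
  # state: type in M/I/D, column k, consumed i, accumulated score
  recurse <- function(type, k, i, acc) {
    if (!is.finite(acc)) return()
    tr <- function(col) lt[k + 1L, col]
    row <- c(M = "M", I = "I", D = "D")[[type]]
    if (mode == "glocal") {
      if (k == M) {
        scores[length(scores) + 1L] <<-
          if (i == L) acc + tr(paste0(row, "M")) else -Inf
        # fallthrough: may also continue with inserts at column M
      }
    } else if (type == "M") {
      # free exit from any match state; remaining residues are flank
      scores[length(scores) + 1L] <<- acc
    }
    # continue: M_{k+1}
    if (k < M && i < L) {
      recurse("M", k + 1L, i + 1L,
              acc + tr(paste0(row, "M")) + em[k + 1L, x[i + 1L]])
    }
    # insert I_k
    if (i < L) {
      recurse("I", k, i + 1L, acc + tr(paste0(row, "I")) + ie[x[i + 1L]])
    }
    # delete D_{k+1}
    if (k < M) {
      recurse("D", k + 1L, i, acc + tr(paste0(row, "D")))
    }
  }
  if (mode == "glocal") {
    recurse("M", 0L, 0L, 0)
  } else {
    for (s in 0:(L - 1)) {     # s flank residues before entry
      for (k0 in seq_len(M)) { # entry column
        recurse("M", k0, s + 1L, -log2(M) + em[k0, x[s + 1L]])
      }
    }
  }
  scores[is.finite(scores)]
}

enum_viterbi <- function(profile, seq, mode = "local", odds = TRUE) {
  s <- enum_path_scores(profile, seq, mode, odds)
  if (length(s) == 0) -Inf else max(s)
}

enum_forward <- function(profile, seq, mode = "local", odds = TRUE) {
  s <- enum_path_scores(profile, seq, mode, odds)
  if (length(s) == 0) return(-Inf)
  m <- max(s)
  m + log2(sum(2^(s - m)))
}

# Random tiny profile built from a random gapped alignment.
random_tiny_alignment <- function(n_rows = 4, n_cols = 4, gap_p = 0.2) {
  seqs <- vapply(seq_len(n_rows), function(i) {
    chars <- sample(egtscreen:::AA20[1:6], n_cols, replace = TRUE)
    gaps <- runif(n_cols) < gap_p
    if (all(gaps)) gaps[1] <- FALSE
    chars[gaps] <- "-"
    paste(chars, collapse = "")
  }, "")
  names(seqs) <- paste0("r", seq_len(n_rows))
  aa_alignment("toy", seqs, taxa = "T1")
}

random_seq <- function(len, alphabet = egtscreen:::AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Exact expected proportion of differing sites between two tips of the
# generator's jump process, by multiplying per-branch transition matrices
# along the tip-to-tip path (root distribution = background).
expected_p_jump <- function(path_lengths, rate) {
  bg <- aa_background()
  P_branch <- function(t) {
    q <- 1 - exp(-rate * t)
    P <- matrix(0, 20, 20)
    for (i in 1:20) {
      w <- bg
      w[i] <- 0
      w <- w / sum(w)
      P[i, ] <- q * w
      P[i, i] <- 1 - q
    }
    P
  }
  P <- diag(20)
  for (t in path_lengths) P <- P %*% P_branch(t)
  1 - sum(bg * diag(P))
}

# Small deterministic alignment fixtures.
ungapped_alignment <- function(rows, family = "fam") {
  aa_alignment(family, rows, taxa = "T1")
}

# Insert-free profile over a 2-symbol alphabet (A/C), used for exhaustive
# probability-conservation checks: with zero insert mass an M-state profile
# emits only sequences of length <= M.
conservation_profile <- function(M) {
  em <- matrix(0, M, 20, dimnames = list(NULL, egtscreen:::AA20))
  em[, "A"] <- 0.6
  em[, "C"] <- 0.4
  bg <- stats::setNames(rep(0, 20), egtscreen:::AA20)
  bg[c("A", "C")] <- 0.5
  trans <- matrix(0, M + 1, 9,
                  dimnames = list(NULL, egtscreen:::TRANS_COLS))
  trans[, "MM"] <- 0.8; trans[, "MD"] <- 0.2
  trans[, "IM"] <- 1
  trans[, "DM"] <- 0.7; trans[, "DD"] <- 0.3
  trans[M + 1, ] <- 0
  trans[M + 1, c("MM", "IM", "DM")] <- 1   # column M exits to End
  trans[1, c("DM", "DD", "DI")] <- 0       # no delete state at begin
  egtscreen:::new_profile_hmm("conservation", em, bg, trans, bg)
}
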