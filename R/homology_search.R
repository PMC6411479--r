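## homology_search: screen proteomes with all family profiles, apply the
## triage rules (E-value threshold, best-N cap), assign each hit protein its
## best-scoring family, and fold retained hits back into the reference
## alignments.

#' Search proteomes with a set of family profiles
#'
#' Every (profile, protein) pair is scored with local Viterbi; hits with
#' E-value at or below `e_threshold` are retained. The E-value database size
#' is the pooled number of proteins searched. Deterministic given inputs.
#'
#' @param profiles Named list of calibrated `profile_hmm` objects.
#' @param proteomes A protein record `data.frame` (rows from one or more
#'   taxa; see [protein_records()]), or a list of such frames.
#' @param e_threshold Retention threshold on the E-value (default `1e-5`).
#' @return Hit table `data.frame`: `family`, `protein`, `taxon`, `bits`,
#'   `evalue`, `start`, `end`, sorted by family then ascending E-value.
#' @export
search_proteomes <- function(profiles, proteomes, e_threshold = 1e-5) {
  if (is.data.frame(proteomes)) proteomes <- list(proteomes)
  prot <- do.call(rbind, proteomes)
  empty_hits <- data.frame(family = character(0), protein = character(0),
                           taxon = character(0), bits = numeric(0),
                           evalue = numeric(0), start = integer(0),
                           end = integer(0), stringsAsFactors = FALSE)
  if (is.null(prot) || nrow(prot) == 0L) {
    warning("empty proteome input: no sequences to search")
    return(empty_hits)
  }
  if (length(profiles) == 0L) return(empty_hits)
  for (p in profiles) {
    if (is.null(p$calibration)) {
      stop("profile '", p$family, "' is not calibrated")
    }
  }
  db_size <- nrow(prot)
  out <- lapply(profiles, function(profile) {
    bits <- score_sequences(profile, prot$sequence, mode = "local",
                            algorithm = "viterbi")
    ev <- evalue(profile, bits, db_size)
    keep <- which(ev <= e_threshold)
    if (length(keep) == 0L) return(NULL)
    ivs <- t(vapply(keep, function(i) {
      viterbi_score(profile, prot$sequence[i], mode = "local")$interval
    }, c(start = 0, end = 0)))
    data.frame(family = profile$family, protein = prot$id[keep],
               taxon = prot$taxon[keep], bits = bits[keep],
               evalue = ev[keep], start = as.integer(ivs[, 1]),
               end = as.integer(ivs[, 2]), stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, c(out, list(empty_hits)))
  hits <- hits[order(hits$family, hits$evalue, -hits$bits, hits$protein), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Keep the best N hits per family
#'
#' Per family, the `top_n` hits by ascending E-value are kept across all
#' taxa pooled; ties break by descending bit score, then lexicographic
#' protein id.
#'
#' @param hits Hit table from [search_proteomes()].
#' @param top_n Cap per family (default 200).
#' @param per_taxon Apply the cap within each taxon instead of pooled.
#' @return Filtered hit table.
#' @export
triage_top_n <- function(hits, top_n = 200L, per_taxon = FALSE) {
  if (nrow(hits) == 0L) return(hits)
  key <- if (per_taxon) paste(hits$family, hits$taxon, sep = "\r") else hits$family
  ord <- order(key, hits$evalue, -hits$bits, hits$protein)
  hits <- hits[ord, , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(hits)), key[ord]), function(i) {
    utils::head(i, top_n)
  }), use.names = FALSE)
  out <- hits[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign a protein to its best-scoring family
#'
#' Scores the sequence against every profile with the forward algorithm and
#' reports the best family together with the bit-score margin over the
#' runner-up. Sequences that no profile scores above `-Inf`, or with a
#' negative best score, are unassigned. Ties break on profile name.
#'
#' @param sequence Residue string.
#' @param profiles Named list of `profile_hmm` objects (at least 2 for a
#'   meaningful margin).
#' @return List with `family` (or `NA` when unassigned) and `margin` (bits).
#' @export
assign_family <- function(sequence, profiles) {
  fams <- vapply(profiles, function(p) p$family, "")
  bits <- vapply(profiles, function(p) {
    forward_score(p, sequence, mode = "local")
  }, 0.0)
  ord <- order(-bits, fams)
  best <- ord[1L]
  if (!is.finite(bits[best]) || bits[best] < 0) {
    return(list(family = NA_character_, margin = 0))
  }
  margin <- if (length(bits) >= 2L) bits[best] - bits[ord[2L]] else Inf
  list(family = unname(fams[best]), margin = unname(margin))
}

#' Assign every hit protein its best family
#'
#' Batch version of [assign_family()]. With `prefilter` below the number of
#' profiles, only the `prefilter` profiles with the best Viterbi score per
#' protein are forward-scored; the best/runner-up margin is computed within
#' that shortlist (Viterbi and forward rankings only diverge between
#' near-tied profiles, which the shortlist keeps).
#'
#' @param proteins Protein record `data.frame`.
#' @param profiles Named list of `profile_hmm` objects.
#' @param prefilter Size of the Viterbi shortlist (default: all profiles).
#' @return `data.frame`: `protein`, `assigned_family`, `margin`.
#' @export
assign_families <- function(proteins, profiles, prefilter = length(profiles)) {
  fams <- vapply(profiles, function(p) p$family, "")
  if (nrow(proteins) == 0L) {
    return(data.frame(protein = character(0),
                      assigned_family = character(0), margin = numeric(0),
                      stringsAsFactors = FALSE))
  }
  if (prefilter >= length(profiles)) {
    res <- lapply(proteins$sequence, assign_family, profiles = profiles)
    return(data.frame(protein = proteins$id,
                      assigned_family = vapply(res, function(r) r$family, ""),
                      margin = vapply(res, function(r) r$margin, 0.0),
                      stringsAsFactors = FALSE))
  }
  vit <- vapply(profiles, function(p) {
    score_sequences(p, proteins$sequence, mode = "local",
                    algorithm = "viterbi")
  }, numeric(nrow(proteins)))
  vit <- matrix(vit, nrow = nrow(proteins))
  res <- lapply(seq_len(nrow(proteins)), function(i) {
    short <- order(-vit[i, ])[seq_len(max(2L, prefilter))]
    assign_family(proteins$sequence[i], profiles[short])
  })
  data.frame(protein = proteins$id,
             assigned_family = vapply(res, function(r) r$family, ""),
             margin = vapply(res, function(r) r$margin, 0.0),
             stringsAsFactors = FALSE)
}

#' Fold retained hits into a family alignment
#'
#' Each hit sequence is aligned to the family profile
#' ([align_to_profile()]) and the alignment is expanded: match residues land
#' in their source columns, and insert blocks become new columns (shared
#' across rows, gap-padded). Reference rows gain gaps in inserted columns,
#' so removing the added rows recovers the original columns. A hit whose id
#' collides with an existing row is suffixed with its taxon, with a warning.
#'
#' @param alignment Reference [aa_alignment()].
#' @param profile The family's `profile_hmm`.
#' @param records Protein record `data.frame` of hits for this family
#'   (zero rows allowed).
#' @return Expanded [aa_alignment()]; added rows have `is_ref = FALSE`.
#' @export
augment_family_alignment <- function(alignment, profile, records) {
  if (is.null(records) || nrow(records) == 0L) return(alignment)
  ids <- records$id
  clash <- ids %in% names(alignment$seqs)
  if (any(clash)) {
    warning("hit id(s) already present in alignment, suffixing with taxon: ",
            paste(ids[clash], collapse = ", "))
    ids[clash] <- paste(ids[clash], records$taxon[clash], sep = "|")
  }
  rows <- lapply(records$sequence, align_to_profile, profile = profile)
  M <- profile$M
  ncol0 <- alignment$n_columns
  col_map <- profile$col_map
  ## width of the insert block after each match column (0 = N-terminal)
  widths <- rep(0L, M + 1L)
  for (r in rows) {
    for (key in names(r$inserts)) {
      b <- as.integer(key) + 1L
      widths[b] <- max(widths[b], length(r$inserts[[key]]))
    }
  }
  ## map block b (after match col b-1) to the original column it follows:
  ## block 1 (N-terminal) goes before column 1, block b>1 after col_map[b-1]
  pad <- function(chars, w) {
    c(chars, rep("-", w - length(chars)))
  }
  expand_ref <- function(gapped) {
    chars <- strsplit(gapped, "", fixed = TRUE)[[1]]
    out <- rep("-", widths[1L])
    prev <- 0L
    for (k in seq_len(M)) {
      j <- col_map[k]
      if (j > prev) out <- c(out, chars[(prev + 1L):j])
      prev <- j
      out <- c(out, rep("-", widths[k + 1L]))
    }
    if (prev < ncol0) out <- c(out, chars[(prev + 1L):ncol0])
    paste(out, collapse = "")
  }
  expand_hit <- function(r) {
    ins <- function(b) {
      key <- as.character(b - 1L)
      chars <- if (key %in% names(r$inserts)) r$inserts[[key]] else character(0)
      pad(chars, widths[b])
    }
    out <- ins(1L)
    prev <- 0L
    for (k in seq_len(M)) {
      j <- col_map[k]
      if (j > prev) out <- c(out, rep("-", j - prev - 1L),
                             if (is.na(r$match[k])) "-" else r$match[k])
      prev <- j
      out <- c(out, ins(k + 1L))
    }
    if (prev < ncol0) out <- c(out, rep("-", ncol0 - prev))
    paste(out, collapse = "")
  }
  ref_rows <- vapply(alignment$seqs, expand_ref, "")
  hit_rows <- vapply(rows, expand_hit, "")
  names(hit_rows) <- ids
  nterm <- records$nterm
  if (is.null(nterm)) nterm <- rep("unknown", nrow(records))
  aa_alignment(alignment$family,
               c(ref_rows, hit_rows),
               taxa = c(alignment$taxa, records$taxon),
               nterm = c(alignment$nterm, nterm),
               is_ref = c(alignment$is_ref, rep(FALSE, length(hit_rows))))
}
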