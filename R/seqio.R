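## seqio: readers/writers for FASTA, aligned FASTA, Newick, and the tabular
## side files (taxon roles, family registry), plus their validation.

#' Construct a set of protein records
#'
#' The in-memory form of a proteome: one row per protein with its identifier,
#' source taxon, residue string, and the N-terminus completeness flag carried
#' over from upstream ORF calling (when known).
#'
#' @param id Character vector of unique identifiers.
#' @param taxon Character vector (recycled if length 1).
#' @param sequence Uppercase amino-acid strings over the 20 canonical
#'   residues plus `X`; stop symbols and gaps are not allowed.
#' @param nterm One of `"complete"`, `"incomplete"`, `"unknown"` per record.
#' @return A `data.frame` with columns `id`, `taxon`, `sequence`, `nterm`.
#' @export
protein_records <- function(id, taxon, sequence,
                            nterm = rep("unknown", length(id))) {
  if (length(taxon) == 1L) taxon <- rep(taxon, length(id))
  stopifnot(length(id) == length(sequence), length(id) == length(taxon),
            length(id) == length(nterm))
  dup <- id[duplicated(id)]
  if (length(dup) > 0L) {
    stop("duplicate protein id(s): ", paste(unique(dup), collapse = ", "))
  }
  if (any(!nzchar(sequence))) {
    stop("empty sequence for id(s): ",
         paste(id[!nzchar(sequence)], collapse = ", "))
  }
  bad <- regexpr(sprintf("[^%sX]", paste(AA20, collapse = "")), sequence)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid residue '%s' at position %d of sequence '%s'",
                 substr(sequence[i], bad[i], bad[i]), bad[i], id[i]))
  }
  if (!all(nterm %in% c("complete", "incomplete", "unknown"))) {
    stop("nterm must be one of complete, incomplete, unknown")
  }
  data.frame(id = as.character(id), taxon = as.character(taxon),
             sequence = as.character(sequence), nterm = as.character(nterm),
             stringsAsFactors = FALSE)
}

## Parse "key=value" metadata tokens after the id in a FASTA header.
parse_header_tags <- function(desc) {
  tags <- regmatches(desc, gregexpr("\\b[A-Za-z_]+=[^ \t]+", desc))[[1]]
  if (length(tags) == 0L) return(character(0))
  kv <- strsplit(tags, "=", fixed = TRUE)
  stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
}

#' Read a protein FASTA file
#'
#' The header token before the first whitespace becomes the record id;
#' an optional `nterm=complete|incomplete` header tag populates the
#' N-terminus flag. Terminal `*` stop symbols are stripped and lowercase
#' residues are uppercased.
#'
#' @param path Path to a FASTA file.
#' @param taxon Taxon name attached to every record (default: file base name
#'   without extension).
#' @return A protein record `data.frame` (see [protein_records()]).
#' @export
read_fasta <- function(path, taxon = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("no such file: ", path)
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate protein id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*+$", "", seqs)
  nterm <- vapply(headers, function(h) {
    tags <- parse_header_tags(h)
    if ("nterm" %in% names(tags) &&
        tags[["nterm"]] %in% c("complete", "incomplete")) {
      tags[["nterm"]]
    } else "unknown"
  }, "", USE.NAMES = FALSE)
  protein_records(ids, taxon, seqs, nterm)
}

#' Write protein records to FASTA
#'
#' @param records Protein record `data.frame`.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(records, path, width = 70L) {
  hdr <- ifelse(records$nterm == "unknown", records$id,
                paste0(records$id, " nterm=", records$nterm))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", hdr[i]), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a protein family alignment
#'
#' @param family Family name.
#' @param seqs Named character vector of gapped rows (names are protein ids),
#'   all the same length, gaps as `-`.
#' @param taxa Taxon per row (recycled if length 1).
#' @param nterm N-terminus flag per row.
#' @param is_ref Logical per row: `TRUE` for curated reference rows, `FALSE`
#'   for rows added from search hits.
#' @return An object of class `aa_alignment`.
#' @export
aa_alignment <- function(family, seqs, taxa = rep(NA_character_, length(seqs)),
                         nterm = rep("unknown", length(seqs)),
                         is_ref = rep(TRUE, length(seqs))) {
  if (length(seqs) == 0L) stop("alignment has no rows")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("alignment rows must be named by protein id")
  }
  if (length(taxa) == 1L) taxa <- rep(taxa, length(seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    off <- which(lens != lens[1L])[1L]
    stop(sprintf("ragged alignment: row '%s' has %d columns, row '%s' has %d",
                 names(seqs)[off], lens[off], names(seqs)[1L], lens[1L]))
  }
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup) > 0L) stop("duplicate row id(s): ", paste(dup, collapse = ", "))
  structure(list(family = family, seqs = seqs, taxa = taxa,
                 nterm = nterm, is_ref = is_ref, n_columns = lens[[1L]]),
            class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("aa_alignment '%s': %d rows x %d columns (%d reference)\n",
              x$family, length(x$seqs), x$n_columns, sum(x$is_ref)))
  invisible(x)
}

#' Remove gaps from an alignment row
#' @param x Gapped string(s).
#' @return Ungapped string(s).
#' @export
degap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Alignment as a character matrix
#' @param alignment An `aa_alignment`.
#' @return Character matrix, rows named by protein id.
#' @export
alignment_matrix <- function(alignment) {
  m <- do.call(rbind, strsplit(alignment$seqs, "", fixed = TRUE))
  rownames(m) <- names(alignment$seqs)
  m
}

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned FASTA file (equal-length gapped rows).
#' @param family Family name to attach.
#' @param taxa Optional taxon per row; by default parsed from a
#'   `taxon=` header tag when present, else `NA`.
#' @return An `aa_alignment`.
#' @export
read_alignment <- function(path, family, taxa = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0L) stop("empty alignment file: ", path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  seqs <- stats::setNames(toupper(as.character(aa)), ids)
  bad <- regexpr(sprintf("[^%sX-]", paste(AA20, collapse = "")), seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid character '%s' at column %d of row '%s'",
                 substr(seqs[i], bad[i], bad[i]), bad[i], ids[i]))
  }
  meta <- lapply(headers, parse_header_tags)
  if (is.null(taxa)) {
    taxa <- vapply(meta, function(t) {
      if ("taxon" %in% names(t)) t[["taxon"]] else NA_character_
    }, "")
  }
  nterm <- vapply(meta, function(t) {
    if ("nterm" %in% names(t) &&
        t[["nterm"]] %in% c("complete", "incomplete")) t[["nterm"]]
    else "unknown"
  }, "")
  aa_alignment(family, seqs, taxa, nterm)
}

#' Write an alignment to aligned FASTA
#' @param alignment An `aa_alignment`.
#' @param path Output path.
#' @export
write_alignment <- function(alignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(alignment$seqs)) {
    tags <- character(0)
    if (!is.na(alignment$taxa[i])) tags <- c(tags, paste0("taxon=", alignment$taxa[i]))
    if (alignment$nterm[i] != "unknown") tags <- c(tags, paste0("nterm=", alignment$nterm[i]))
    writeLines(paste0(">", paste(c(names(alignment$seqs)[i], tags), collapse = " ")), con)
    writeLines(alignment$seqs[[i]], con)
  }
  invisible(path)
}

#' Read a Newick tree
#'
#' Internal node labels, when present, must be integers in `[0, 100]` and are
#' interpreted as support values attached to the child node of the edge they
#' annotate. Missing branch lengths default to 0; missing labels mean
#' unknown support.
#'
#' @param text Newick string (or a file path when `is_file = TRUE`).
#' @param is_file Read `text` as a file path.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(text, is_file = FALSE) {
  if (is_file) text <- paste(readLines(text, warn = FALSE), collapse = "")
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) {
      stop(sprintf("unbalanced parentheses in Newick at character %d", i))
    }
  }
  if (depth != 0L) {
    stop(sprintf("unbalanced parentheses in Newick at character %d",
                 length(chars)))
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error: unreadable tree")
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  if (!is.null(tree$node.label)) {
    lab <- tree$node.label
    nonempty <- nzchar(lab) & !is.na(lab)
    val <- suppressWarnings(as.numeric(lab[nonempty]))
    if (any(is.na(val)) || any(val != floor(val)) ||
        any(val < 0 | val > 100)) {
      stop("internal node labels must be integer support values in [0, 100]")
    }
  }
  tree
}

#' Write a tree to Newick
#' @param tree An [ape::phylo] tree (supports in `node.label`).
#' @param path Optional output path; when `NULL` the string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Integer support values of a tree
#'
#' @param tree An [ape::phylo] tree.
#' @return Integer vector over internal nodes (`NA` = unknown).
#' @export
node_supports <- function(tree) {
  n_int <- tree$Nnode
  if (is.null(tree$node.label)) return(rep(NA_integer_, n_int))
  out <- suppressWarnings(as.integer(tree$node.label))
  length(out) <- n_int
  out
}

#' Read the taxon-role table
#'
#' A TSV with header columns `taxon` and `role`; roles come from the closed
#' vocabulary `query_host_lineage`, `host_outgroup`, `endosymbiont_algal`,
#' `other_reference`.
#'
#' @param path TSV path.
#' @return Named character vector: taxon -> role.
#' @export
read_taxon_roles <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("taxon", "role") %in% names(df))) {
    stop("taxon-role table needs header columns: taxon, role")
  }
  taxon_roles(stats::setNames(df$role, df$taxon))
}

#' Validate a taxon-role map
#' @param roles Named character vector taxon -> role.
#' @return The validated vector.
#' @export
taxon_roles <- function(roles) {
  bad <- setdiff(unique(roles), ROLE_LEVELS)
  if (length(bad) > 0L) {
    stop("unknown role(s): ", paste(bad, collapse = ", "),
         "; allowed roles are: ", paste(ROLE_LEVELS, collapse = ", "))
  }
  dup <- names(roles)[duplicated(names(roles))]
  if (length(dup) > 0L) {
    stop("taxon listed more than once: ", paste(unique(dup), collapse = ", "))
  }
  roles
}

#' Write a taxon-role table
#' @param roles Named character vector taxon -> role.
#' @param path Output TSV path.
#' @export
write_taxon_roles <- function(roles, path) {
  utils::write.table(data.frame(taxon = names(roles), role = unname(roles)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a family registry
#'
#' A TSV with header columns `family`, `display`, `subcomplex`, and
#' optionally `notes`, mapping nucleoporin families to NPC subcomplexes.
#' Merged families (e.g. `Nup120-160`) are single entries.
#'
#' @param path TSV path.
#' @return A `data.frame` with columns `family`, `display`, `subcomplex`,
#'   `notes`.
#' @export
read_registry <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("family", "subcomplex") %in% names(df))) {
    stop("registry needs header columns: family, subcomplex")
  }
  if (is.null(df$display)) df$display <- df$family
  if (is.null(df$notes)) df$notes <- ""
  family_registry(df)
}

#' Validate a family registry
#' @param df `data.frame` with columns `family`, `subcomplex` (and optional
#'   `display`, `notes`).
#' @return The validated registry `data.frame`.
#' @export
family_registry <- function(df) {
  if (is.null(df$display)) df$display <- df$family
  if (is.null(df$notes)) df$notes <- ""
  df$notes <- as.character(df$notes)
  df$notes[is.na(df$notes)] <- ""
  df$display <- as.character(df$display)
  bad <- setdiff(unique(df$subcomplex), SUBCOMPLEX_LEVELS)
  if (length(bad) > 0L) {
    stop("unknown subcomplex: ", paste(bad, collapse = ", "),
         "; allowed: ", paste(SUBCOMPLEX_LEVELS, collapse = ", "))
  }
  dup <- df$family[duplicated(df$family)]
  if (length(dup) > 0L) {
    stop("family listed more than once: ", paste(unique(dup), collapse = ", "))
  }
  df[, c("family", "display", "subcomplex", "notes")]
}

#' Write a family registry
#' @param registry Registry `data.frame`.
#' @param path Output TSV path.
#' @export
write_registry <- function(registry, path) {
  utils::write.table(registry, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Default registry of 32 canonical nucleoporin families
#'
#' The canonical NPC inventory grouped into the six subcomplexes
#' (cytoplasmic complex, outer ring, inner ring, transmembrane ring, central
#' channel, nuclear basket). Merged families are single entries. The notes
#' field records multi-location proteins such as Nup98, which associates with
#' both faces of the pore and the central channel.
#'
#' @return Registry `data.frame` with 32 rows.
#' @export
default_registry <- function() {
  e <- function(family, subcomplex, notes = "") {
    data.frame(family = family, display = family, subcomplex = subcomplex,
               notes = notes, stringsAsFactors = FALSE)
  }
  family_registry(rbind(
    e("Nup214",     "cytoplasmic complex"),
    e("Nup88",      "cytoplasmic complex"),
    e("Gle1",       "cytoplasmic complex"),
    e("Rae1",       "cytoplasmic complex", "transient; mRNA export factor"),
    e("Nup358",     "cytoplasmic complex", "animal-specific"),
    e("Nup85",      "outer ring"),
    e("Nup96",      "outer ring"),
    e("Nup107",     "outer ring"),
    e("Nup120-160", "outer ring", "merged family"),
    e("Nup133",     "outer ring"),
    e("Sec13",      "outer ring", "shared with COPII coat"),
    e("Seh1",       "outer ring"),
    e("Nup37",      "outer ring", "animal-specific"),
    e("Nup43",      "outer ring", "animal-specific"),
    e("Aladin",     "outer ring"),
    e("Nup35",      "inner ring"),
    e("Nup93",      "inner ring"),
    e("Nup155",     "inner ring"),
    e("Nup188",     "inner ring"),
    e("Nup192-205", "inner ring", "merged family"),
    e("Ndc1",       "transmembrane ring"),
    e("Gp210",      "transmembrane ring"),
    e("Pom121",     "transmembrane ring", "animal-specific"),
    e("Pom152",     "transmembrane ring", "traditionally fungal-specific"),
    e("Pom34",      "transmembrane ring", "fungal-specific"),
    e("Nup54",      "central channel"),
    e("Nup58",      "central channel"),
    e("Nup62",      "central channel"),
    e("Nup98",      "central channel",
      "multi-location: both pore faces and nucleoplasm; FG-repeat bearing"),
    e("Tpr",        "nuclear basket"),
    e("Nup50",      "nuclear basket"),
    e("Nup153",     "nuclear basket")
  ))
}

#' Collapse transcript isoforms by id prefix
#'
#' Transcriptome assemblies often emit several isoforms per gene. When ids
#' share a gene prefix (everything before the last match of `sep_pattern`),
#' this keeps one record per prefix — the longest sequence, ties broken by
#' id order. How the original study collapsed isoforms is not recorded
#' anywhere, so this is an optional, explicit rule, off unless called.
#'
#' @param records Protein record `data.frame`.
#' @param sep_pattern Regular expression separating gene prefix from isoform
#'   suffix (default `"\\.[0-9]+$"`, i.e. a trailing dotted number).
#' @return Filtered protein record `data.frame`.
#' @export
collapse_isoforms <- function(records, sep_pattern = "\\.[0-9]+$") {
  prefix <- sub(sep_pattern, "", records$id)
  ord <- order(prefix, -nchar(records$sequence), records$id)
  keep <- !duplicated(prefix[ord])
  out <- records[ord, , drop = FALSE][keep, , drop = FALSE]
  out <- out[order(match(out$id, records$id)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
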