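# Alignment data model and gapped/ungapped coordinate arithmetic.
#
# An `aa_alignment` is a thin S3 container: parallel vectors of row ids,
# species labels, homolog-group labels and equal-length gapped amino-acid
# strings.  Coordinates are 1-based inclusive throughout; '-' is the
# canonical gap ('.' is accepted on input and normalized).

AA_RESIDUES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_AMBIGUOUS <- c("X", "B", "Z")
AA_ALPHABET_RE <- "[^ACDEFGHIKLMNPQRSTVWYXBZ.-]"

#' Construct a protein alignment
#'
#' Builds an `aa_alignment` from gapped sequences.  All rows must share one
#' length; ids must be unique; letters are restricted to the 20 amino
#' acids, the ambiguity codes `X`/`B`/`Z` and the gap characters `-`/`.`.
#' On construction (unless `normalize = FALSE`) `.` gaps are rewritten to
#' `-`, lowercase letters are uppercased, and columns consisting entirely
#' of gaps are dropped with a message.
#'
#' @param ids Character vector of unique row identifiers.
#' @param seqs Character vector of gapped sequences, parallel to `ids`.
#' @param species Optional character vector of species names per row.
#' @param homolog_group Optional character vector of paralog-group labels.
#' @param normalize Normalize gaps and drop all-gap columns (default TRUE).
#' @return An object of class `aa_alignment`.
#' @export
aa_alignment <- function(ids, seqs, species = NULL, homolog_group = NULL,
                         normalize = TRUE) {
  ids <- unname(as.character(ids))
  seqs <- unname(toupper(as.character(seqs)))
  if (length(ids) != length(seqs))
    stop("`ids` and `seqs` must have the same length")
  if (length(ids) == 0L) stop("alignment must contain at least one row")
  if (anyDuplicated(ids))
    stop("duplicate row id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(seqs))) stop("empty sequence for row ", ids[!nzchar(seqs)][1])
  widths <- nchar(seqs)
  if (length(unique(widths)) > 1L) {
    ref <- widths[1]  # the first row defines the width
    bad <- ids[widths != ref][1]
    stop("rows differ in length (row '", bad, "' has ", widths[ids == bad],
         " columns, expected ", ref, ")")
  }
  for (k in seq_along(seqs)) {
    m <- regexpr(AA_ALPHABET_RE, seqs[k])
    if (m > 0)
      stop("illegal character '", substr(seqs[k], m, m), "' in row '",
           ids[k], "' at column ", m)
  }
  if (is.null(species)) species <- rep(NA_character_, length(ids))
  if (is.null(homolog_group)) homolog_group <- rep(NA_character_, length(ids))
  aln <- structure(
    list(id = ids, species = unname(as.character(species)),
         homolog_group = unname(as.character(homolog_group)), seqs = seqs),
    class = "aa_alignment")
  if (normalize) aln <- normalize_alignment(aln) else {
    aln$seqs <- gsub(".", "-", aln$seqs, fixed = TRUE)
  }
  aln
}

normalize_alignment <- function(aln) {
  aln$seqs <- gsub(".", "-", aln$seqs, fixed = TRUE)
  mat <- aln_matrix(aln)
  allgap <- colSums(mat != "-") == 0L
  if (any(allgap)) {
    message("removed ", sum(allgap), " all-gap column(s): ",
            paste(utils::head(which(allgap), 10), collapse = ", "))
    mat <- mat[, !allgap, drop = FALSE]
    aln$seqs <- unname(apply(mat, 1L, paste, collapse = ""))
  }
  aln
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("aa_alignment: ", length(x$id), " rows x ", aln_width(x),
      " columns\n", sep = "")
  n <- min(6L, length(x$id))
  w <- min(60L, aln_width(x))
  for (k in seq_len(n))
    cat(format(x$id[k], width = 14), substr(x$seqs[k], 1, w),
        if (aln_width(x) > w) "..." else "", "\n")
  if (length(x$id) > n) cat("... (", length(x$id) - n, " more rows)\n", sep = "")
  invisible(x)
}

#' Alignment dimensions
#' @param aln An `aa_alignment`.
#' @return `aln_width`: number of columns; `aln_nrow`: number of rows.
#' @export
aln_width <- function(aln) nchar(aln$seqs[1])

#' @rdname aln_width
#' @export
aln_nrow <- function(aln) length(aln$id)

#' Alignment as a character matrix (rows x columns)
#' @param aln An `aa_alignment`.
#' @return Character matrix with row names set to row ids.
#' @export
aln_matrix <- function(aln) {
  mat <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(mat) <- aln$id
  mat
}

aln_row_index <- function(aln, seq_id) {
  k <- match(seq_id, aln$id)
  if (is.na(k)) stop("unknown seq_id '", seq_id, "'")
  k
}

#' Slice alignment columns or rows
#'
#' Subsets without renormalizing (all-gap columns are kept so that
#' coordinates remain interpretable against the parent alignment).
#'
#' @param aln An `aa_alignment`.
#' @param rows Row ids or indices (default all).
#' @param cols Column index vector (default all).
#' @return A new `aa_alignment`.
#' @export
aln_slice <- function(aln, rows = NULL, cols = NULL) {
  if (is.null(rows)) rows <- seq_along(aln$id)
  if (is.character(rows)) rows <- vapply(rows, aln_row_index, 1L, aln = aln)
  if (is.null(cols)) cols <- seq_len(aln_width(aln))
  mat <- aln_matrix(aln)[rows, cols, drop = FALSE]
  structure(list(id = aln$id[rows], species = aln$species[rows],
                 homolog_group = aln$homolog_group[rows],
                 seqs = unname(apply(mat, 1L, paste, collapse = ""))),
            class = "aa_alignment")
}

# ---------------------------------------------------------------------------
# I/O

parse_fasta_header <- function(name) {
  name <- sub("\\s.*$", "", name)
  parts <- strsplit(name, "|", fixed = TRUE)[[1]]
  list(id = parts[1],
       species = if (length(parts) >= 2 && nzchar(parts[2])) parts[2] else NA_character_,
       group = if (length(parts) >= 3 && nzchar(parts[3])) parts[3] else NA_character_)
}

apply_sidecar <- function(ids, species, group, meta) {
  if (is.null(meta)) return(list(species = species, group = group))
  if (is.character(meta)) meta <- utils::read.delim(meta, stringsAsFactors = FALSE)
  need <- c("id", "species")
  if (!all(need %in% names(meta)))
    stop("sidecar metadata must have columns id, species[, homolog_group]")
  k <- match(ids, meta$id)
  hit <- !is.na(k)
  species[hit] <- meta$species[k[hit]]
  if ("homolog_group" %in% names(meta)) group[hit] <- meta$homolog_group[k[hit]]
  list(species = species, group = group)
}

#' Read a protein multiple sequence alignment
#'
#' Reads aligned FASTA or Clustal files into an `aa_alignment`.  FASTA
#' headers are parsed with the `id|species|homolog_group` convention (both
#' metadata fields optional); a sidecar TSV with columns
#' `id, species, homolog_group` overrides header-derived labels.  The
#' Clustal reader accepts CLUSTAL, CLUSTAL W and CLUSTAL X (2.1) header
#' lines and ignores conservation lines.  After parsing, gaps are
#' normalized and all-gap columns removed.
#'
#' @param path File path.
#' @param format `"fasta"` or `"clustal"`.
#' @param meta Optional sidecar metadata: a TSV path or a data frame.
#' @return An `aa_alignment`.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal"), meta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("no sequences in ", path)
    hdr <- lapply(names(set), parse_fasta_header)
    ids <- vapply(hdr, `[[`, "", "id")
    species <- vapply(hdr, `[[`, "", "species")
    group <- vapply(hdr, `[[`, "", "group")
    seqs <- as.character(set)
  } else {
    parsed <- parse_clustal(path)
    ids <- parsed$ids
    seqs <- parsed$seqs
    hdr <- lapply(ids, parse_fasta_header)
    ids <- vapply(hdr, `[[`, "", "id")
    species <- vapply(hdr, `[[`, "", "species")
    group <- vapply(hdr, `[[`, "", "group")
  }
  sc <- apply_sidecar(ids, species, group, meta)
  aa_alignment(ids, seqs, sc$species, sc$group)
}

parse_clustal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^CLUSTAL", lines[1], ignore.case = TRUE))
    stop("not a Clustal file (missing CLUSTAL header): ", path)
  body <- lines[-1]
  ids <- character()
  chunks <- list()
  for (ln in body) {
    if (!nzchar(trimws(ln))) next
    # conservation lines contain only space, '*', ':', '.'
    if (grepl("^[ *:.]+$", ln)) next
    m <- regmatches(ln, regexec("^(\\S+)\\s+(\\S+)(\\s+\\d+)?\\s*$", ln))[[1]]
    if (length(m) == 0L) stop("unparseable Clustal line: '", ln, "'")
    id <- m[2]
    seg <- m[3]
    if (is.null(chunks[[id]])) {
      ids <- c(ids, id)
      chunks[[id]] <- seg
    } else chunks[[id]] <- paste0(chunks[[id]], seg)
  }
  if (length(ids) == 0L) stop("no sequences in Clustal file: ", path)
  list(ids = ids, seqs = unname(unlist(chunks[ids])))
}

fasta_name <- function(aln, k) {
  nm <- aln$id[k]
  sp <- aln$species[k]
  gr <- aln$homolog_group[k]
  if (!is.na(sp) || !is.na(gr))
    nm <- paste0(nm, "|", ifelse(is.na(sp), "", sp))
  if (!is.na(gr)) nm <- paste0(nm, "|", gr)
  nm
}

#' Write a protein multiple sequence alignment
#'
#' Writes aligned FASTA (wrapped at `width` columns) or Clustal.  Species
#' and homolog-group labels are encoded in the sequence names with the
#' `id|species|homolog_group` convention, so a write/read cycle preserves
#' row metadata exactly.
#'
#' @param aln An `aa_alignment`.
#' @param path Output file path.
#' @param format `"fasta"` or `"clustal"`.
#' @param width Line width for sequence blocks (default 60).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "clustal"),
                            width = 60L) {
  format <- match.arg(format)
  if (!inherits(aln, "aa_alignment") || length(aln$id) == 0L)
    stop("nothing to write: not a non-empty aa_alignment")
  names <- vapply(seq_along(aln$id), function(k) fasta_name(aln, k), "")
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "fasta") {
    for (k in seq_along(aln$id)) {
      writeLines(paste0(">", names[k]), con)
      s <- aln$seqs[k]
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    }
  } else {
    writeLines("CLUSTAL multiple sequence alignment", con)
    writeLines("", con)
    wname <- max(nchar(names)) + 4L
    starts <- seq(1L, aln_width(aln), by = width)
    for (s0 in starts) {
      for (k in seq_along(aln$id)) {
        seg <- substr(aln$seqs[k], s0, min(s0 + width - 1L, aln_width(aln)))
        writeLines(paste0(formatC(names[k], width = -wname), seg), con)
      }
      writeLines("", con)
    }
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Coordinate arithmetic

#' Map alignment columns to ungapped residue positions
#'
#' For a given row, returns the 1-based residue position corresponding to
#' each alignment column (the count of non-gap characters up to and
#' including the column), or `NA` where the cell is a gap.
#'
#' @param aln An `aa_alignment`.
#' @param seq_id Row identifier.
#' @param column 1-based column index (vectorized).
#' @return Integer vector; `NA` marks gap cells.
#' @export
column_to_residue <- function(aln, seq_id, column) {
  k <- aln_row_index(aln, seq_id)
  column <- as.integer(column)
  if (any(column < 1L | column > aln_width(aln)))
    stop("column out of range [1, ", aln_width(aln), "]")
  cells <- strsplit(aln$seqs[k], "", fixed = TRUE)[[1]]
  pos <- cumsum(cells != "-")
  out <- pos[column]
  out[cells[column] == "-"] <- NA_integer_
  out
}

#' Map ungapped residue positions to alignment columns
#'
#' Inverse of [column_to_residue()] on non-gap cells.
#'
#' @param aln An `aa_alignment`.
#' @param seq_id Row identifier.
#' @param residue 1-based residue position on the ungapped row (vectorized).
#' @return Integer vector of 1-based columns.
#' @export
residue_to_column <- function(aln, seq_id, residue) {
  k <- aln_row_index(aln, seq_id)
  residue <- as.integer(residue)
  cells <- strsplit(aln$seqs[k], "", fixed = TRUE)[[1]]
  cols <- which(cells != "-")
  if (any(residue < 1L | residue > length(cols)))
    stop("residue out of range [1, ", length(cols), "] for row '", seq_id, "'")
  cols[residue]
}

#' Ungapped sequence of a row
#' @param aln An `aa_alignment`.
#' @param seq_id Row identifier.
#' @return Ungapped character string.
#' @export
ungapped <- function(aln, seq_id) {
  k <- aln_row_index(aln, seq_id)
  gsub("-", "", aln$seqs[k], fixed = TRUE)
}

#' Region on an ungapped reference sequence
#'
#' A `region_spec` records a 1-based inclusive residue range on the
#' ungapped reference row, the coordinate system used for reported
#' signature-window positions.
#'
#' @param seq_id Reference row id.
#' @param start,end 1-based inclusive residue positions, `start <= end`.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(seq_id, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start)
    stop("invalid region: require 1 <= start <= end")
  structure(list(seq_id = seq_id, start = start, end = end),
            class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat("region ", x$start, "-", x$end, " on ", x$seq_id, "\n", sep = "")
  invisible(x)
}

#' @export
format.region_spec <- function(x, ...) paste0(x$start, "-", x$end)
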