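# Single-copy family selection, supermatrix concatenation, and
# gap-fraction column trimming.
#
# Families arrive as a precomputed membership table (e.g. from a
# sequence-identity clustering tool); this module only applies the
# coverage rule, concatenates per-family alignments genome-wise, and
# removes gap-heavy columns with a simple documented fraction rule.

#' Read a family membership table
#'
#' TSV with columns `family_id`, `genome`, `sequence_id`; one row per
#' family member.
#'
#' @param path TSV file path.
#' @return A `family_table` data frame.
#' @export
read_family_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("family_id", "genome", "sequence_id")
  if (!all(need %in% names(df)))
    stop("family table must have columns ", paste(need, collapse = ", "))
  class(df) <- c("family_table", "data.frame")
  df
}

#' Select single-copy families by genome coverage
#'
#' A genome counts toward a family only when it contributes exactly one
#' member; genomes with duplicated members are disqualified from that
#' family (and reported).  Families present single-copy in at least
#' `ceiling(min_fraction * |roster|)` genomes are retained.
#'
#' @param table A `family_table` data frame.
#' @param min_fraction Minimum single-copy genome coverage (default 0.8).
#' @param roster Genome roster; default all genomes in the table.
#' @return Character vector of retained `family_id`s, with attribute
#'   `disqualified` (data frame of family/genome pairs dropped for
#'   duplication).
#' @export
select_families <- function(table, min_fraction = 0.8, roster = NULL) {
  if (is.null(roster)) roster <- unique(table$genome)
  if (length(roster) == 0L) stop("empty genome roster")
  table <- table[table$genome %in% roster, , drop = FALSE]
  counts <- stats::aggregate(sequence_id ~ family_id + genome, table, length)
  dup <- counts[counts$sequence_id > 1L, c("family_id", "genome")]
  if (nrow(dup) > 0L)
    message(nrow(dup), " genome membership(s) disqualified for duplication")
  single <- counts[counts$sequence_id == 1L, , drop = FALSE]
  need <- ceiling(min_fraction * length(roster))
  cov <- table(single$family_id)
  keep <- names(cov)[cov >= need]
  keep <- sort(keep)
  attr(keep, "disqualified") <- dup
  keep
}

#' Concatenate per-family alignments into a supermatrix
#'
#' Rows are keyed by genome (each family alignment must have at most one
#' row per genome, with the genome name as the row id or species label).
#' Genomes missing from a family are padded with gaps across that
#' family's block.  The partition map records each family's column
#' interval.
#'
#' @param per_family Named list of `aa_alignment`s (names = family ids).
#' @param roster Genome roster; default the union of genomes seen.
#' @return List with `alignment` (an `aa_alignment`, one row per roster
#'   genome, not renormalized) and `partition` (data frame `family`,
#'   `start`, `end`).
#' @export
concatenate_alignments <- function(per_family, roster = NULL) {
  if (length(per_family) == 0L) stop("no family alignments supplied")
  genome_of <- function(aln) ifelse(is.na(aln$species), aln$id, aln$species)
  if (is.null(roster))
    roster <- unique(unlist(lapply(per_family, genome_of)))
  parts <- data.frame(family = names(per_family), start = NA_integer_,
                      end = NA_integer_, stringsAsFactors = FALSE)
  chunks <- matrix("", nrow = length(roster), ncol = length(per_family))
  at <- 1L
  for (f in seq_along(per_family)) {
    aln <- per_family[[f]]
    g <- genome_of(aln)
    if (anyDuplicated(g))
      stop("family '", names(per_family)[f],
           "' has more than one row for genome ",
           g[duplicated(g)][1])
    w <- aln_width(aln)
    pad <- strrep("-", w)
    k <- match(roster, g)
    chunks[, f] <- ifelse(is.na(k), pad, aln$seqs[k])
    parts$start[f] <- at
    parts$end[f] <- at + w - 1L
    at <- at + w
  }
  seqs <- apply(chunks, 1L, paste, collapse = "")
  aln <- aa_alignment(roster, seqs, species = roster, normalize = FALSE)
  list(alignment = aln, partition = parts)
}

#' Remove gap-heavy columns
#'
#' Drops every column whose gap fraction exceeds `max_gap_fraction`.
#' Idempotent: trimming a trimmed alignment removes nothing further.
#'
#' @param aln An `aa_alignment`.
#' @param max_gap_fraction Maximum tolerated gap fraction (default 0.5;
#'   columns strictly above it are removed).
#' @return The trimmed `aa_alignment`, with attribute `removed` (the
#'   removed column indices in input coordinates).
#' @export
trim_columns <- function(aln, max_gap_fraction = 0.5) {
  mat <- aln_matrix(aln)
  frac <- colSums(mat == "-") / nrow(mat)
  drop <- which(frac > max_gap_fraction)
  out <- if (length(drop) > 0L)
    aln_slice(aln, cols = setdiff(seq_len(ncol(mat)), drop))
  else aln
  attr(out, "removed") <- drop
  out
}

#' Write a supermatrix in relaxed PHYLIP format
#' @param aln An `aa_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(length(aln$id), aln_width(aln)), con)
  wname <- max(nchar(aln$id)) + 2L
  writeLines(paste0(formatC(aln$id, width = -wname), aln$seqs), con)
  invisible(path)
}

#' Write a RAxML-style partition file
#' @param partition Partition data frame from [concatenate_alignments()].
#' @param path Output path.
#' @param model Substitution model tag per partition (default `"AUTO"`).
#' @return `path`, invisibly.
#' @export
write_partition_file <- function(partition, path, model = "AUTO") {
  writeLines(sprintf("%s, %s = %d-%d", model, partition$family,
                     partition$start, partition$end), path)
  invisible(path)
}
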