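# Candidate indel scanning and the flank-conservation rule.
#
# A candidate indel is a maximal run of "mixed" alignment columns (columns
# containing both residues and gaps) in which the rows split into a
# residue-carrying side and a gap side.  Rows gapped over only part of the
# run make the candidate non-uniform instead of splitting it: signature
# indels must have one specific length.

#' Flank-conservation parameters
#'
#' Controls the rule that a candidate indel must be flanked on both sides
#' by conserved alignment columns: at least `min_conserved` conserved
#' columns within the nearest `window` majority-non-gap columns on each
#' side.  A column counts as conserved when the modal non-ambiguous
#' residue is shared by at least `conservation_fraction` of its non-gap
#' rows and fewer than half of the rows are gapped.  Candidates closer
#' than `max_edge_distance` columns to an alignment terminus are excluded
#' as likely terminal-extension artifacts.
#'
#' @param window Columns examined on each side of the indel (40-50;
#'   default 45).
#' @param min_conserved Conserved columns required per side (default 4).
#' @param conservation_fraction Minimum fraction of non-gap rows sharing
#'   the modal residue (default 0.8).
#' @param max_edge_distance Minimum columns between an indel and either
#'   alignment terminus (default 20).
#' @return An object of class `flank_params`.
#' @export
flank_params <- function(window = 45L, min_conserved = 4L,
                         conservation_fraction = 0.8,
                         max_edge_distance = 20L) {
  window <- as.integer(window)
  min_conserved <- as.integer(min_conserved)
  if (window < 40L || window > 50L)
    stop("`window` must lie in [40, 50]")
  if (min_conserved < 1L) stop("`min_conserved` must be >= 1")
  if (conservation_fraction <= 0 || conservation_fraction > 1)
    stop("`conservation_fraction` must lie in (0, 1]")
  structure(list(window = window, min_conserved = min_conserved,
                 conservation_fraction = conservation_fraction,
                 max_edge_distance = as.integer(max_edge_distance)),
            class = "flank_params")
}

#' Scan an alignment for candidate indels
#'
#' Finds every maximal run of consecutive mixed columns (columns with at
#' least one residue and at least one gap).  Within a run, rows carrying
#' residues at every column are the residue side (`bearers`), rows gapped
#' at every column are the gap side, and rows gapped over part of the run
#' mark the candidate as non-uniform (`uniform_length = FALSE`).  Runs
#' lacking a full-residue or full-gap row are not candidates.  Runs within
#' `max_edge_distance` columns of either terminus are excluded and
#' reported in the `excluded` attribute.  Candidates whose residue or gap
#' side is a single row are flagged `"singleton"` (single-sequence indels
#' are often artifacts).
#'
#' @param aln An `aa_alignment` with at least 4 rows.
#' @param params A [flank_params()] object.
#' @return List of `candidate_indel` objects ordered by start column, with
#'   attribute `excluded` (edge-proximal spans).  Each candidate has
#'   fields `span` (first/last column), `length`, `bearers` (residue-side
#'   ids, sorted), `gap_rows`, `partial_rows`, `uniform_length`, `flags`.
#' @export
scan_candidate_indels <- function(aln, params = flank_params()) {
  mat <- aln_matrix(aln)
  # rows with no residues at all carry no gap-pattern signal; they are
  # treated as absent homologs (reported as missing by the specificity
  # call) rather than allowed to mark every column as mixed
  informative <- rowSums(mat != "-") > 0L
  mat <- mat[informative, , drop = FALSE]
  ids <- aln$id[informative]
  if (nrow(mat) < 4L)
    stop("alignment must have at least 4 informative rows to scan for ",
         "candidate indels")
  gap <- mat == "-"
  ngap <- colSums(gap)
  mixed <- ngap > 0L & ngap < nrow(mat)
  if (!any(mixed)) {
    out <- list()
    attr(out, "excluded") <- list()
    return(out)
  }
  r <- rle(mixed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts, ends)[r$values, , drop = FALSE]
  out <- list()
  excluded <- list()
  w <- ncol(mat)
  for (i in seq_len(nrow(runs))) {
    s <- unname(runs[i, 1]); e <- unname(runs[i, 2])
    block <- gap[, s:e, drop = FALSE]
    ng <- rowSums(block)
    full_res <- which(ng == 0L)
    full_gap <- which(ng == e - s + 1L)
    partial <- which(ng > 0L & ng < e - s + 1L)
    if (length(full_res) == 0L || length(full_gap) == 0L) next
    cand <- structure(list(
      span = c(s, e),
      length = e - s + 1L,
      bearers = sort(ids[full_res]),
      gap_rows = sort(ids[full_gap]),
      partial_rows = sort(ids[partial]),
      uniform_length = length(partial) == 0L,
      flags = character()), class = "candidate_indel")
    if (length(full_res) == 1L || length(full_gap) == 1L)
      cand$flags <- c(cand$flags, "singleton")
    if (s - 1L < params$max_edge_distance || w - e < params$max_edge_distance) {
      excluded <- c(excluded, list(cand))
      next
    }
    out <- c(out, list(cand))
  }
  if (length(excluded) > 0L)
    message(length(excluded), " candidate(s) excluded within ",
            params$max_edge_distance, " columns of an alignment terminus")
  attr(out, "excluded") <- excluded
  out
}

#' @export
print.candidate_indel <- function(x, ...) {
  cat("candidate indel: columns ", x$span[1], "-", x$span[2],
      " (length ", x$length, "), ", length(x$bearers), " residue row(s) vs ",
      length(x$gap_rows), " gap row(s)",
      if (!x$uniform_length) " [non-uniform]" else "",
      if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else "",
      "\n", sep = "")
  invisible(x)
}

# conserved-column test for a column vector of residues (gaps as "-")
column_is_conserved <- function(cells, conservation_fraction) {
  n <- length(cells)
  nongap <- cells[cells != "-"]
  if (2L * (n - length(nongap)) >= n) return(FALSE)  # gapped in >= half the rows
  plain <- nongap[!nongap %in% AA_AMBIGUOUS]
  if (length(plain) == 0L) return(FALSE)
  tab <- table(plain)
  max(tab) >= conservation_fraction * length(nongap)
}

#' Assess flank conservation around a candidate indel
#'
#' Walks outward from each edge of the candidate's column span over up to
#' `params$window` columns that are non-gap in the majority of rows
#' (majority-gap columns are skipped and do not consume the window), and
#' counts conserved columns on each side.  The candidate passes when both
#' counts reach `params$min_conserved`.
#'
#' @param aln The alignment the candidate was scanned from.
#' @param cand A `candidate_indel`.
#' @param params A [flank_params()] object.
#' @return A `flank_assessment`: `left_conserved`, `right_conserved`,
#'   `left_examined`, `right_examined`, `passed`.
#' @export
assess_flanks <- function(aln, cand, params = flank_params()) {
  w <- aln_width(aln)
  if (cand$span[1] < 1L || cand$span[2] > w)
    stop("candidate span lies outside the alignment")
  mat <- aln_matrix(aln)
  mat <- mat[rowSums(mat != "-") > 0L, , drop = FALSE]  # as in the scan
  n <- nrow(mat)
  majority_nongap <- colSums(mat == "-") * 2L < n
  side_count <- function(cols) {
    cols <- cols[majority_nongap[cols]]
    cols <- utils::head(cols, params$window)
    examined <- length(cols)
    conserved <- sum(vapply(cols, function(j)
      column_is_conserved(mat[, j], params$conservation_fraction), TRUE))
    c(conserved = conserved, examined = examined)
  }
  left <- side_count(rev(seq_len(cand$span[1] - 1L)))
  right <- side_count(seq(cand$span[2] + 1L, length.out = w - cand$span[2]))
  structure(list(
    left_conserved = unname(left["conserved"]),
    right_conserved = unname(right["conserved"]),
    left_examined = unname(left["examined"]),
    right_examined = unname(right["examined"]),
    passed = left["conserved"] >= params$min_conserved &&
      right["conserved"] >= params$min_conserved),
    class = "flank_assessment")
}

#' @export
print.flank_assessment <- function(x, ...) {
  cat("flanks: left ", x$left_conserved, "/", x$left_examined,
      " conserved, right ", x$right_conserved, "/", x$right_examined,
      " -> ", if (x$passed) "PASS" else "FAIL", "\n", sep = "")
  invisible(x)
}

#' Extract the signature window around a candidate indel
#'
#' Slices the alignment to the candidate indel plus `flank_residues`
#' residues of the reference row on each side, and reports the window as a
#' [region_spec()] in ungapped reference coordinates (the "indel position"
#' range used in signature tables).  The window is truncated (and flagged)
#' when the reference terminus is closer than the requested flank.
#'
#' @param aln The alignment the candidate was scanned from.
#' @param cand A `candidate_indel`.
#' @param flank_residues Reference residues to include per side (default 45).
#' @param ref_id Reference row id; default the first residue-side bearer.
#' @return List with `window` (an `aa_alignment` slice, all-gap columns
#'   retained), `region` (a `region_spec`), `indel_cols` (the candidate's
#'   column span inside the window), `indel_region` (reference residue
#'   span of the indel block, for insertions), `truncated` flag.
#' @export
extract_signature_region <- function(aln, cand, flank_residues = 45L,
                                     ref_id = NULL) {
  if (is.null(ref_id)) ref_id <- cand$bearers[1]
  k <- aln_row_index(aln, ref_id)
  len <- nchar(ungapped(aln, ref_id))
  r1 <- column_to_residue(aln, ref_id, cand$span[1])
  r2 <- column_to_residue(aln, ref_id, cand$span[2])
  if (is.na(r1) || is.na(r2))
    stop("reference row '", ref_id, "' is gapped inside the candidate block; ",
         "choose a residue-side reference")
  start <- max(1L, r1 - as.integer(flank_residues))
  end <- min(len, r2 + as.integer(flank_residues))
  truncated <- (r1 - start) < flank_residues || (end - r2) < flank_residues
  c1 <- residue_to_column(aln, ref_id, start)
  c2 <- residue_to_column(aln, ref_id, end)
  window <- aln_slice(aln, cols = c1:c2)
  # per-row residue offset of the first window column, for display
  mat <- aln_matrix(aln)
  row_start <- vapply(seq_len(nrow(mat)), function(i) {
    before <- sum(mat[i, seq_len(c1 - 1L)] != "-")
    before + 1L
  }, 1L)
  names(row_start) <- aln$id
  attr(window, "row_start") <- row_start
  list(window = window,
       region = region_spec(ref_id, start, end),
       indel_cols = cand$span - c1 + 1L,
       indel_region = c(r1, r2),
       truncated = truncated)
}

#' Validate a candidate into a CSI record
#'
#' A candidate becomes a conserved signature indel record only when its
#' length is uniform across bearers, its flanks pass the conservation
#' rule, and its specificity call resolved to a named clade.  Otherwise a
#' rejection listing every failed criterion is returned.
#'
#' @param cand A `candidate_indel`.
#' @param flanks Its [assess_flanks()] result.
#' @param spec Its [evaluate_specificity()] result.
#' @param meta Named list of labels: `protein_name`, `gene_name`,
#'   `accession` (all optional).
#' @param polarity Optional [polarize_indel()] result; determines whether
#'   the record reads "ins" or "del" ("indel" when unpolarized).
#' @param region Optional `region_spec` from [extract_signature_region()].
#' @param window_block Optional residue span of the block inside the
#'   signature window (used by the homolog screen).
#' @return A `csi_record`, or a `csi_rejection` with a `reasons` field.
#' @export
call_csi <- function(cand, flanks, spec, meta = list(), polarity = NULL,
                     region = NULL, window_block = NULL) {
  reasons <- character()
  if (!isTRUE(cand$uniform_length)) reasons <- c(reasons, "non-uniform length")
  if (!isTRUE(flanks$passed)) reasons <- c(reasons, "flank conservation")
  if (is.null(spec$clade) || identical(spec$clade, "none"))
    reasons <- c(reasons, "no clade specificity")
  if (length(reasons) > 0L)
    return(structure(list(span = cand$span, reasons = reasons),
                     class = "csi_rejection"))
  type <- if (is.null(polarity)) "indel"
  else switch(polarity$state, insertion = "ins", deletion = "del", "indel")
  flags <- cand$flags
  if (isTRUE(spec$paralog_restricted)) flags <- c(flags, "paralog-restricted")
  structure(list(
    protein_name = meta$protein_name %||% NA_character_,
    gene_name = meta$gene_name %||% NA_character_,
    accession = meta$accession %||% NA_character_,
    indel_size = cand$length,
    indel_type = type,
    region = region,
    window_block = window_block,
    specificity = spec,
    bearers = cand$bearers,
    span = cand$span,
    flags = flags), class = "csi_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.csi_record <- function(x, ...) {
  cat("CSI: ", x$indel_size, " aa ", x$indel_type,
      if (!is.null(x$region)) paste0(" at ", format(x$region)) else "",
      ", specific for ", x$specificity$clade, "\n", sep = "")
  if (length(x$specificity$exceptions))
    cat("  exceptions: ", paste(x$specificity$exceptions, collapse = ", "), "\n")
  if (length(x$flags)) cat("  flags: ", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.csi_rejection <- function(x, ...) {
  cat("rejected candidate (columns ", x$span[1], "-", x$span[2], "): ",
      paste(x$reasons, collapse = "; "), "\n", sep = "")
  invisible(x)
}
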