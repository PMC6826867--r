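# Homolog screening: BLAST tabular input, hit filtering, a semi-global
# affine-gap aligner, and per-hit indel presence/absence calls.
#
# The aligner is semi-global: the signature window is aligned end to end
# against the best-matching substring of the hit (end gaps on the hit are
# free), with BLOSUM62 scoring and BLAST-style affine gap costs (a gap of
# length k costs gap_open + k * gap_extend, i.e. -11 - k at defaults).

blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

#' Read a BLAST tabular hit list (outfmt 6)
#'
#' Parses the standard 12-column tab-separated BLAST output
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`); extra trailing columns are ignored.
#'
#' @param path TSV file path (no header line).
#' @return A data frame with the 12 standard columns.
#' @export
read_blast_tab <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12L) stop("expected >= 12 tab-separated columns (outfmt 6)")
  df <- df[, 1:12]
  names(df) <- cols
  df
}

#' Assemble hit records from a BLAST table and hit sequences
#'
#' Joins the tabular hits (by `sseqid`) with their unaligned sequences,
#' read from a FASTA whose headers follow the `id|species` convention.
#'
#' @param blast Data frame from [read_blast_tab()].
#' @param fasta Path to the hit FASTA, or a named character vector of
#'   sequences.
#' @return A `hit_records` data frame: `hit_id`, `species`, `e_value`,
#'   `sequence`.
#' @export
hit_records <- function(blast, fasta) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    set <- Biostrings::readBStringSet(fasta)
    hdr <- lapply(names(set), parse_fasta_header)
    seqs <- stats::setNames(as.character(set), vapply(hdr, `[[`, "", "id"))
    species <- stats::setNames(vapply(hdr, `[[`, "", "species"),
                               vapply(hdr, `[[`, "", "id"))
  } else {
    seqs <- fasta
    species <- stats::setNames(rep(NA_character_, length(fasta)), names(fasta))
  }
  k <- match(blast$sseqid, names(seqs))
  if (anyNA(k))
    stop("hit sequence(s) missing from FASTA: ",
         paste(utils::head(blast$sseqid[is.na(k)], 5), collapse = ", "))
  out <- data.frame(hit_id = blast$sseqid, species = unname(species[k]),
                    e_value = blast$evalue, sequence = toupper(unname(seqs[k])),
                    stringsAsFactors = FALSE)
  class(out) <- c("hit_records", "data.frame")
  out
}

#' Filter and rank homolog hits
#'
#' Retains hits with E-value strictly below `e_max`, sorts them ascending
#' by E-value (ties broken by `hit_id`), and truncates to the top `top_n`.
#' The screening depth is capped at 500.
#'
#' @param hits A `hit_records` data frame (or any data frame with
#'   `e_value` and `hit_id` columns).
#' @param e_max E-value cutoff, exclusive (default 1e-20).
#' @param top_n Maximum hits retained (default 250; hard cap 500).
#' @return The filtered, ordered data frame.
#' @export
filter_hits <- function(hits, e_max = 1e-20, top_n = 250L) {
  top_n <- as.integer(top_n)
  if (top_n > 500L) {
    warning("screening depth capped at 500 hits")
    top_n <- 500L
  }
  if (nrow(hits) == 0L) return(hits)
  keep <- hits[hits$e_value < e_max, , drop = FALSE]
  keep <- keep[order(keep$e_value, keep$hit_id), , drop = FALSE]
  utils::head(keep, top_n)
}

# ---------------------------------------------------------------------------
# Pairwise aligner (Gotoh three-state DP, vectorized by row)

NEG_INF <- -1e18

#' Align a signature window against a homolog hit
#'
#' Affine-gap dynamic programming.  In `"semiglobal"` mode (the default)
#' the whole window must align while leading/trailing residues of the hit
#' are free, matching the geometry of a short signature window against a
#' full-length homolog; `"global"` mode penalizes end gaps on both
#' sequences.  A gap of length k costs `gap_open + k * gap_extend`.
#' Traceback ties prefer a substitution over opening a gap, and extend
#' gaps leftward, so the output is deterministic.
#'
#' @param window_seq Ungapped reference window (character string).
#' @param hit_seq Ungapped hit sequence.
#' @param matrix Substitution matrix name (`"BLOSUM62"`) or a numeric
#'   matrix with residue dimnames.
#' @param gap_open Gap opening cost (default -11).
#' @param gap_extend Per-residue gap extension cost (default -1).
#' @param mode `"semiglobal"` or `"global"`.
#' @return A `pairwise_alignment`: `score`, gapped strings `window_aln`
#'   and `hit_aln`, and `hit_start`/`hit_end` (1-based aligned span of
#'   the hit; semiglobal mode only).
#' @export
align_signature <- function(window_seq, hit_seq, matrix = "BLOSUM62",
                            gap_open = -11, gap_extend = -1,
                            mode = c("semiglobal", "global")) {
  mode <- match.arg(mode)
  sub <- if (is.character(matrix)) {
    if (!identical(matrix, "BLOSUM62"))
      stop("unknown substitution matrix: ", matrix)
    blosum62()
  } else matrix
  a <- strsplit(toupper(window_seq), "")[[1]]
  b <- strsplit(toupper(hit_seq), "")[[1]]
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) stop("sequences must be non-empty")
  bad <- setdiff(c(a, b), rownames(sub))
  if (length(bad) > 0L)
    stop("residue(s) not in substitution matrix: ", paste(bad, collapse = ", "))
  go <- gap_open; ge <- gap_extend
  # S[i, j] = substitution score for a[i] vs b[j]
  S <- sub[a, b, drop = FALSE]
  M <- matrix(NEG_INF, n + 1L, m + 1L)  # ends in a[i]~b[j] pair
  X <- matrix(NEG_INF, n + 1L, m + 1L)  # ends in gap in window (consumes b[j])
  Y <- matrix(NEG_INF, n + 1L, m + 1L)  # ends in gap in hit    (consumes a[i])
  M[1, ] <- if (mode == "semiglobal") 0 else c(0, rep(NEG_INF, m))
  if (mode == "global" && m > 0L) X[1, 2:(m + 1L)] <- go + ge * seq_len(m)
  for (i in seq_len(n)) {
    r <- i + 1L
    prevM <- M[r - 1L, ]; prevX <- X[r - 1L, ]; prevY <- Y[r - 1L, ]
    best_prev <- pmax(prevM, prevX, prevY)
    M[r, 2:(m + 1L)] <- S[i, ] + best_prev[1:m]
    Y[r, ] <- pmax(prevM + go + ge, prevY + ge)
    # X along the row: X[r, j] = ge*j + max_{k < j} (M[r, k+1] + go - ge*k)
    Mi <- M[r, ]
    A <- Mi + go - ge * (0:m)
    X[r, 2:(m + 1L)] <- ge * seq_len(m) + cummax(A[1:m])
  }
  if (mode == "semiglobal") {
    fin <- pmax(M[n + 1L, ], Y[n + 1L, ])
    jend <- which.max(fin) - 1L  # which.max returns first (leftmost) maximum
    score <- fin[jend + 1L]
  } else {
    fin <- max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
    jend <- m
    score <- fin
  }
  # traceback (all scores are integer-valued, so equality tests are exact)
  i <- n; j <- jend
  state <- if (mode == "semiglobal") {
    if (M[n + 1L, j + 1L] >= Y[n + 1L, j + 1L]) "M" else "Y"
  } else {
    vals <- c(M = M[n + 1L, m + 1L], Y = Y[n + 1L, m + 1L],
              X = X[n + 1L, m + 1L])
    names(vals)[which.max(vals)]
  }
  done <- function(i, j) i == 0L && (mode == "semiglobal" || j == 0L)
  wa <- character(); ha <- character()
  while (!done(i, j)) {
    r <- i + 1L; c <- j + 1L
    if (state == "M") {
      wa <- c(a[i], wa); ha <- c(b[j], ha)
      i <- i - 1L; j <- j - 1L
      if (done(i, j)) break
      prev <- c(M = M[i + 1L, j + 1L], Y = Y[i + 1L, j + 1L],
                X = X[i + 1L, j + 1L])
      state <- names(prev)[which.max(prev)]  # ties prefer substitution
    } else if (state == "Y") {
      wa <- c(a[i], wa); ha <- c("-", ha)
      prev <- c(Y = Y[r - 1L, c] + ge, M = M[r - 1L, c] + go + ge)
      i <- i - 1L
      state <- names(prev)[which.max(prev)]  # ties extend the gap leftward
    } else {
      wa <- c("-", wa); ha <- c(b[j], ha)
      prev <- c(X = X[r, c - 1L] + ge, M = M[r, c - 1L] + go + ge)
      j <- j - 1L
      state <- names(prev)[which.max(prev)]
    }
  }
  hit_start <- j + 1L
  structure(list(score = unname(score),
                 window_aln = paste(wa, collapse = ""),
                 hit_aln = paste(ha, collapse = ""),
                 hit_start = if (mode == "semiglobal") hit_start else 1L,
                 hit_end = if (mode == "semiglobal") jend else m,
                 mode = mode,
                 gap_open = go, gap_extend = ge), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("pairwise alignment (", x$mode, "), score ", x$score, "\n",
      "  window: ", x$window_aln, "\n  hit:    ", x$hit_aln, "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Per-hit classification

#' Classify a hit's indel state against a CSI
#'
#' Inspects the aligned signature window (reference carries residues
#' across the indel block) and decides whether the hit shows the residue
#' state, the gap state, or neither.  The gap state requires one
#' contiguous gap of exactly the CSI length covering the block within
#' `slack` columns; partial or mis-sized gaps, blocks straddled by gap
#' edges, or flank identity below `flank_floor` yield `ambiguous`.  The
#' state is then mapped through the CSI's polarity: for an insertion the
#' residue state means `has_indel`; for a deletion the gap state does.
#'
#' @param pa A `pairwise_alignment` of the window against the hit.
#' @param csi A `csi_record` (uses `window_block` and `indel_type`).
#' @param slack Positional tolerance in columns (default 3).
#' @param flank_floor Minimum identity over the window flanks (default 0.3).
#' @return One of `"has_indel"`, `"lacks_indel"`, `"ambiguous"`.
#' @export
classify_hit <- function(pa, csi, slack = 3L, flank_floor = 0.3) {
  block <- csi$window_block
  if (is.null(block)) stop("csi record lacks `window_block`")
  wa <- strsplit(pa$window_aln, "")[[1]]
  ha <- strsplit(pa$hit_aln, "")[[1]]
  wpos <- cumsum(wa != "-")
  in_block <- wa != "-" & wpos >= block[1] & wpos <= block[2]
  blen <- block[2] - block[1] + 1L
  if (sum(in_block) != blen) return("ambiguous")  # coverage is partial
  # flank identity over window residues outside the block
  flank <- wa != "-" & !in_block
  ident <- sum(wa[flank] == ha[flank] & ha[flank] != "-")
  if (sum(flank) == 0L || ident / sum(flank) < flank_floor) return("ambiguous")
  hit_gap <- ha == "-"
  state <- if (!any(hit_gap[in_block])) {
    "residue"
  } else if (all(hit_gap[in_block])) {
    # the covering gap run must be contiguous, exactly blen long, and
    # positioned within slack of the block
    runs <- rle(hit_gap)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    bcols <- which(in_block)
    k <- which(runs$values & starts <= bcols[1] & ends >= bcols[length(bcols)])
    if (length(k) != 1L || runs$lengths[k] != blen) "straddle"
    else if (abs(starts[k] - bcols[1]) > slack) "straddle"
    else "gap"
  } else "straddle"
  if (state == "straddle") return("ambiguous")
  if (csi$indel_type == "del") {
    if (state == "gap") "has_indel" else "lacks_indel"
  } else {
    if (state == "residue") "has_indel" else "lacks_indel"
  }
}

#' Screen a homolog hit set against a CSI
#'
#' Filters the hits, aligns each retained hit to the signature window,
#' classifies its indel state, and summarizes: the verdict is
#' `"uniquely shared"` when every in-clade hit with a definite call has
#' the indel and no out-of-clade hit does, `"not specific"` otherwise,
#' and `"insufficient data"` when no hits survive filtering.  Hits whose
#' species is unknown count as out-of-clade for the verdict.
#'
#' @param csi A `csi_record`.
#' @param window_seq Ungapped reference signature window string.
#' @param hits A `hit_records` data frame.
#' @param tax Optional `clade_taxonomy` used to resolve in-clade species
#'   (default: bearers listed in the CSI's specificity call).
#' @param e_max,top_n Passed to [filter_hits()].
#' @param slack,flank_floor Passed to [classify_hit()].
#' @param ... Passed to [align_signature()].
#' @return A `screen_result`: per-hit data frame (`hit_id`, `species`,
#'   `e_value`, `score`, `call`, `in_clade`), `counts`, `verdict`,
#'   `intruders`.
#' @export
screen_hits <- function(csi, window_seq, hits, tax = NULL,
                        e_max = 1e-20, top_n = 250L,
                        slack = 3L, flank_floor = 0.3, ...) {
  kept <- filter_hits(hits, e_max = e_max, top_n = top_n)
  clade_sp <- if (!is.null(tax) && csi$specificity$clade != "none")
    clade_species(tax, csi$specificity$clade)
  else csi$specificity$bearers
  if (nrow(kept) == 0L) {
    return(structure(list(
      hits = cbind(kept, score = numeric(0), call = character(0),
                   in_clade = logical(0)),
      counts = c(has_indel = 0L, lacks_indel = 0L, ambiguous = 0L),
      verdict = "insufficient data", intruders = character()),
      class = "screen_result"))
  }
  calls <- character(nrow(kept))
  scores <- numeric(nrow(kept))
  for (k in seq_len(nrow(kept))) {
    pa <- align_signature(window_seq, kept$sequence[k], ...)
    scores[k] <- pa$score
    calls[k] <- classify_hit(pa, csi, slack = slack, flank_floor = flank_floor)
  }
  in_clade <- !is.na(kept$species) & kept$species %in% clade_sp
  counts <- c(has_indel = sum(calls == "has_indel"),
              lacks_indel = sum(calls == "lacks_indel"),
              ambiguous = sum(calls == "ambiguous"))
  intruders <- kept$hit_id[!in_clade & calls == "has_indel"]
  ok <- length(intruders) == 0L &&
    !any(in_clade & calls == "lacks_indel")
  df <- data.frame(hit_id = kept$hit_id, species = kept$species,
                   e_value = kept$e_value, score = scores, call = calls,
                   in_clade = in_clade, stringsAsFactors = FALSE)
  structure(list(hits = df, counts = counts,
                 verdict = if (ok) "uniquely shared" else "not specific",
                 intruders = intruders), class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen: ", nrow(x$hits), " hit(s); has=", x$counts["has_indel"],
      " lacks=", x$counts["lacks_indel"], " ambiguous=",
      x$counts["ambiguous"], "; verdict: ", x$verdict, "\n", sep = "")
  if (length(x$intruders))
    cat("  intruders:", paste(x$intruders, collapse = ", "), "\n")
  invisible(x)
}
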