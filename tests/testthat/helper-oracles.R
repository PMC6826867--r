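# Independent oracles and fixture builders used across the test files.

make_aln <- function(seqs, ids = NULL, species = NULL, group = NULL) {
  if (is.null(ids)) ids <- paste0("r", seq_along(seqs))
  if (is.null(species)) species <- paste0("sp", seq_along(seqs))
  suppressMessages(aa_alignment(ids, seqs, species = species,
                                homolog_group = group))
}

# Random gapped alignment with no all-gap columns.  Gap structure mixes
# iid gaps with short shared gap blocks so that candidate indels of
# various bearer sets arise.
random_alignment <- function(n_rows, n_cols, gap_prob = 0.08,
                             block_prob = 0.35) {
  mat <- matrix(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                       n_rows * n_cols, replace = TRUE),
                nrow = n_rows)
  gaps <- matrix(runif(n_rows * n_cols) < gap_prob, nrow = n_rows)
  if (runif(1) < block_prob && n_cols > 10) {
    len <- sample(1:4, 1)
    at <- sample(seq(2, n_cols - len - 1), 1)
    rows <- sample(n_rows, sample(seq_len(n_rows - 1), 1))
    gaps[rows, at:(at + len - 1)] <- TRUE
  }
  # keep at least one residue per column
  for (j in which(colSums(!gaps) == 0)) gaps[sample(n_rows, 1), j] <- FALSE
  mat[gaps] <- "-"
  make_aln(apply(mat, 1, paste, collapse = ""))
}

# Brute-force candidate-indel enumerator: tests every column interval for
# the run conditions and every row bipartition for uniformity.
oracle_scan <- function(aln, params = flank_params()) {
  mat <- aln_matrix(aln)
  ids <- aln$id[rowSums(mat != "-") > 0]
  mat <- mat[rowSums(mat != "-") > 0, , drop = FALSE]
  n <- nrow(mat); w <- ncol(mat)
  gap <- mat == "-"
  mixed <- vapply(seq_len(w), function(j) any(gap[, j]) && !all(gap[, j]), TRUE)
  out <- list()
  for (i in seq_len(w)) {
    if (!mixed[i]) next
    for (j in i:w) {
    if (!mixed[j]) break
    if (i > 1 && mixed[i - 1]) next
    if (j < w && mixed[j + 1]) next
    block <- gap[, i:j, drop = FALSE]
    full_res <- which(rowSums(block) == 0)
    full_gap <- which(rowSums(block) == j - i + 1)
    if (length(full_res) == 0 || length(full_gap) == 0) next
    # uniformity via explicit bipartition search
    uniform <- FALSE
    for (msk in seq_len(2^n - 2)) {
      S <- which(bitwAnd(msk, 2^(seq_len(n) - 1)) > 0)
      if (all(rowSums(block[S, , drop = FALSE]) == 0) &&
          all(rowSums(block[-S, , drop = FALSE]) == j - i + 1)) {
        uniform <- TRUE
        break
      }
    }
    if (i - 1 < params$max_edge_distance || w - j < params$max_edge_distance)
      next
    out[[length(out) + 1]] <- list(
      span = c(i, j), length = j - i + 1L,
      bearers = sort(ids[full_res]), gap_rows = sort(ids[full_gap]),
      uniform_length = uniform)
    }
  }
  out
}

cand_essence <- function(x) lapply(x, function(c)
  list(span = c$span, length = c$length, bearers = c$bearers,
       gap_rows = c$gap_rows, uniform_length = c$uniform_length))

# Exhaustive affine-gap alignment enumerator.  Recursion over alignment
# moves; leading/trailing hit residues are free in semiglobal mode.
oracle_align_score <- function(a, b, gap_open = -11, gap_extend = -1,
                               mode = "semiglobal") {
  sub <- local({
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  n <- length(av); m <- length(bv)
  best <- -Inf
  rec <- function(i, j, score, last) {
    if (i == n) {
      if (mode == "semiglobal") {
        best <<- max(best, score)
        return(invisible(NULL))
      }
      if (j == m) {
        best <<- max(best, score)
        return(invisible(NULL))
      }
      # global: consume the rest of the hit as a gap in the window
      cost <- gap_extend * (m - j) + if (last == "X") 0 else gap_open
      best <<- max(best, score + cost)
      return(invisible(NULL))
    }
    if (j < m)
      rec(i + 1, j + 1, score + sub[av[i + 1], bv[j + 1]], "M")
    rec(i + 1, j, score + gap_extend + if (last == "Y") 0 else gap_open, "Y")
    if (j < m)
      rec(i, j + 1, score + gap_extend + if (last == "X") 0 else gap_open, "X")
  }
  starts <- if (mode == "semiglobal") 0:m else 0
  for (j0 in starts) rec(0, j0, 0, "S")
  best
}

# LCA oracle by ancestor-set intersection (independent of the prefix-walk
# implementation).
oracle_lca <- function(tax, species) {
  sets <- lapply(tax$lineages[species], unique)
  common <- Reduce(intersect, sets)
  if (length(common) == 0) return(NA_character_)
  depths <- vapply(common, function(cl) match(cl, tax$lineages[[species[1]]]), 1L)
  common[which.max(depths)]
}

random_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}
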