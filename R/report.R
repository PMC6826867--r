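# Presentation artifacts: dash-identity alignment blocks, signature
# tables, and per-CSI signature bundle files.
#
# Dash-identity notation: the top (reference) row is printed verbatim;
# in every other row a dash marks identity with the top residue, a letter
# marks a difference, and a space marks a gap (so identity dashes and gap
# symbols cannot collide).  All coordinates printed are 1-based inclusive.

#' Format a signature window in dash-identity notation
#'
#' Renders an alignment window as fixed-width text lines: a label column,
#' the starting residue coordinate of each row, the dash-identity
#' sequence, and the ending residue coordinate.  The indel block can be
#' delimited with `|` box markers.  Row coordinates honour the
#' `row_start` attribute set by [extract_signature_region()] so that
#' positions refer to the full-length protein.
#'
#' @param window An `aa_alignment` (typically a signature window).
#' @param top_id Reference row rendered verbatim (default the first row).
#' @param box Optional column span `c(first, last)` to box.
#' @return Character vector of lines, class `signature_block`, with
#'   attributes `label_width`, `coord_width`, `box`, `top_id` used by
#'   [decode_signature()].
#' @export
format_signature <- function(window, top_id = NULL, box = NULL) {
  if (is.null(top_id)) top_id <- window$id[1]
  k <- aln_row_index(window, top_id)
  ord <- c(k, setdiff(seq_along(window$id), k))
  mat <- aln_matrix(window)[ord, , drop = FALSE]
  w <- ncol(mat)
  if (!is.null(box)) {
    box <- as.integer(box)
    if (box[1] < 1L || box[2] > w || box[1] > box[2])
      stop("box span lies outside the window")
  }
  ids <- window$id[ord]
  sp <- window$species[ord]
  labels <- ifelse(is.na(sp) | sp == ids, ids, paste0(ids, " ", sp))
  row_start <- attr(window, "row_start")
  starts <- if (is.null(row_start)) rep(1L, length(ord)) else
    unname(row_start[window$id[ord]])
  nres <- rowSums(mat != "-")
  ends <- starts + pmax(nres - 1L, 0L)
  top <- mat[1, ]
  render <- function(i) {
    cells <- mat[i, ]
    out <- cells
    if (i == 1L) {
      out[cells == "-"] <- " "
    } else {
      out[cells == top & cells != "-" & top != "-"] <- "-"
      out[cells == "-"] <- " "
    }
    if (!is.null(box)) {
      out <- append(out, "|", after = box[2])
      out <- append(out, "|", after = box[1] - 1L)
    }
    paste(out, collapse = "")
  }
  lw <- max(nchar(labels)) + 2L
  cw <- max(nchar(c(starts, ends))) + 1L
  lines <- vapply(seq_along(ord), function(i)
    paste0(formatC(labels[i], width = -lw),
           formatC(starts[i], width = cw), " ", render(i), " ",
           formatC(ends[i], width = -cw)), "")
  structure(lines, class = "signature_block", label_width = lw,
            coord_width = cw, box = box, top_id = top_id,
            ids = ids, species = sp)
}

#' @export
print.signature_block <- function(x, ...) {
  cat(x, sep = "\n")
  invisible(x)
}

#' Decode a dash-identity block back into an alignment
#'
#' Inverse of [format_signature()]: reconstructs the window rows from the
#' rendered lines using the layout attributes carried on the block.
#'
#' @param block A `signature_block`.
#' @return An `aa_alignment` with the original row order restored.
#' @export
decode_signature <- function(block) {
  lw <- attr(block, "label_width")
  cw <- attr(block, "coord_width")
  box <- attr(block, "box")
  ids <- attr(block, "ids")
  sp <- attr(block, "species")
  seq_start <- lw + cw + 2L
  body <- vapply(block, function(ln) {
    s <- substr(ln, seq_start, nchar(ln))
    sub("\\s+\\S+\\s*$", "", s)  # strip trailing end coordinate
  }, "", USE.NAMES = FALSE)
  strip_box <- function(s) {
    if (is.null(box)) return(s)
    cells <- strsplit(s, "")[[1]][-c(box[1], box[2] + 2L)]
    paste(cells, collapse = "")
  }
  body <- vapply(body, strip_box, "", USE.NAMES = FALSE)
  w <- max(nchar(body))
  body <- formatC(body, width = -w)  # restore trailing gaps lost to trimming
  top <- strsplit(body[1], "")[[1]]
  top[top == " "] <- "-"
  rows <- list(paste(top, collapse = ""))
  for (i in seq_along(body)[-1]) {
    cells <- strsplit(body[i], "")[[1]]
    cells[cells == "-"] <- top[cells == "-"]
    cells[cells == " "] <- "-"
    rows[[i]] <- paste(cells, collapse = "")
  }
  aa_alignment(ids, unlist(rows), species = sp, normalize = FALSE)
}

# ---------------------------------------------------------------------------
# Table export

csi_row <- function(rec) {
  data.frame(
    protein_name = rec$protein_name %||% NA_character_,
    gene_name = rec$gene_name %||% NA_character_,
    accession = rec$accession %||% NA_character_,
    indel = paste0(rec$indel_size, " aa ", rec$indel_type),
    position = if (is.null(rec$region)) NA_character_ else format(rec$region),
    specificity = rec$specificity$clade,
    exceptions = paste(rec$specificity$exceptions, collapse = ","),
    flags = paste(rec$flags, collapse = ","),
    stringsAsFactors = FALSE)
}

#' Export CSI records as a signature table
#'
#' One row per record with columns `protein_name`, `gene_name`,
#' `accession`, `indel` (e.g. `"5 aa ins"`), `position` (e.g.
#' `"411-454"`, ASCII hyphen), `specificity`, `exceptions`, `flags`.
#' Rows are ordered by specificity rank (deepest clade first, i.e. most
#' specific groups lead) and then by gene name; duplicate
#' (accession, position) pairs are rejected.
#'
#' @param records List of `csi_record` objects.
#' @param path Output TSV path (optional; omit to just get the data
#'   frame).
#' @return The table as a data frame, invisibly when written.
#' @export
export_csi_table <- function(records, path = NULL) {
  if (length(records) == 0L) {
    df <- csi_row(structure(list(
      indel_size = 1L, indel_type = "ins",
      specificity = list(clade = "", exceptions = character()),
      flags = character()), class = "csi_record"))[0, ]
  } else {
    df <- do.call(rbind, lapply(records, csi_row))
    key <- paste(df$accession, df$position)
    if (anyDuplicated(key[!is.na(df$accession)]))
      stop("duplicate (accession, position) row(s): ",
           paste(unique(key[duplicated(key)]), collapse = "; "))
    depth <- vapply(records, function(r)
      as.numeric(r$specificity$depth %||% NA_real_), 1)
    depth[is.na(depth)] <- 0L
    ord <- order(-depth, df$gene_name, df$position)
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
  }
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    return(invisible(df))
  }
  df
}

#' Read a signature table written by [export_csi_table()]
#' @param path TSV path.
#' @return Data frame with the table columns.
#' @export
read_csi_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = NULL)
}

# ---------------------------------------------------------------------------
# Signature bundle files

#' Write a self-contained signature file for one CSI
#'
#' The bundle holds a YAML metadata block (protein/gene/accession labels,
#' indel size and polarity, window region, specificity call, flags, and
#' any simulation truth attached in benchmark mode), the dash-identity
#' alignment block, and the homolog-screen summary, separated by `---`
#' fences so the file parses back losslessly.
#'
#' @param csi A `csi_record`.
#' @param window Optional `signature_block` (or an `aa_alignment`, which
#'   is formatted with the box at the CSI columns).
#' @param screen Optional `screen_result`.
#' @param path Output path.
#' @param truth Optional named list of planted-truth metadata.
#' @return `path`, invisibly.
#' @export
write_signature_file <- function(csi, window = NULL, screen = NULL, path,
                                 truth = NULL) {
  meta <- list(
    format = "csindel-signature/1",
    protein_name = csi$protein_name,
    gene_name = csi$gene_name,
    accession = csi$accession,
    indel_size = csi$indel_size,
    indel_type = csi$indel_type,
    position = if (is.null(csi$region)) NULL else format(csi$region),
    reference = if (is.null(csi$region)) NULL else csi$region$seq_id,
    specificity = list(
      clade = csi$specificity$clade,
      bearers = as.list(csi$specificity$bearers),
      exceptions = as.list(csi$specificity$exceptions),
      intruders = as.list(csi$specificity$intruders),
      missing = as.list(csi$specificity$missing)),
    flags = as.list(csi$flags))
  if (!is.null(truth)) meta$truth <- truth
  lines <- c("---", strsplit(yaml::as.yaml(meta), "\n")[[1]], "---")
  if (!is.null(window)) {
    if (inherits(window, "aa_alignment"))
      window <- format_signature(window)
    lines <- c(lines, "# alignment", unclass(window), "---")
  }
  if (!is.null(screen)) {
    lines <- c(lines, "# screen",
               paste0("hits\t", nrow(screen$hits)),
               paste0("has_indel\t", screen$counts["has_indel"]),
               paste0("lacks_indel\t", screen$counts["lacks_indel"]),
               paste0("ambiguous\t", screen$counts["ambiguous"]),
               paste0("verdict\t", screen$verdict), "---")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Parse a signature file written by [write_signature_file()]
#' @param path File path.
#' @return List with `meta` (named list), `alignment` (character lines or
#'   `NULL`), `screen` (named character vector or `NULL`).
#' @export
read_signature_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fences <- which(lines == "---")
  if (length(fences) < 2L || fences[1] != 1L)
    stop("not a signature file (missing YAML fences): ", path)
  meta <- yaml::yaml.load(paste(lines[(fences[1] + 1L):(fences[2] - 1L)],
                                collapse = "\n"))
  sections <- list(alignment = NULL, screen = NULL)
  k <- 2L
  while (k < length(fences)) {
    body <- lines[(fences[k] + 1L):(fences[k + 1L] - 1L)]
    if (length(body) > 0L && body[1] == "# alignment")
      sections$alignment <- body[-1]
    if (length(body) > 0L && body[1] == "# screen") {
      kv <- strsplit(body[-1], "\t", fixed = TRUE)
      sections$screen <- stats::setNames(
        vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
    }
    k <- k + 1L
  }
  list(meta = meta, alignment = sections$alignment, screen = sections$screen)
}
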