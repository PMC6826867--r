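# Named-clade taxonomy, specificity calls, and indel polarization.
#
# The taxonomy is user-supplied (lineage table or newick with internal
# labels); the package never infers a tree.  Each species maps to an
# ordered clade path from the root, e.g.
# Nematoda > Chromadorea > Rhabditoidea > Caenorhabditis > C_elegans.
# Outgroup species (used only to polarize indels) are declared with the
# reserved lineage token "outgroup" rather than edited into the tree.

OUTGROUP_TOKEN <- "outgroup"

#' Construct a named-clade taxonomy
#'
#' @param lineages Named list: for each species, the character vector of
#'   named clades from the root down (the species name itself is not part
#'   of the path).
#' @param outgroups Character vector of declared outgroup species (not
#'   part of the focal taxonomy; used for indel polarization).
#' @return An object of class `clade_taxonomy`.
#' @export
clade_taxonomy <- function(lineages, outgroups = character()) {
  if (length(lineages) > 0L && anyDuplicated(names(lineages)))
    stop("duplicate species in taxonomy")
  if (any(names(lineages) %in% outgroups))
    stop("species cannot be both in the taxonomy and declared outgroup")
  # every named clade must map to one node: lineages containing a clade
  # must agree on the path down to it
  all_names <- unique(unlist(lineages))
  for (cl in all_names) {
    paths <- lapply(lineages, function(p) {
      k <- match(cl, p)
      if (is.na(k)) NULL else p[seq_len(k)]
    })
    paths <- paths[!vapply(paths, is.null, TRUE)]
    if (length(unique(paths)) > 1L)
      stop("clade '", cl, "' maps to more than one node")
  }
  structure(list(lineages = lineages, outgroups = as.character(outgroups)),
            class = "clade_taxonomy")
}

#' @export
print.clade_taxonomy <- function(x, ...) {
  cat("clade_taxonomy: ", length(x$lineages), " species, ",
      length(unique(unlist(x$lineages))), " named clades, ",
      length(x$outgroups), " declared outgroup(s)\n", sep = "")
  invisible(x)
}

#' Read a taxonomy from a lineage table
#'
#' The table is a TSV with columns `species` and `lineage`, where
#' `lineage` is the comma-separated clade path from the root (e.g.
#' `Nematoda,Chromadorea,Rhabditoidea,Caenorhabditis`).  A lineage equal
#' to the reserved token `outgroup` declares the species an outgroup.
#'
#' @param path TSV file path.
#' @return A `clade_taxonomy`.
#' @export
read_lineage_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("species", "lineage") %in% names(df)))
    stop("lineage table must have columns species, lineage")
  out <- trimws(df$lineage) == OUTGROUP_TOKEN
  lineages <- lapply(df$lineage[!out], function(s) trimws(strsplit(s, ",")[[1]]))
  names(lineages) <- df$species[!out]
  clade_taxonomy(lineages, outgroups = df$species[out])
}

#' Write a taxonomy as a lineage table
#' @param tax A `clade_taxonomy`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_lineage_table <- function(tax, path) {
  df <- data.frame(
    species = c(names(tax$lineages), tax$outgroups),
    lineage = c(vapply(tax$lineages, paste, "", collapse = ","),
                rep(OUTGROUP_TOKEN, length(tax$outgroups))),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy from a newick tree with internal node labels
#'
#' Tip labels become species; labelled internal nodes become named clades
#' on the lineage path of every descendant tip (unlabelled internal nodes
#' are anonymous and skipped).  Tips descending from an internal node
#' labelled `outgroup` are declared outgroups.
#'
#' @param path Newick file path, or `text =` a newick string.
#' @param text Optional newick string instead of a file.
#' @return A `clade_taxonomy`.
#' @export
taxonomy_from_newick <- function(path = NULL, text = NULL) {
  tree <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse newick input")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  labels <- tree$node.label
  lineages <- list()
  outgroups <- character()
  for (i in seq_len(ntip)) {
    nodes <- ape::nodepath(tree, from = root, to = i)
    inner <- nodes[nodes > ntip]
    lab <- labels[inner - ntip]
    lab <- lab[!is.na(lab) & nzchar(lab)]
    if (OUTGROUP_TOKEN %in% lab) {
      outgroups <- c(outgroups, tree$tip.label[i])
    } else {
      lineages[[tree$tip.label[i]]] <- lab
    }
  }
  clade_taxonomy(lineages, outgroups)
}

#' Species belonging to a named clade
#' @param tax A `clade_taxonomy`.
#' @param clade Clade name.
#' @return Character vector of species.
#' @export
clade_species <- function(tax, clade) {
  hits <- vapply(tax$lineages, function(p) clade %in% p, TRUE)
  names(tax$lineages)[hits]
}

#' Depth of a named clade (1 = root)
#' @param tax A `clade_taxonomy`.
#' @param clade Clade name.
#' @return Integer depth, or `NA` if the clade is unknown.
#' @export
clade_depth <- function(tax, clade) {
  for (p in tax$lineages) {
    k <- match(clade, p)
    if (!is.na(k)) return(k)
  }
  NA_integer_
}

#' Smallest named clade containing a species set
#'
#' Computes the longest common prefix of the species' lineage paths; the
#' last element is the deepest named clade containing them all.
#'
#' @param tax A `clade_taxonomy`.
#' @param species Character vector of species (must resolve in the
#'   taxonomy).
#' @return Clade name, or `NA` when the species share no named clade.
#' @export
smallest_clade <- function(tax, species) {
  species <- unique(species)
  miss <- setdiff(species, names(tax$lineages))
  if (length(miss) > 0L)
    stop("species not in taxonomy: ", paste(miss, collapse = ", "))
  if (length(species) == 0L) return(NA_character_)
  paths <- tax$lineages[species]
  prefix <- paths[[1]]
  for (p in paths[-1]) {
    k <- 0L
    while (k < min(length(prefix), length(p)) && prefix[k + 1L] == p[k + 1L])
      k <- k + 1L
    prefix <- prefix[seq_len(k)]
    if (k == 0L) return(NA_character_)
  }
  prefix[length(prefix)]
}

# ---------------------------------------------------------------------------
# Specificity

resolve_species <- function(species, tax) {
  known <- species %in% names(tax$lineages) | species %in% tax$outgroups
  if (!all(known))
    stop("species not resolvable in taxonomy (and not a declared outgroup): ",
         paste(unique(species[!known]), collapse = ", "))
  invisible(TRUE)
}

# rows all-gap across [s-window, e+window] are missing data
missing_rows <- function(aln, span, window) {
  w <- aln_width(aln)
  cols <- max(1L, span[1] - window):min(w, span[2] + window)
  mat <- aln_matrix(aln)[, cols, drop = FALSE]
  aln$id[rowSums(mat != "-") == 0L]
}

side_call <- function(tax, bearer_sp, other_sp, tolerance, allow_exceptions) {
  in_tax <- intersect(bearer_sp, names(tax$lineages))
  out_carriers <- intersect(bearer_sp, tax$outgroups)
  if (length(in_tax) == 0L)
    return(list(ok = FALSE, clade = "none", exceptions = character(),
                intruders = out_carriers))
  clade <- smallest_clade(tax, in_tax)
  if (is.na(clade))
    return(list(ok = FALSE, clade = "none", exceptions = character(),
                intruders = out_carriers))
  leaves <- clade_species(tax, clade)
  # intruders: carriers outside the clade (incl. outgroup carriers)
  intruders <- c(setdiff(in_tax, leaves), out_carriers)
  # exceptions: clade members scorable in the alignment but lacking the state
  exceptions <- intersect(other_sp, leaves)
  countable <- setdiff(exceptions, allow_exceptions)
  ok <- length(intruders) == 0L && length(countable) <= tolerance
  list(ok = ok, clade = if (ok) clade else "none",
       exceptions = sort(exceptions), intruders = sort(intruders),
       resolved_clade = clade)
}

#' Evaluate the taxonomic specificity of a candidate indel
#'
#' Determines the smallest named clade whose members exactly share the
#' candidate's indel state.  Evaluation is per homolog group: rows of
#' other groups are ignored, and the call is flagged paralog-restricted
#' when another group of a bearer species lacks the state.  Rows entirely
#' gapped across the signature window are "missing data" and are neither
#' bearers nor exceptions.  By default both character states are tried
#' (`side = "auto"`): the residue side first, then the gap side (for
#' deletion-type signatures the indel-bearing clade is the gapped side);
#' the first side yielding a clean call wins.
#'
#' @param cand A `candidate_indel`.
#' @param aln The alignment it was scanned from (rows must carry species
#'   labels resolvable in `tax` or declared as outgroups).
#' @param tax A `clade_taxonomy`.
#' @param tolerance Maximum number of in-clade species allowed to lack the
#'   state (default 0, strict uniqueness).
#' @param allow_exceptions Named species excluded from the tolerance count
#'   (documented exceptions).
#' @param side `"auto"`, `"residue"`, or `"gap"`.
#' @param group Homolog group to evaluate; default the group of the first
#'   residue-side bearer row (`NA` groups form their own group).
#' @param window Columns flanking the block used to decide missing data
#'   (default 45).
#' @return A `specificity_call`: `clade` (or `"none"`), `bearers`
#'   (species sharing the state), `exceptions`, `intruders`, `missing`,
#'   `side`, `depth`, `paralog_restricted`, `group`.
#' @export
evaluate_specificity <- function(cand, aln, tax, tolerance = 0L,
                                 allow_exceptions = character(),
                                 side = c("auto", "residue", "gap"),
                                 group = NULL, window = 45L) {
  side <- match.arg(side)
  resolve_species(aln$species, tax)
  grp <- aln$homolog_group
  grp[is.na(grp)] <- "__ungrouped__"
  if (is.null(group)) {
    k <- match(cand$bearers[1], aln$id)
    group <- grp[k]
  }
  focal <- aln$id[grp == group]
  miss <- intersect(missing_rows(aln, cand$span, window), focal)
  res_rows <- setdiff(intersect(cand$bearers, focal), miss)
  gap_rows <- setdiff(intersect(cand$gap_rows, focal), miss)
  sp_of <- function(ids) unique(aln$species[match(ids, aln$id)])
  res_sp <- sp_of(res_rows)
  gap_sp <- sp_of(gap_rows)
  tries <- switch(side, residue = "residue", gap = "gap",
                  auto = c("residue", "gap"))
  chosen <- NULL
  for (s in tries) {
    bearer_sp <- if (s == "residue") res_sp else gap_sp
    other_sp <- if (s == "residue") gap_sp else res_sp
    call <- side_call(tax, bearer_sp, setdiff(other_sp, bearer_sp),
                      tolerance, allow_exceptions)
    call$side <- s
    call$bearer_sp <- sort(bearer_sp)
    if (call$ok) { chosen <- call; break }
    if (is.null(chosen)) chosen <- call  # keep first side's diagnostics
  }
  # paralog restriction: another group of a bearer species lacks the state
  paralog <- FALSE
  other_groups <- setdiff(unique(grp), group)
  if (length(other_groups) > 0L && chosen$ok) {
    state_rows <- if (chosen$side == "residue") cand$bearers else cand$gap_rows
    for (og in other_groups) {
      og_ids <- aln$id[grp == og]
      og_sp <- sp_of(setdiff(og_ids, state_rows))
      if (length(intersect(og_sp, chosen$bearer_sp)) > 0L) paralog <- TRUE
    }
  }
  structure(list(
    clade = chosen$clade,
    bearers = chosen$bearer_sp,
    exceptions = chosen$exceptions,
    intruders = chosen$intruders,
    missing = sort(sp_of(miss)),
    side = chosen$side,
    depth = if (chosen$clade == "none") NA_integer_
            else clade_depth(tax, chosen$clade),
    paralog_restricted = paralog,
    group = group), class = "specificity_call")
}

#' @export
print.specificity_call <- function(x, ...) {
  cat("specificity: ", x$clade, " (", x$side, " side, ",
      length(x$bearers), " bearer species)\n", sep = "")
  if (length(x$exceptions)) cat("  exceptions:", paste(x$exceptions, collapse = ", "), "\n")
  if (length(x$intruders)) cat("  intruders:", paste(x$intruders, collapse = ", "), "\n")
  if (length(x$missing)) cat("  missing:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

#' Polarize an indel as insertion or deletion using outgroups
#'
#' An indel whose residue state is absent from every scorable outgroup row
#' is an insertion (the residues were gained on the bearer stem); one
#' whose residue state is present in every scorable outgroup is a deletion
#' in the gapped rows.  Outgroup rows entirely gapped across the
#' surrounding window are unscorable; rows gapped over part of the block
#' count as disagreement.  With no scorable outgroups, or disagreement
#' among them, the polarity is ambiguous.
#'
#' @param cand A `candidate_indel`.
#' @param aln The alignment it was scanned from.
#' @param outgroup_ids Row ids of the outgroup sequences.
#' @param window Columns used to decide scorability (default 45).
#' @return An `indel_polarity`: `state` in
#'   `{"insertion", "deletion", "ambiguous"}` and `outgroup_support`.
#' @export
polarize_indel <- function(cand, aln, outgroup_ids, window = 45L) {
  outgroup_ids <- intersect(outgroup_ids, aln$id)
  scorable <- setdiff(outgroup_ids, missing_rows(aln, cand$span, window))
  if (length(scorable) == 0L)
    return(structure(list(state = "ambiguous", outgroup_support = 0L),
                     class = "indel_polarity"))
  mat <- aln_matrix(aln)[match(scorable, aln$id),
                         cand$span[1]:cand$span[2], drop = FALSE]
  ng <- rowSums(mat == "-")
  width <- cand$span[2] - cand$span[1] + 1L
  state <- if (all(ng == width)) "insertion"
  else if (all(ng == 0L)) "deletion"
  else "ambiguous"
  structure(list(state = state, outgroup_support = length(scorable)),
            class = "indel_polarity")
}

#' @export
print.indel_polarity <- function(x, ...) {
  cat("polarity: ", x$state, " (", x$outgroup_support,
      " scorable outgroup row(s))\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Homolog groups

#' Partition sequences into homolog (paralog) groups
#'
#' When homolog-group labels are already present on the alignment they are
#' respected verbatim.  Otherwise sequences are clustered by
#' single-linkage on global pairwise identity (identical aligned residues
#' divided by alignment columns, computed with the package's affine-gap
#' aligner): pairs at or above `identity_threshold` join one group.
#'
#' @param aln An `aa_alignment` (gaps are stripped before alignment).
#' @param identity_threshold Single-linkage threshold (default 0.5).
#' @return The alignment with `homolog_group` filled in (`"g1"`, `"g2"`,
#'   ... in order of first appearance).
#' @export
partition_homolog_groups <- function(aln, identity_threshold = 0.5) {
  if (any(!is.na(aln$homolog_group))) return(aln)
  n <- length(aln$id)
  seqs <- vapply(aln$id, function(id) ungapped(aln, id), "")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    pa <- align_signature(seqs[i], seqs[j], mode = "global")
    a <- strsplit(pa$window_aln, "")[[1]]
    b <- strsplit(pa$hit_aln, "")[[1]]
    ident <- sum(a == b & a != "-") / length(a)
    if (ident >= identity_threshold) parent[find(j)] <- find(i)
  }
  roots <- vapply(seq_len(n), find, 1L)
  labels <- paste0("g", match(roots, unique(roots)))
  aln$homolog_group <- labels
  aln
}
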