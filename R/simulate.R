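# Clade-structured protein family simulator with planted signature
# indels and emitted ground truth.
#
# The simulator is the package's desk-scale stand-in for a genome-wide
# homolog scan: it generates families whose statistical regime matches
# what the detector assumes (highly conserved flank zones, one
# clade-fixed indel of exact length, background substitutions, optional
# lineage-specific indel noise and within-species paralogs), and emits
# the true alignment alongside the unaligned sequences so pipeline tests
# do not depend on an external aligner.
#
# Sequence evolution is deliberately simple: uniform random replacement
# at variable sites, with the branch length read as the per-site
# substitution probability on that branch.  Gap structure, not
# substitution realism, is what the detector consumes.

DEFAULT_TREE_NEWICK <- paste0(
  "(((((((C_elegans:0.02,C_briggsae:0.02):0.01,",
  "(C_remanei:0.02,C_brenneri:0.02):0.01):0.01,",
  "(C_japonica:0.03,C_sinica:0.03):0.01)Caenorhabditis:0.06,",
  "D_pachys:0.08)Rhabditoidea:0.05,",
  "(S_ratti:0.10,(A_ceylanicum:0.08,(B_malayi:0.08,A_suum:0.08):0.02):0.02)",
  ":0.02)Chromadorea:0.05,",
  "(T_spiralis:0.08,T_muris:0.08)Enoplea:0.06)Nematoda:0.04,",
  "(C_muris:0.12,(P_falciparum:0.12,(B_xinjiang:0.12,E_necatrix:0.12)",
  ":0.03):0.03)outgroup:0.04);")

#' Default simulation tree
#'
#' A 17-taxon tree with named clades mirroring the nested structure of a
#' nematode phylogeny: six Caenorhabditis species plus Diploscapter
#' (family Rhabditoidea) inside the class Chromadorea, two Enoplea
#' species, and four apicomplexan outgroups.  Branch lengths are read as
#' per-site substitution probabilities by the simulator.
#'
#' @return An `ape` `phylo` object with internal node labels.
#' @export
default_sim_tree <- function() ape::read.tree(text = DEFAULT_TREE_NEWICK)

#' Default named-clade taxonomy matching [default_sim_tree()]
#' @return A `clade_taxonomy` (outgroup tips declared as outgroups).
#' @export
default_taxonomy <- function() taxonomy_from_newick(text = DEFAULT_TREE_NEWICK)

#' Specify a family simulation
#'
#' @param tree A `phylo` tree with named clade labels (default
#'   [default_sim_tree()]); branch lengths are per-site substitution
#'   probabilities.
#' @param root_length Root sequence length in residues (default 400).
#' @param frozen_fraction Fraction of root sites that never substitute
#'   (default 0.25), in addition to the frozen flank zones around planted
#'   indels.
#' @param planted_csis List of planted signatures, each a list with
#'   `clade`, `length`, `type` (`"ins"`/`"del"`), `position` (root
#'   coordinate; an insertion goes between `position` and `position + 1`,
#'   a deletion removes `position .. position + length - 1`), and
#'   `flank_freeze_width` (default 10).
#' @param background_indel_rate Expected count of background indels per
#'   terminal branch (Poisson; default 0.03).  Background indels model
#'   lineage-specific gap noise: length 1-3, placed on terminal branches
#'   outside all frozen zones.
#' @param paralog_spec Optional list(`clade`, `divergence`): species of
#'   the clade contribute a second homolog (group `"g2"`) evolved from a
#'   diverged duplicate of the root, which never receives the planted
#'   indels.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(tree = default_sim_tree(), root_length = 400L,
                     frozen_fraction = 0.25, planted_csis = list(),
                     background_indel_rate = 0.03, paralog_spec = NULL,
                     seed = 1L) {
  root_length <- as.integer(root_length)
  if (frozen_fraction < 0 || frozen_fraction > 1)
    stop("`frozen_fraction` must lie in [0, 1]")
  edge_margin <- 20L
  zones <- list()
  planted_csis <- lapply(planted_csis, function(cs) {
    cs$flank_freeze_width <- as.integer(cs$flank_freeze_width %||% 10L)
    if (is.null(cs$clade) || is.null(cs$length) || is.null(cs$type) ||
        is.null(cs$position))
      stop("planted CSI needs clade, length, type, position")
    cs$length <- as.integer(cs$length)
    cs$position <- as.integer(cs$position)
    if (cs$length < 1L) stop("planted CSI length must be >= 1")
    if (!cs$type %in% c("ins", "del"))
      stop("planted CSI type must be 'ins' or 'del'")
    span <- if (cs$type == "ins") c(cs$position, cs$position + 1L)
    else c(cs$position, cs$position + cs$length - 1L)
    zone <- c(span[1] - cs$flank_freeze_width,
              span[2] + cs$flank_freeze_width)
    if (zone[1] <= edge_margin || zone[2] > root_length - edge_margin)
      stop("planted CSI at position ", cs$position,
           " is too close to a sequence terminus")
    for (z in zones) if (zone[1] <= z[2] && z[1] <= zone[2])
      stop("planted CSIs overlap each other's frozen zones")
    zones <<- c(zones, list(zone))
    cs
  })
  structure(list(tree = tree, root_length = root_length,
                 frozen_fraction = frozen_fraction,
                 planted_csis = planted_csis,
                 background_indel_rate = background_indel_rate,
                 paralog_spec = paralog_spec, seed = as.integer(seed)),
            class = "sim_spec")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

mutate_sites <- function(res, variable, prob) {
  if (prob <= 0) return(res)
  hit <- which(variable & stats::runif(length(res)) < prob)
  if (length(hit) > 0L) {
    for (k in hit) res[k] <- sample(setdiff(AA_RESIDUES, res[k]), 1L)
  }
  res
}

# find the node number of a named clade (tip or internal label)
clade_node <- function(tree, clade) {
  ntip <- length(tree$tip.label)
  k <- match(clade, tree$node.label)
  if (!is.na(k)) return(ntip + k)
  k <- match(clade, tree$tip.label)
  if (!is.na(k)) return(k)
  stop("clade '", clade, "' not found in tree labels")
}

#' Simulate one protein family with planted signature indels
#'
#' Draws a uniform-random root sequence, evolves it down the tree
#' (frozen sites never change), applies each planted indel on the stem
#' branch of its target clade, scatters background indels on terminal
#' branches outside frozen zones, and assembles the true alignment from
#' the global column registry.  Generation is a pure function of
#' `spec$seed`; the emitted truth is self-checked against the alignment.
#'
#' @param spec A [sim_spec()].
#' @return List with `alignment` (the true `aa_alignment`; row ids are
#'   species names, paralog rows suffixed `_p2`), `seqs` (named character
#'   vector of ungapped sequences), and `truth` (per-CSI list with
#'   `clade`, `length`, `type`, `position`, `bearer_species`,
#'   `column_span`; plus `rows`, a data frame of id/species/group/bearer
#'   flags).
#' @export
simulate_family <- function(spec) with_seed(spec$seed, {
  tree <- spec$tree
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  L <- spec$root_length
  root_res <- sample(AA_RESIDUES, L, replace = TRUE)
  frozen <- stats::runif(L) < spec$frozen_fraction
  for (cs in spec$planted_csis) {
    fw <- cs$flank_freeze_width
    span <- if (cs$type == "ins") c(cs$position, cs$position + 1L)
    else c(cs$position, cs$position + cs$length - 1L)
    frozen[max(1L, span[1] - fw):min(L, span[2] + fw)] <- TRUE
  }
  stems <- vapply(spec$planted_csis, function(cs)
    clade_node(tree, cs$clade), 1L)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  edge_len <- stats::setNames(tree$edge.length, tree$edge[, 2])
  event_counter <- 0L
  truth_cols <- vector("list", length(spec$planted_csis))
  tip_seqs <- list()

  is_frozen_key <- function(keys) {
    int <- keys == floor(keys)
    out <- rep(FALSE, length(keys))
    out[int] <- frozen[keys[int]]
    out
  }
  apply_insertion <- function(keys, res, pos, len) {
    event_counter <<- event_counter + 1L
    newk <- pos + (event_counter * 20L + seq_len(len)) * 1e-6
    at <- max(which(keys <= pos))
    list(keys = append(keys, newk, after = at),
         res = append(res, sample(AA_RESIDUES, len, replace = TRUE),
                      after = at),
         new_keys = newk)
  }
  apply_deletion <- function(keys, res, pos, len) {
    drop <- which(keys >= pos & keys <= pos + len - 1L)
    list(keys = keys[-drop], res = res[-drop],
         del_keys = keys[drop])
  }
  background_events <- function(keys, res) {
    n_ev <- stats::rpois(1L, spec$background_indel_rate)
    for (ev in seq_len(n_ev)) {
      len <- sample(1:3, 1L)
      if (stats::runif(1) < 0.5) {
        ok <- which(!is_frozen_key(keys) & keys == floor(keys))
        if (length(ok) == 0L) next
        pos <- keys[sample(ok, 1L)]
        ins <- apply_insertion(keys, res, pos, len)
        keys <- ins$keys; res <- ins$res
      } else {
        cand <- which(keys == floor(keys))
        cand <- cand[vapply(cand, function(k0) {
          span <- keys[k0] + 0:(len - 1L)
          all(span <= L) && !any(frozen[span])
        }, TRUE)]
        if (length(cand) == 0L) next
        pos <- keys[sample(cand, 1L)]
        del <- apply_deletion(keys, res, pos, len)
        keys <- del$keys; res <- del$res
      }
    }
    list(keys = keys, res = res)
  }
  descend <- function(node, keys, res, apply_events, suffix) {
    kids <- children[[as.character(node)]]
    if (is.null(kids)) {
      tip_seqs[[paste0(tree$tip.label[node], suffix)]] <<-
        list(keys = keys, res = res)
      return(invisible(NULL))
    }
    for (child in kids) {
      k2 <- keys; r2 <- res
      if (apply_events) {
        hit <- which(stems == child)
        for (h in hit) {
          cs <- spec$planted_csis[[h]]
          if (cs$type == "ins") {
            ins <- apply_insertion(k2, r2, cs$position, cs$length)
            k2 <- ins$keys; r2 <- ins$res
            truth_cols[[h]] <<- ins$new_keys
          } else {
            del <- apply_deletion(k2, r2, cs$position, cs$length)
            k2 <- del$keys; r2 <- del$res
            truth_cols[[h]] <<- del$del_keys
          }
        }
      }
      r2 <- mutate_sites(r2, !is_frozen_key(k2), edge_len[[as.character(child)]])
      if (child <= ntip && apply_events) {
        bg <- background_events(k2, r2)
        k2 <- bg$keys; r2 <- bg$res
      }
      descend(child, k2, r2, apply_events, suffix)
    }
  }
  descend(root, seq_len(L) + 0, root_res, TRUE, "")

  if (!is.null(spec$paralog_spec)) {
    pr <- spec$paralog_spec
    dup_res <- mutate_sites(root_res, !frozen, pr$divergence)
    descend(root, seq_len(L) + 0, dup_res, FALSE, "_p2")
    keep_sp <- clade_species(default_taxonomy_from_tree(tree), pr$clade)
    drop <- grepl("_p2$", names(tip_seqs)) &
      !sub("_p2$", "", names(tip_seqs)) %in% keep_sp
    tip_seqs <- tip_seqs[!drop]
  }

  all_keys <- sort(unique(unlist(lapply(tip_seqs, `[[`, "keys"))))
  rows <- vapply(tip_seqs, function(s) {
    cells <- rep("-", length(all_keys))
    cells[match(s$keys, all_keys)] <- s$res
    paste(cells, collapse = "")
  }, "")
  ids <- names(tip_seqs)
  species <- sub("_p2$", "", ids)
  has_paralog <- !is.null(spec$paralog_spec)
  group <- if (has_paralog) ifelse(grepl("_p2$", ids), "g2", "g1")
  else rep(NA_character_, length(ids))
  aln <- aa_alignment(ids, rows, species = species, homolog_group = group,
                      normalize = FALSE)
  tax <- default_taxonomy_from_tree(tree)
  truth <- list()
  for (h in seq_along(spec$planted_csis)) {
    cs <- spec$planted_csis[[h]]
    cols <- match(truth_cols[[h]], all_keys)
    bearer_sp <- clade_species(tax, cs$clade)
    truth[[h]] <- list(clade = cs$clade, length = cs$length, type = cs$type,
                       position = cs$position,
                       bearer_species = bearer_sp,
                       column_span = range(cols))
    # self-check: the emitted alignment must realize the planted truth
    mat <- aln_matrix(aln)[, cols, drop = FALSE]
    g1 <- if (has_paralog) group == "g1" else rep(TRUE, length(ids))
    carriers <- rowSums(mat != "-") == length(cols)
    expect_carrier <- g1 & species %in% bearer_sp
    if (cs$type == "del") expect_carrier <- g1 & !species %in% bearer_sp |
      !g1
    if (!identical(unname(carriers), unname(expect_carrier)))
      stop("simulator self-check failed: truth inconsistent with alignment")
  }
  rows_df <- data.frame(id = ids, species = species,
                        homolog_group = if (has_paralog) group else NA,
                        stringsAsFactors = FALSE)
  for (h in seq_along(truth))
    rows_df[[paste0("bearer_csi", h)]] <-
    rows_df$species %in% truth[[h]]$bearer_species &
    (if (has_paralog) rows_df$homolog_group == "g1" else TRUE)
  seqs <- vapply(ids, function(id) ungapped(aln, id), "")
  list(alignment = aln, seqs = seqs,
       truth = list(csis = truth, rows = rows_df))
})

# taxonomy derived from an arbitrary simulation tree (cached for default)
default_taxonomy_from_tree <- function(tree) {
  taxonomy_from_newick(text = ape::write.tree(tree))
}

#' Generate a synthetic homolog hit set for a signature window
#'
#' In-clade hits carry the indel state, out-of-clade hits lack it; both
#' are mutated at the given per-site divergence outside the frozen flank
#' zone around the block.  Synthetic E-values are monotone in each hit's
#' divergence.
#'
#' @param csi_window List with `seq` (residue-side window string),
#'   `block` (`c(start, end)` residue span of the indel inside the
#'   window), `type` (`"ins"`/`"del"`), `clade`, and optionally
#'   `freeze` (frozen flank width, default 10).
#' @param n_in_clade,n_out_clade Hit counts.
#' @param divergence Per-site substitution probability in [0, 0.5).
#' @param seed Integer seed.
#' @param tax Taxonomy used to draw hit species (default
#'   [default_taxonomy()]).
#' @return List with `hits` (a `hit_records` data frame) and `truth`
#'   (data frame `hit_id`, `species`, `bearer`).
#' @export
generate_hit_set <- function(csi_window, n_in_clade, n_out_clade,
                             divergence, seed = 1L,
                             tax = default_taxonomy()) {
  if (divergence < 0 || divergence >= 0.5)
    stop("`divergence` must lie in [0, 0.5)")
  with_seed(seed, {
    res <- strsplit(csi_window$seq, "")[[1]]
    blk <- csi_window$block
    fw <- csi_window$freeze %||% 10L
    frozen <- seq_along(res) >= blk[1] - fw & seq_along(res) <= blk[2] + fw
    without_block <- res[-(blk[1]:blk[2])]
    frozen_wo <- frozen[-(blk[1]:blk[2])]
    in_sp <- clade_species(tax, csi_window$clade)
    out_sp <- c(setdiff(names(tax$lineages), in_sp), tax$outgroups)
    n <- n_in_clade + n_out_clade
    if (n == 0L) {
      hits <- data.frame(hit_id = character(), species = character(),
                         e_value = numeric(), sequence = character(),
                         stringsAsFactors = FALSE)
      class(hits) <- c("hit_records", "data.frame")
      return(list(hits = hits,
                  truth = data.frame(hit_id = character(),
                                     species = character(),
                                     bearer = logical())))
    }
    bearer <- c(rep(TRUE, n_in_clade), rep(FALSE, n_out_clade))
    ids <- sprintf("hit%03d", seq_len(n))
    species <- character(n)
    species[bearer] <- rep_len(in_sp, n_in_clade)
    species[!bearer] <- rep_len(out_sp, n_out_clade)
    seqs <- character(n)
    evals <- numeric(n)
    for (k in seq_len(n)) {
      carries <- if (csi_window$type == "ins") bearer[k] else !bearer[k]
      base <- if (carries) res else without_block
      fz <- if (carries) frozen else frozen_wo
      d_k <- divergence * stats::runif(1, 0.9, 1.1)
      seqs[k] <- paste(mutate_sites(base, !fz, d_k), collapse = "")
      evals[k] <- 10^(-(160 - 250 * d_k))
    }
    blast <- data.frame(qseqid = "window", sseqid = ids, pident = NA,
                        length = nchar(seqs), mismatch = NA, gapopen = NA,
                        qstart = 1L, qend = nchar(csi_window$seq),
                        sstart = 1L, send = nchar(seqs), evalue = evals,
                        bitscore = NA, stringsAsFactors = FALSE,
                        row.names = NULL)
    hits <- hit_records(blast, stats::setNames(seqs, ids))
    hits$species <- species
    list(hits = hits,
         truth = data.frame(hit_id = ids, species = species, bearer = bearer,
                            stringsAsFactors = FALSE))
  })
}

#' Generate a benchmark suite of simulated families
#'
#' Simulates `n_families` independent families, a stated fraction of
#' which carry exactly one planted CSI with randomized clade, length,
#' type and position; the rest are null families.  Deterministic under
#' `seed`.  When `dir` is given, each family's unaligned FASTA and true
#' alignment are written there together with a `manifest.tsv`.
#'
#' @param n_families Number of families (default 100).
#' @param fraction_with_csi Fraction carrying one planted CSI (default
#'   0.2).
#' @param spec_template A [sim_spec()] supplying everything except the
#'   planted CSI and seed.
#' @param seed Master seed.
#' @param dir Optional output directory.
#' @return List with `manifest` (data frame: `family`, `has_csi`,
#'   `clade`, `length`, `type`, `position`, `seed`) and `cases` (list of
#'   [simulate_family()] results).
#' @export
make_benchmark_suite <- function(n_families = 100L, fraction_with_csi = 0.2,
                                 spec_template = sim_spec(), seed = 1L,
                                 dir = NULL) {
  n_families <- as.integer(n_families)
  n_csi <- round(n_families * fraction_with_csi)
  clades <- c("Caenorhabditis", "Rhabditoidea", "Chromadorea", "Nematoda",
              "Enoplea")
  L <- spec_template$root_length
  manifest <- data.frame(family = sprintf("family%03d", seq_len(n_families)),
                         has_csi = seq_len(n_families) <= n_csi,
                         clade = rep(NA_character_, n_families),
                         length = rep(NA_integer_, n_families),
                         type = rep(NA_character_, n_families),
                         position = rep(NA_integer_, n_families),
                         seed = rep(NA_integer_, n_families),
                         stringsAsFactors = FALSE)
  if (n_families == 0L) return(list(manifest = manifest, cases = list()))
  cases <- vector("list", n_families)
  with_seed(seed, {
    params <- data.frame(
      clade = sample(clades, n_families, replace = TRUE),
      len = sample(1:6, n_families, replace = TRUE),
      type = sample(c("ins", "del"), n_families, replace = TRUE),
      pos = sample(seq(60L, L - 60L), n_families, replace = TRUE),
      seed = sample.int(2147483646L, n_families))
    for (k in seq_len(n_families)) {
      planted <- if (manifest$has_csi[k]) {
        manifest$clade[k] <- params$clade[k]
        manifest$length[k] <- params$len[k]
        manifest$type[k] <- params$type[k]
        manifest$position[k] <- params$pos[k]
        list(list(clade = params$clade[k], length = params$len[k],
                  type = params$type[k], position = params$pos[k]))
      } else list()
      manifest$seed[k] <- params$seed[k]
      spec_k <- sim_spec(tree = spec_template$tree, root_length = L,
                         frozen_fraction = spec_template$frozen_fraction,
                         planted_csis = planted,
                         background_indel_rate =
                           spec_template$background_indel_rate,
                         paralog_spec = spec_template$paralog_spec,
                         seed = params$seed[k])
      cases[[k]] <- simulate_family(spec_k)
    }
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_len(n_families)) {
      fam <- manifest$family[k]
      aln <- cases[[k]]$alignment
      write_alignment(aln, file.path(dir, paste0(fam, ".true.fasta")), "fasta")
      con <- file(file.path(dir, paste0(fam, ".fasta")), "w")
      for (id in aln$id) {
        writeLines(paste0(">", id), con)
        writeLines(ungapped(aln, id), con)
      }
      close(con)
    }
    utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(manifest = manifest, cases = cases)
}
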