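# Taxonomy, specificity calls, polarization, homolog groups.

tax <- default_taxonomy()

# alignment with one clean indel; bearer species chosen by the caller
state_aln <- function(bearer_sp, all_sp = c(names(tax$lineages),
                                            tax$outgroups),
                      block = "WWW") {
  left <- strrep("ACDEFGHIKL", 5)
  right <- strrep("MNPQRSTVWY", 5)
  gapb <- strrep("-", nchar(block))
  seqs <- vapply(all_sp, function(sp)
    paste0(left, if (sp %in% bearer_sp) block else gapb, right), "")
  make_aln(seqs, ids = all_sp, species = all_sp)
}

scan1 <- function(aln) scan_candidate_indels(aln, flank_params())[[1]]

test_that("lineage tables round-trip and validate clade uniqueness", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_lineage_table(tax, f)
  back <- read_lineage_table(f)
  expect_equal(back$lineages, tax$lineages)
  expect_setequal(back$outgroups, tax$outgroups)
  expect_error(clade_taxonomy(list(a = c("X", "Y"), b = c("Z", "Y"))),
               "more than one node")
})

test_that("newick import maps labelled nodes to clade paths", {
  expect_equal(tax$lineages$C_elegans,
               c("Nematoda", "Chromadorea", "Rhabditoidea", "Caenorhabditis"))
  expect_equal(tax$lineages$T_muris, c("Nematoda", "Enoplea"))
  expect_setequal(tax$outgroups,
                  c("C_muris", "P_falciparum", "B_xinjiang", "E_necatrix"))
  expect_setequal(clade_species(tax, "Rhabditoidea"),
                  c("C_elegans", "C_briggsae", "C_remanei", "C_brenneri",
                    "C_japonica", "C_sinica", "D_pachys"))
})

test_that("smallest_clade agrees with the ancestor-set-intersection oracle", {
  set.seed(13)
  sp <- names(tax$lineages)
  for (rep in 1:100) {
    pick <- sample(sp, sample(1:8, 1))
    expect_identical(smallest_clade(tax, pick), oracle_lca(tax, pick))
  }
  expect_error(smallest_clade(tax, "Homo_sapiens"), "not in taxonomy")
})

test_that("specificity resolves the exact bearer clade", {
  caeno <- clade_species(tax, "Caenorhabditis")
  aln <- state_aln(caeno)
  call <- evaluate_specificity(scan1(aln), aln, tax)
  expect_equal(call$clade, "Caenorhabditis")
  expect_equal(call$side, "residue")
  expect_length(call$exceptions, 0)
  expect_length(call$intruders, 0)
})

test_that("gap-side bearers are found for deletion-type signatures", {
  caeno <- clade_species(tax, "Caenorhabditis")
  aln <- state_aln(setdiff(c(names(tax$lineages), tax$outgroups), caeno))
  call <- evaluate_specificity(scan1(aln), aln, tax)
  expect_equal(call$clade, "Caenorhabditis")
  expect_equal(call$side, "gap")
})

test_that("in-clade absences fail at tolerance 0 and pass as exceptions", {
  chroma <- setdiff(clade_species(tax, "Chromadorea"), "S_ratti")
  aln <- state_aln(chroma)
  strict <- evaluate_specificity(scan1(aln), aln, tax, tolerance = 0)
  expect_equal(strict$clade, "none")
  lax <- evaluate_specificity(scan1(aln), aln, tax, tolerance = 1)
  expect_equal(lax$clade, "Chromadorea")
  expect_equal(lax$exceptions, "S_ratti")
  allow <- evaluate_specificity(scan1(aln), aln, tax,
                                allow_exceptions = "S_ratti")
  expect_equal(allow$clade, "Chromadorea")
})

test_that("bearers spanning every taxonomy species resolve to the root clade", {
  aln <- state_aln(names(tax$lineages))
  call <- evaluate_specificity(scan1(aln), aln, tax)
  expect_equal(call$clade, "Nematoda")
})

test_that("an out-of-clade carrier voids the call", {
  caeno <- clade_species(tax, "Caenorhabditis")
  aln <- state_aln(c(caeno, "T_muris"))
  call <- evaluate_specificity(scan1(aln), aln, tax)
  expect_equal(call$clade, "none")
})

test_that("raising tolerance never turns a successful call into none", {
  set.seed(42)
  sp <- c(names(tax$lineages), tax$outgroups)
  for (rep in 1:20) {
    bearers <- sample(sp, sample(2:10, 1))
    aln <- state_aln(bearers)
    cand <- scan1(aln)
    oks <- vapply(0:3, function(tol)
      evaluate_specificity(cand, aln, tax, tolerance = tol)$clade != "none",
      TRUE)
    # once successful, success persists at every higher tolerance
    expect_true(all(diff(oks) >= 0))
  }
})

test_that("unresolvable species are reported by name", {
  aln <- state_aln("C_elegans", all_sp = c("C_elegans", "C_briggsae",
                                           "Homo_sapiens", "T_muris"))
  expect_error(evaluate_specificity(scan1(aln), aln, tax), "Homo_sapiens")
})

test_that("rows gapped across the whole window count as missing, not exceptions", {
  caeno <- clade_species(tax, "Caenorhabditis")
  aln <- state_aln(caeno)
  k <- match("C_sinica", aln$id)
  aln$seqs[k] <- strrep("-", aln_width(aln))
  # C_sinica's homolog is unscorable; the clade call must still succeed
  cand <- scan_candidate_indels(aln)[[1]]
  call <- evaluate_specificity(cand, aln, tax)
  expect_equal(call$clade, "Caenorhabditis")
  expect_equal(call$missing, "C_sinica")
  expect_length(call$exceptions, 0)
})

test_that("outgroup absence/presence polarizes insertions and deletions", {
  caeno <- clade_species(tax, "Caenorhabditis")
  ins_aln <- state_aln(caeno)
  cand <- scan1(ins_aln)
  pol <- polarize_indel(cand, ins_aln, tax$outgroups)
  expect_equal(pol$state, "insertion")
  expect_equal(pol$outgroup_support, 4L)

  # swap bearer/non-bearer roles: the same block becomes a deletion
  del_aln <- state_aln(setdiff(c(names(tax$lineages), tax$outgroups), caeno))
  pol2 <- polarize_indel(scan1(del_aln), del_aln, tax$outgroups)
  expect_equal(pol2$state, "deletion")

  expect_equal(polarize_indel(cand, ins_aln, character())$state, "ambiguous")
  expect_equal(polarize_indel(cand, ins_aln, character())$outgroup_support, 0L)
})

test_that("polarity is invariant under row reordering", {
  caeno <- clade_species(tax, "Caenorhabditis")
  aln <- state_aln(caeno)
  cand <- scan1(aln)
  set.seed(3)
  perm <- sample(length(aln$id))
  shuf <- make_aln(aln$seqs[perm], ids = aln$id[perm],
                   species = aln$species[perm])
  expect_equal(polarize_indel(scan1(shuf), shuf, tax$outgroups)$state,
               polarize_indel(cand, aln, tax$outgroups)$state)
})

test_that("pre-labelled homolog groups pass through verbatim", {
  aln <- make_aln(c("ACDEF", "ACDEF"), ids = c("a1", "a2"),
                  species = c("sp1", "sp1"), group = c("nrfl-1a", "nrfl-1b"))
  expect_equal(partition_homolog_groups(aln)$homolog_group,
               c("nrfl-1a", "nrfl-1b"))
})

test_that("identity clustering splits divergent within-species paralogs", {
  set.seed(8)
  base <- random_protein(60)
  near <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    at <- sample(length(v), k)
    for (i in at) v[i] <- sample(setdiff(AA_set, v[i]), 1)
    paste(v, collapse = "")
  }
  AA_set <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  far <- random_protein(60)  # unrelated: identity ~5%
  aln <- make_aln(c(base, near(base, 3), far),
                  ids = c("s1_a", "s2_a", "s1_b"),
                  species = c("sp1", "sp2", "sp1"))
  out <- partition_homolog_groups(aln, identity_threshold = 0.5)
  expect_equal(out$homolog_group[1], out$homolog_group[2])
  expect_false(out$homolog_group[1] == out$homolog_group[3])
})

test_that("a second homolog group lacking the indel never changes the call", {
  caeno <- clade_species(tax, "Caenorhabditis")
  aln <- state_aln(caeno)
  aln$homolog_group <- rep("g1", length(aln$id))
  base_call <- evaluate_specificity(scan_candidate_indels(aln)[[1]], aln, tax)
  # add a paralog row set for the bearer species, without the indel
  left <- strrep("ACDEFGHIKL", 5)
  right <- strrep("MNPQRSTVWY", 5)
  extra <- paste0(left, "---", right)
  aln2 <- suppressMessages(aa_alignment(
    c(aln$id, paste0(caeno, "_p2")),
    c(aln$seqs, rep(extra, length(caeno))),
    species = c(aln$species, caeno),
    homolog_group = c(aln$homolog_group, rep("g2", length(caeno)))))
  cand2 <- scan_candidate_indels(aln2)[[1]]
  call2 <- evaluate_specificity(cand2, aln2, tax)
  expect_equal(call2$clade, base_call$clade)
  expect_equal(call2$bearers, base_call$bearers)
  expect_true(call2$paralog_restricted)
})
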