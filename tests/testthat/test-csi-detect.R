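# Candidate scanning, flank conservation, window extraction, validation.

# a 6-row alignment with one clean 2-column indel in the middle of a
# conserved context; bearers r1-r3
toy_indel_aln <- function(flank = 25) {
  left <- strrep("ACDEFGHIKL", ceiling(flank / 10))
  left <- substr(left, 1, flank)
  right <- substr(strrep("MNPQRSTVWY", ceiling(flank / 10)), 1, flank)
  make_aln(c(rep(paste0(left, "WW", right), 3),
             rep(paste0(left, "--", right), 3)))
}

test_that("gap-free alignments yield no candidates", {
  aln <- make_aln(rep("ACDEFGHIKLMNPQRSTVWY", 4))
  p <- flank_params(max_edge_distance = 0)
  expect_length(scan_candidate_indels(aln, p), 0)
})

test_that("a planted block is found once with the right span and bearers", {
  aln <- toy_indel_aln(flank = 48)
  cands <- scan_candidate_indels(aln, flank_params())
  expect_length(cands, 1)
  expect_equal(cands[[1]]$span, c(49, 50))
  expect_equal(cands[[1]]$length, 2L)
  expect_equal(cands[[1]]$bearers, c("r1", "r2", "r3"))
  expect_equal(cands[[1]]$gap_rows, c("r4", "r5", "r6"))
  expect_true(cands[[1]]$uniform_length)
})

test_that("scanning needs at least four rows", {
  expect_error(scan_candidate_indels(make_aln(c("AC-D", "ACDD", "ACDD"))),
               "4 informative rows")
})

test_that("edge-proximal runs are excluded but reported", {
  aln <- make_aln(c("W-CDEFGHIKLMNPQRSTVWYACDEFGHIKL",
                    "WWCDEFGHIKLMNPQRSTVWYACDEFGHIKL",
                    "WWCDEFGHIKLMNPQRSTVWYACDEFGHIKL",
                    "WWCDEFGHIKLMNPQRSTVWYACDEFGHIKL"))
  expect_message(cands <- scan_candidate_indels(aln, flank_params()),
                 "excluded")
  expect_length(cands, 0)
  expect_length(attr(cands, "excluded"), 1)
})

test_that("single-row indels are retained but flagged", {
  aln <- toy_indel_aln(flank = 48)
  aln$seqs[2] <- aln$seqs[4]
  aln$seqs[3] <- aln$seqs[4]
  cands <- scan_candidate_indels(aln)
  expect_length(cands, 1)
  expect_true("singleton" %in% cands[[1]]$flags)
})

test_that("partial-length gaps make a candidate non-uniform, not split", {
  aln <- toy_indel_aln(flank = 48)
  # r3 has a 1-residue gap inside the 2-column block
  substr(aln$seqs[3], 49, 49) <- "-"
  cands <- scan_candidate_indels(aln)
  expect_length(cands, 1)
  expect_equal(cands[[1]]$span, c(49, 50))
  expect_false(cands[[1]]$uniform_length)
  expect_equal(cands[[1]]$partial_rows, "r3")
})

test_that("scan matches the brute-force interval/bipartition oracle", {
  set.seed(77)
  p <- flank_params()
  for (rep in 1:60) {
    aln <- random_alignment(sample(4:8, 1), sample(50:120, 1))
    got <- suppressMessages(scan_candidate_indels(aln, p))
    expect_identical(cand_essence(got), cand_essence(oracle_scan(aln, p)))
  }
})

test_that("scan is invariant under row reordering", {
  set.seed(5)
  aln <- random_alignment(6, 100)
  perm <- sample(6)
  shuf <- make_aln(aln$seqs[perm], ids = aln$id[perm],
                   species = aln$species[perm])
  a <- suppressMessages(scan_candidate_indels(aln))
  b <- suppressMessages(scan_candidate_indels(shuf))
  expect_identical(cand_essence(a), cand_essence(b))
})

test_that("flank assessment counts conserved columns per side", {
  # identical rows: every column conserved; counts limited by availability
  aln <- toy_indel_aln(flank = 48)
  cand <- scan_candidate_indels(aln)[[1]]
  fa <- assess_flanks(aln, cand, flank_params())
  expect_equal(fa$left_conserved, 45L)
  expect_equal(fa$right_conserved, 45L)
  expect_true(fa$passed)

  # exactly 3 conserved columns per side fails min_conserved = 4
  set.seed(9)
  scramble <- function(n) vapply(seq_len(n), function(i)
    random_protein(1), "")
  left_var <- vapply(1:4, function(r)
    paste(c(vapply(1:42, function(i) random_protein(1), ""),
            strsplit("ACD", "")[[1]]), collapse = ""), "")
  right_var <- vapply(1:4, function(r)
    paste(c(strsplit("MNP", "")[[1]],
            vapply(1:42, function(i) random_protein(1), "")), collapse = ""), "")
  seqs <- paste0(left_var, c("WW", "WW", "--", "--"), right_var)
  aln2 <- make_aln(seqs)
  cand2 <- scan_candidate_indels(aln2)[[1]]
  fa2 <- assess_flanks(aln2, cand2, flank_params())
  expect_lt(fa2$left_conserved, 4L)
  expect_false(fa2$passed)
})

test_that("truncated flanks count only available columns", {
  # block 10 columns from the right end: at most 9 right-side columns
  left <- strrep("ACDEFGHIKL", 5)
  seqs <- c(rep(paste0(left, "WW", "MNPQRSTVW"), 2),
            rep(paste0(left, "--", "MNPQRSTVW"), 2))
  aln <- make_aln(seqs)
  cand <- scan_candidate_indels(aln, flank_params(max_edge_distance = 5))[[1]]
  fa <- assess_flanks(aln, cand, flank_params())
  expect_equal(fa$right_examined, 9L)
  expect_equal(fa$right_conserved, 9L)
})

test_that("ambiguity codes never count toward conservation", {
  col_x <- make_aln(c("XXAW", "XXAW", "XXA-", "XXA-"))
  # columns 1-2 are all-X: modal non-ambiguous residue does not exist
  expect_false(csindel:::column_is_conserved(c("X", "X", "X", "X"), 0.8))
  expect_true(csindel:::column_is_conserved(c("A", "A", "A", "A"), 0.8))
  expect_false(csindel:::column_is_conserved(c("A", "A", "X", "X"), 0.8))
  expect_false(csindel:::column_is_conserved(c("A", "-", "-", "-"), 0.8))
})

test_that("raising thresholds never enlarges the accepted set", {
  set.seed(31)
  for (rep in 1:10) {
    aln <- random_alignment(6, 110, gap_prob = 0.05)
    loose <- flank_params(min_conserved = 4, conservation_fraction = 0.7)
    strict1 <- flank_params(min_conserved = 5, conservation_fraction = 0.7)
    strict2 <- flank_params(min_conserved = 4, conservation_fraction = 0.9)
    accepted <- function(p) {
      cands <- suppressMessages(scan_candidate_indels(aln, p))
      keep <- vapply(cands, function(cc)
        isTRUE(assess_flanks(aln, cc, p)$passed), TRUE)
      vapply(cands[keep], function(cc) paste(cc$span, collapse = "-"), "")
    }
    base <- accepted(loose)
    expect_true(all(accepted(strict1) %in% base))
    expect_true(all(accepted(strict2) %in% base))
  }
})

test_that("signature windows carry correct regions and localize the indel", {
  spec <- sim_spec(planted_csis = list(list(clade = "Caenorhabditis",
                                            length = 3, type = "ins",
                                            position = 180)), seed = 12)
  fam <- simulate_family(spec)
  cand <- scan_candidate_indels(fam$alignment)[[1]]
  ext <- extract_signature_region(fam$alignment, cand, flank_residues = 45)
  expect_s3_class(ext$window, "aa_alignment")
  expect_equal(ext$region$seq_id, cand$bearers[1])
  expect_lt(ext$region$start, ext$indel_region[1])
  expect_gt(ext$region$end, ext$indel_region[2])
  expect_false(ext$truncated)
  # locality: rescanning the slice finds the same indel at the same length
  inner <- scan_candidate_indels(ext$window,
                                 flank_params(max_edge_distance = 20))
  expect_length(inner, 1)
  expect_equal(inner[[1]]$length, cand$length)
  expect_equal(sort(inner[[1]]$bearers), sort(cand$bearers))
})

test_that("windows truncate (and flag) near the protein start", {
  left <- strrep("ACDEFGHIKLMNPQRSTVWYACDEF", 1)
  right <- strrep("MNPQRSTVWY", 5)
  aln <- make_aln(c(rep(paste0(left, "W", right), 2),
                    rep(paste0(left, "-", right), 2)))
  cand <- scan_candidate_indels(aln, flank_params(max_edge_distance = 10))[[1]]
  ext <- extract_signature_region(aln, cand, flank_residues = 45)
  expect_true(ext$truncated)
  expect_equal(ext$region$start, 1L)
})

test_that("call_csi validates or enumerates every failed criterion", {
  ok_spec <- structure(list(clade = "Caenorhabditis", exceptions = character(),
                            intruders = character(), missing = character(),
                            bearers = "C_elegans", depth = 4L,
                            paralog_restricted = FALSE),
                       class = "specificity_call")
  none_spec <- ok_spec; none_spec$clade <- "none"
  cand <- list(span = c(50, 54), length = 5L, bearers = "C_elegans",
               uniform_length = TRUE, flags = character())
  bad_cand <- cand; bad_cand$uniform_length <- FALSE
  pass <- structure(list(passed = TRUE), class = "flank_assessment")
  fail <- structure(list(passed = FALSE), class = "flank_assessment")
  pol <- structure(list(state = "insertion", outgroup_support = 2L),
                   class = "indel_polarity")

  rec <- call_csi(cand, pass, ok_spec, meta = list(gene_name = "parg-1"),
                  polarity = pol)
  expect_s3_class(rec, "csi_record")
  expect_equal(rec$indel_size, 5L)
  expect_equal(rec$indel_type, "ins")

  rej <- call_csi(bad_cand, fail, none_spec)
  expect_s3_class(rej, "csi_rejection")
  expect_setequal(rej$reasons, c("non-uniform length", "flank conservation",
                                 "no clade specificity"))
})

test_that("flank parameter bounds are enforced", {
  expect_error(flank_params(window = 30), "40")
  expect_error(flank_params(conservation_fraction = 0), "conservation_fraction")
  expect_error(flank_params(min_conserved = 0), "min_conserved")
})
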