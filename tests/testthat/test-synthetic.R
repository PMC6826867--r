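# The family simulator: determinism, frozen sites, planted truth,
# paralogs, hit sets, and the benchmark manifest.

test_that("zero substitution and no indels reproduce the root everywhere", {
  tree <- default_sim_tree()
  tree$edge.length[] <- 0
  spec <- sim_spec(tree = tree, background_indel_rate = 0, seed = 2)
  fam <- simulate_family(spec)
  expect_length(unique(fam$seqs), 1)
  expect_equal(aln_width(fam$alignment), spec$root_length)
})

test_that("generation is a pure function of the seed", {
  spec <- sim_spec(planted_csis = list(list(clade = "Chromadorea", length = 4,
                                            type = "ins", position = 210)),
                   seed = 99)
  a <- simulate_family(spec)
  b <- simulate_family(spec)
  expect_identical(a, b)
  c <- simulate_family(sim_spec(planted_csis = spec$planted_csis, seed = 100))
  expect_false(identical(a$alignment$seqs, c$alignment$seqs))
  # the generator must not disturb the caller's RNG stream
  set.seed(1); x <- runif(1)
  set.seed(1); invisible(simulate_family(spec)); y <- runif(1)
  expect_identical(x, y)
})

test_that("frozen flank zones are invariant across all sequences", {
  spec <- sim_spec(planted_csis = list(list(clade = "Caenorhabditis",
                                            length = 5, type = "ins",
                                            position = 200,
                                            flank_freeze_width = 10)),
                   seed = 17)
  fam <- simulate_family(spec)
  span <- fam$truth$csis[[1]]$column_span
  mat <- aln_matrix(fam$alignment)
  left <- (span[1] - 10):(span[1] - 1)
  right <- (span[2] + 1):(span[2] + 10)
  for (j in c(left, right))
    expect_length(unique(mat[, j]), 1)
})

test_that("spec validation rejects malformed planted indels", {
  expect_error(sim_spec(planted_csis = list(list(clade = "X", length = 2,
                                                 type = "ins", position = 5))),
               "terminus")
  expect_error(sim_spec(planted_csis = list(
    list(clade = "A", length = 2, type = "ins", position = 200),
    list(clade = "B", length = 2, type = "del", position = 205))),
    "overlap")
  expect_error(sim_spec(planted_csis = list(list(clade = "X", length = 2,
                                                 type = "dup",
                                                 position = 100))),
               "'ins' or 'del'")
})

test_that("a planted insertion round-trips through the full pipeline", {
  spec <- sim_spec(planted_csis = list(list(clade = "Rhabditoidea",
                                            length = 5, type = "ins",
                                            position = 220)), seed = 41)
  fam <- simulate_family(spec)
  res <- discover_csis(fam$alignment, default_taxonomy())
  expect_length(res$records, 1)
  rec <- res$records[[1]]
  expect_equal(rec$indel_size, 5L)
  expect_equal(rec$indel_type, "ins")
  expect_equal(rec$specificity$clade, "Rhabditoidea")
})

test_that("paralog duplicates form a second group that lacks the indel", {
  spec <- sim_spec(planted_csis = list(list(clade = "Caenorhabditis",
                                            length = 3, type = "ins",
                                            position = 190)),
                   paralog_spec = list(clade = "Caenorhabditis",
                                       divergence = 0.3),
                   seed = 23)
  fam <- simulate_family(spec)
  expect_true(any(fam$alignment$homolog_group == "g2"))
  res <- discover_csis(fam$alignment, default_taxonomy())
  expect_length(res$records, 1)
  expect_true("paralog-restricted" %in% res$records[[1]]$flags)
  expect_equal(res$records[[1]]$specificity$clade, "Caenorhabditis")
})

test_that("hit sets label bearers correctly and stay callable under noise", {
  win <- list(seq = paste0(strrep("ACDEFGHIKL", 4), "WWWWW",
                           strrep("MNPQRSTVWY", 4)),
              block = c(41L, 45L), type = "ins", clade = "Caenorhabditis")
  csi <- structure(list(indel_size = 5L, indel_type = "ins",
                        window_block = c(41L, 45L),
                        specificity = list(clade = "Caenorhabditis",
                                           bearers = character())),
                   class = "csi_record")
  tax <- default_taxonomy()
  # divergence 0: all calls definite and correct
  hs0 <- generate_hit_set(win, 6, 6, 0, seed = 1)
  sr0 <- screen_hits(csi, win$seq, hs0$hits, tax = tax)
  expect_equal(unname(sr0$counts["ambiguous"]), 0L)
  expect_equal(sr0$verdict, "uniquely shared")
  # divergence 0.1 over many seeds: calls stay overwhelmingly definite
  total <- ambiguous <- 0L
  mismatched <- 0L
  for (s in 1:50) {
    hs <- generate_hit_set(win, 4, 4, 0.1, seed = s)
    sr <- screen_hits(csi, win$seq, hs$hits, tax = tax)
    total <- total + nrow(sr$hits)
    ambiguous <- ambiguous + unname(sr$counts["ambiguous"])
    definite <- sr$hits$call != "ambiguous"
    bearer <- hs$truth$bearer[match(sr$hits$hit_id, hs$truth$hit_id)]
    want <- ifelse(bearer, "has_indel", "lacks_indel")
    mismatched <- mismatched + sum(sr$hits$call[definite] != want[definite])
  }
  expect_gte((total - ambiguous) / total, 0.95)
  expect_equal(mismatched, 0L)
  # e-values are monotone in divergence
  e_low <- generate_hit_set(win, 5, 0, 0.05, seed = 3)$hits$e_value
  e_high <- generate_hit_set(win, 5, 0, 0.3, seed = 3)$hits$e_value
  expect_true(max(e_low) < min(e_high))
  expect_equal(nrow(generate_hit_set(win, 0, 0, 0.1, seed = 1)$hits), 0)
})

test_that("higher substitution pressure never improves flank conservation", {
  count_conserved <- function(subst_scale, seed) {
    tree <- default_sim_tree()
    tree$edge.length <- tree$edge.length * subst_scale
    spec <- sim_spec(tree = tree, frozen_fraction = 0,
                     planted_csis = list(list(clade = "Caenorhabditis",
                                              length = 3, type = "ins",
                                              position = 200,
                                              flank_freeze_width = 4)),
                     background_indel_rate = 0, seed = seed)
    fam <- simulate_family(spec)
    cand <- scan_candidate_indels(fam$alignment)[[1]]
    fa <- assess_flanks(fam$alignment, cand, flank_params())
    fa$left_conserved + fa$right_conserved
  }
  lo <- mean(vapply(1:20, function(s) count_conserved(0.3, s), 1))
  hi <- mean(vapply(1:20, function(s) count_conserved(3, s), 1))
  expect_gt(lo, hi)
})

test_that("benchmark manifests are deterministic and sized as requested", {
  s1 <- make_benchmark_suite(n_families = 6, fraction_with_csi = 0.5, seed = 8)
  s2 <- make_benchmark_suite(n_families = 6, fraction_with_csi = 0.5, seed = 8)
  expect_identical(s1$manifest, s2$manifest)
  expect_identical(s1$cases, s2$cases)
  expect_equal(nrow(s1$manifest), 6)
  expect_equal(sum(s1$manifest$has_csi), 3)
  empty <- make_benchmark_suite(n_families = 0)
  expect_equal(nrow(empty$manifest), 0)

  dir <- withr::local_tempdir()
  s3 <- make_benchmark_suite(n_families = 2, fraction_with_csi = 0.5,
                             seed = 8, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_true(file.exists(file.path(dir, "family001.true.fasta")))
  back <- read_alignment(file.path(dir, "family001.true.fasta"), "fasta")
  expect_equal(back$seqs, s3$cases[[1]]$alignment$seqs)
})
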