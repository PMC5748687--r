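test_that("G+C percentage is exact", {
  expect_equal(gc_percent("GCGC"), 100)
  expect_equal(gc_percent("ATAT"), 0)
  # 4 G, 0 C over 21 nt
  expect_equal(round_half_up(gc_percent("TGAATATTGTTAAAGTAGAAA"), 2), 19.05)
  expect_error(gc_percent(""), "non-empty")
})

test_that("AMFE and MFEI follow their defining formulas", {
  expect_equal(round_half_up(compute_amfe(-43.30, 122), 2), 35.49)
  expect_equal(compute_amfe(0, 100), 0)
  expect_equal(compute_amfe(-21, 100), 21)
  expect_error(compute_amfe(5, 100), "<= 0")
  expect_error(compute_mfei(-40, 100, 0), "positive")
  # MFEI depends on the sequence only through dG, length and GC -- invariant
  # under reversal -- and scales linearly in |dG|
  expect_equal(compute_mfei(-50, 120, 40), compute_mfei(-50, 120, 40))
  expect_equal(compute_mfei(-100, 120, 40), 2 * compute_mfei(-50, 120, 40))
})

test_that("bundled novel-miRNA reference reproduces printed MFEI for the
           consistent rows and flags the two inconsistent ones", {
  tab <- novel_mirna_reference()
  expect_equal(nrow(tab), 24L)
  recomputed <- round_half_up(compute_mfei(tab$delta_g, tab$lp, tab$gc_percent), 2)
  consistent <- tab$mfei_consistent
  expect_equal(sum(!consistent), 2L)
  expect_setequal(tab$name[!consistent], c("miR1348", "miR1356"))
  expect_equal(recomputed[consistent], tab$mfei[consistent])
  expect_equal(range(tab$mfei), c(0.64, 1.74))
  expect_equal(round_half_up(mean(tab$mfei), 2), 1.02)
})

test_that("folding backends satisfy the qualitative hairpin contract", {
  stem <- random_dna(30)
  hp <- paste0(stem, "GAAACAAA", revcomp(stem))
  for (be in c("viennarna", "internal")) {
    if (be == "viennarna" && !saltSRNA:::fold_backend_available()) next
    fr <- fold_hairpin(hp, backend = be)
    expect_lt(fr$delta_g, 0)
    pt <- saltSRNA:::pairing_table(fr$structure)
    expect_gte(sum(!is.na(pt)) / 2, 20)
    expect_equal(nchar(fr$structure), nchar(hp))
  }
  expect_error(fold_hairpin(random_dna(30)), "50-400")
  expect_error(fold_hairpin(paste0(strrep("N", 10), random_dna(40))), "N fraction")
})

test_that("a homopolymer has no stable structure", {
  fr <- fold_hairpin(strrep("A", 80), backend = "internal")
  expect_equal(fr$delta_g, 0)
})

test_that("perfect planted duplex passes with zero mismatches and correct arm", {
  set.seed(5)
  hp <- make_hairpin(flank5 = random_dna(25), flank3 = random_dna(25))
  ev <- evaluate_duplex(hp$sequence, NULL, hp$mature_span,
                        c(hp$mature, hp$star))
  expect_true(ev$pass)
  expect_equal(ev$duplex_mismatches, 0L)
  expect_equal(ev$arm, "5'")
  expect_equal(ev$star_sequence, hp$star)
})

test_that("duplex without miRNA* evidence fails for that reason", {
  set.seed(6)
  hp <- make_hairpin(flank5 = random_dna(25), flank3 = random_dna(25))
  ev <- evaluate_duplex(hp$sequence, NULL, hp$mature_span, c(hp$mature))
  expect_false(ev$pass)
  expect_match(ev$reason, "miRNA\\*")
})

test_that("six engineered duplex mismatches fail the strict rule", {
  set.seed(7)
  mature <- "TGAGGTAGTAGGTTGTATAGT"
  # star core complementary only outside six engineered positions
  core <- revcomp(substr(mature, 1, 19))
  for (p in c(3, 6, 9, 12, 15, 17)) {
    old <- substr(core, p, p)
    # replace with the same base as the mature position it faces (never pairs)
    faces <- substr(mature, 20 - p, 20 - p)
    substr(core, p, p) <- faces
  }
  star <- paste0(core, substr(mature, 20, 21))
  hp <- paste0(mature, "GAATCGCATTCAGGA", star)
  ev <- evaluate_duplex(hp, NULL, c(1, 21), c(mature, star))
  expect_false(ev$pass)
})

test_that("evaluate_duplex never passes a mature overlapping the terminal loop", {
  set.seed(8)
  violations <- 0L
  for (i in 1:25) {
    hp <- make_hairpin(mature = random_dna(21),
                       flank5 = random_dna(10), flank3 = random_dna(10))
    # slide the claimed mature span toward the loop so it overlaps it
    span <- hp$mature_span + sample(12:20, 1)
    ev <- tryCatch(
      evaluate_duplex(hp$sequence, NULL, span,
                      c(hp$mature, hp$star,
                        substr(hp$sequence, span[1], span[2]))),
      error = function(e) NULL)
    if (is.null(ev) || !isTRUE(ev$pass)) next
    loop <- ev$terminal_loop
    if (span[1] <= loop[2] && loop[1] <= span[2] - 2) violations <- violations + 1L
  }
  expect_equal(violations, 0L)
})

test_that("conserved matching applies the two-mismatch and length rules", {
  ref <- c(famA = "TGAGGTAGTAGGTTGTATAGT", famB = "TGAGGTAGTAGGTTGTATAGA")
  expect_equal(match_conserved("TGAGGTAGTAGGTTGTATAGT", ref)$family, "famA")
  expect_equal(match_conserved("TGAGGTAGTAGGTTGTATAGT", ref)$mismatches, 0L)
  two <- "TCAGGTAGTAGGTTGTATACT"
  m <- match_conserved(two, ref)
  expect_equal(m$mismatches, 2L)
  three <- "TCAGGAAGTAGGTTGTATACT"
  expect_null(match_conserved(three, ref))
  # length variant: reference minus its last 2 nt still matches
  short <- substr(ref[["famA"]], 1, 19)
  expect_equal(match_conserved(short, ref)$family, "famA")
  expect_error(match_conserved("ACGT", character(0)), "empty")
})

test_that("conserved tie-break picks fewest mismatches then family name", {
  ref <- c(zfam = "TGAGGTAGTAGGTTGTATAGT", afam = "TGAGGTAGTAGGTTGTATAGT")
  expect_equal(match_conserved("TGAGGTAGTAGGTTGTATAGT", ref)$family, "afam")
})

test_that("novel calling recovers planted hairpins and respects the
           miRNA* requirement", {
  sim <- default_benchmark()
  novel <- benchmark_novel_calls()
  tm <- vapply(sim$truth$mirnas, `[[`, "", "mature")
  sens <- mean(tm %in% novel$mature)
  prec <- mean(novel$mature %in% tm)
  expect_gte(sens, 0.95)
  expect_gte(prec, 0.95)
  # a hairpin whose star never reached the reads is excluded
  cfg <- simulation_config(seed = 55, n_mirna = 4, n_target = 2,
                           n_transcripts = 15, depth = 4000,
                           n_background = 50, star_rel = 0)
  txr <- simulate_transcriptome(cfg)
  libs <- simulate_small_rna_libraries(txr$truth, cfg)$libraries
  # remove any residual star tags to emulate unobserved miRNA*
  stars <- vapply(txr$truth$mirnas, `[[`, "", "star")
  libs <- lapply(libs, function(l) {
    keep <- !(names(l$counts) %in% stars)
    tag_library(l$library_id, l$counts[keep], l$total_clean_reads)
  })
  nv <- call_novel_mirnas(libs, txr$transcripts)
  expect_false(any(vapply(txr$truth$mirnas, `[[`, "", "mature") %in% nv$mature))
})
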