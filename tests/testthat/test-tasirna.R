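trigger <- "AAGCTCAGGAGGGATAGCGCC"

# build a two-hit transcript: left flank, site5, gap, site3, right flank
make_locus_tx <- function(gap_len, trigger_seq = trigger) {
  site <- revcomp(trigger_seq)
  left <- random_dna(60); right <- random_dna(60)
  seq <- paste0(left, site, random_dna(gap_len), site, right)
  list(sequence = seq,
       site5 = c(61L, 81L),
       site3 = c(81L + gap_len + 1L, 81L + gap_len + 21L))
}

test_that("trigger-site search equals a sliding-window oracle", {
  set.seed(51)
  txs <- setNames(vapply(1:20, function(i) random_dna(200), ""),
                  paste0("t", 1:20))
  # plant one perfect and one single-G:U site
  perfect <- revcomp(trigger)
  gu <- perfect
  gpos <- which(strsplit(trigger, "")[[1]] == "G")[1]
  facing <- 21 - gpos + 1
  substr(gu, facing, facing) <- "T"
  txs[["t1"]] <- paste0(substr(txs[["t1"]], 1, 50), perfect,
                        substr(txs[["t1"]], 72, 150), gu)
  sites <- find_trigger_sites(trigger, txs, max_score = 3)
  s1 <- sites[sites$transcript == "t1", ]
  expect_true(any(s1$start == 51 & s1$score == 0))
  expect_true(any(s1$score == 0.5))
  # oracle: every window scored explicitly
  oracle <- list()
  for (tid in names(txs)) {
    s <- txs[[tid]]
    for (p in seq_len(nchar(s) - 20)) {
      sc <- score_alignment(trigger, substr(s, p, p + 20))
      if (sc <= 3) oracle[[length(oracle) + 1L]] <-
          data.frame(transcript = tid, start = p, score = sc)
    }
  }
  oracle <- do.call(rbind, oracle)
  expect_equal(sites[c("transcript", "start", "score")],
               oracle[c("transcript", "start", "score")])
})

test_that("phase counts match the two-hit arithmetic", {
  expect_equal(phase_count(174), 8L)
  expect_equal(phase_count(261), 12L)
  expect_equal(phase_count(168), 8L)
})

test_that("two-hit detection computes spacing and phases from planted loci", {
  set.seed(52)
  for (gap in c(168L, 174L, 261L)) {
    lt <- make_locus_tx(gap)
    sites <- find_trigger_sites(trigger, c(tx = lt$sequence), max_score = 4.5)
    loci <- detect_two_hit_locus(sites)
    expect_equal(nrow(loci), 1L)
    expect_equal(loci$spacing_nt, gap)
    expect_equal(loci$phase_count, phase_count(gap))
    expect_equal(c(loci$site5_start, loci$site5_end), lt$site5)
    expect_equal(c(loci$site3_start, loci$site3_end), lt$site3)
  }
})

test_that("two-hit detection equals a brute-force pairing oracle", {
  set.seed(53)
  for (i in 1:15) {
    n_sites <- sample(2:5, 1)
    starts <- sort(sample(seq(1, 600, by = 30), n_sites))
    sites <- data.frame(transcript = "t", start = starts, end = starts + 20L,
                        score = sample(c(0, 0.5, 1), n_sites, replace = TRUE),
                        cleaved = FALSE)
    loci <- detect_two_hit_locus(sites)
    # oracle: all sites non-overlapping by construction; closest pair wins
    gaps <- starts[-1] - (starts[-n_sites] + 20L) - 1L
    k <- which.min(gaps)
    expect_equal(nrow(loci), 1L)
    expect_equal(loci$site5_start, starts[k])
    expect_equal(loci$site3_start, starts[k + 1])
    expect_equal(loci$spacing_nt, gaps[k])
  }
})

test_that("phase windows tile the register without overlap", {
  set.seed(54)
  lt <- make_locus_tx(168L)
  sites <- find_trigger_sites(trigger, c(tx = lt$sequence))
  locus <- detect_two_hit_locus(sites)
  lib <- tag_library("CK", c(setNames(1L, random_dna(21))))
  ph <- extract_phases(locus, lt$sequence, lib, max_k = 8)
  expect_equal(nrow(ph), 8L)
  expect_true(all(ph$end - ph$start == 20L))
  expect_equal(diff(ph$start), rep(-21L, 7))
  expect_true(all(nchar(ph$sequence) == 21L))
  expect_false(any(ph$truncated))
  # anchored at the 3' site cleavage position
  expect_equal(ph$start[1], (locus$site3_end - 9L) - 21L)
  # 5'-anchored register as the configurable alternative
  ph5 <- extract_phases(locus, lt$sequence, lib, anchor = "site5_end", max_k = 4)
  expect_equal(ph5$start[1], locus$site5_end + 1L)
  expect_equal(diff(ph5$start), rep(21L, 3))
})

test_that("planted D7/D8 content is recovered with abundances", {
  sim <- default_benchmark()
  profiles <- lapply(sim$degradome, build_profile,
                     transcripts = sim$transcripts)
  pooled <- saltSRNA:::pool_profiles(profiles)
  sites <- find_trigger_sites(sim$truth$trigger, sim$transcripts,
                              profiles = pooled)
  loci <- detect_two_hit_locus(sites)
  for (pl in sim$truth$tas3) {
    row <- loci[loci$transcript == pl$transcript, ]
    expect_equal(nrow(row), 1L)
    expect_equal(row$phase_count, pl$phases)
    expect_true(row$validated)   # only the 3' site is degradome-cleaved
    ph <- extract_phases(row, sim$transcripts[[pl$transcript]], sim$srna)
    expect_equal(ph$sequence[ph$k == 7], pl$d7)
    expect_equal(ph$sequence[ph$k == 8], pl$d8)
    ck_col <- ph$abundance_CK
    expect_gt(ck_col[ph$k == 7], 0)
  }
})

test_that("tasiRNA target prediction finds one- and two-site genes", {
  set.seed(55)
  tasi <- "TTCTTGACCTTGTAAGACCTT"
  g1 <- random_dna(500)
  substr(g1, 100, 120) <- revcomp(tasi)
  g2 <- random_dna(500)
  substr(g2, 80, 100) <- revcomp(tasi)
  substr(g2, 300, 320) <- revcomp(tasi)
  g3 <- random_dna(500)  # a 3-mismatch site only
  site3mm <- revcomp(tasi)
  for (p in c(3, 9, 15))

    substr(site3mm, p, p) <- c(A = "C", C = "A", G = "A", T = "C")[[substr(site3mm, p, p)]]
  substr(g3, 200, 220) <- site3mm
  res <- predict_tasi_targets(tasi, c(g1 = g1, g2 = g2, g3 = g3),
                              max_mismatch = 2.0)
  expect_setequal(res$gene, c("g1", "g2"))
  expect_equal(res$n_sites[res$gene == "g1"], 1L)
  expect_equal(res$n_sites[res$gene == "g2"], 2L)
  expect_equal(res$site1_start[res$gene == "g2"], 80L)
  expect_equal(res$site2_start[res$gene == "g2"], 300L)
})

test_that("expression correlation classifies direction", {
  r <- correlate_series(c(1, 0.5, 0.2), c(1, 2, 4))
  expect_equal(r$class, "negative")
  expect_lt(abs(r$r - (-0.944)), 0.01)
  expect_equal(correlate_series(1:4, 1:4)$class, "positive")
  expect_equal(correlate_series(1:4, 1:4)$r, 1)
  expect_error(correlate_series(c(1, 1, 1), c(1, 2, 3)), "constant")
})
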