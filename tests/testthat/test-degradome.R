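# exhaustive enumeration oracle over ungapped and all single-gap antisense
# alignments, scoring WC = 0, G:U = 0.5, other = 1, gap position = 1
oracle_score <- function(mirna, site) {
  cost1 <- function(m, t) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    if (comp[[m]] == t) return(0)
    if ((m == "G" && t == "T") || (m == "T" && t == "G")) return(0.5)
    1
  }
  pair_sum <- function(mv, sv) {
    s <- 0
    for (i in seq_along(mv)) s <- s + cost1(mv[i], sv[length(sv) - i + 1])
    s
  }
  mv <- strsplit(mirna, "")[[1]]
  sv <- strsplit(site, "")[[1]]
  d <- length(sv) - length(mv)
  if (d == 0) return(pair_sum(mv, sv))
  k <- abs(d)
  best <- Inf
  if (d > 0) {
    # delete k site positions (facing a gap in the miRNA), contiguous run
    sv_rev <- rev(sv)
    for (g in 0:length(mv)) {
      kept <- rev(sv_rev[-(seq_len(k) + g)])
      best <- min(best, k + pair_sum(mv, kept))
    }
  } else {
    for (g in 0:length(sv)) {
      mv2 <- mv[-(seq_len(k) + g)]
      best <- min(best, k + pair_sum(mv2, sv))
    }
  }
  best
}

test_that("alignment scoring follows the G:U = 0.5 rule", {
  mir <- "TGAGGTAGTAGGTTGTATAGT"
  perfect <- revcomp(mir)
  expect_equal(score_alignment(mir, perfect), 0)
  # one G:U wobble: the site base facing a miRNA G becomes T
  gu <- perfect
  gpos <- which(strsplit(mir, "")[[1]] == "G")[1]
  facing <- nchar(perfect) - gpos + 1
  substr(gu, facing, facing) <- "T"
  expect_equal(score_alignment(mir, gu), 0.5)
  # 3 mispairs + 2 G:U = 4.0 (disjoint position sets)
  s <- perfect
  mpos <- c(2, 5, 8)
  gupos <- setdiff(which(strsplit(mir, "")[[1]] == "G"), mpos)[1:2]
  for (p in mpos) {
    f <- nchar(s) - p + 1
    mb <- substr(mir, p, p)
    bad <- setdiff(c("A", "C", "G", "T"),
                   c(c(A = "T", C = "G", G = "C", T = "A")[[mb]],
                     if (mb == "G") "T", if (mb == "T") "G"))
    substr(s, f, f) <- bad[1]
  }
  for (p in gupos) substr(s, nchar(s) - p + 1, nchar(s) - p + 1) <- "T"
  expect_equal(score_alignment(mir, s), 4.0)
})

test_that("alignment scorer equals the exhaustive-enumeration oracle", {
  set.seed(41)
  for (i in 1:60) {
    mir <- random_dna(21)
    d <- sample(-2:2, 1)
    site <- random_dna(21 + d)
    expect_equal(score_alignment(mir, site), oracle_score(mir, site),
                 info = paste(mir, site))
  }
  expect_error(score_alignment(random_dna(21), random_dna(25)), "more than 2")
})

test_that("cleavage site is the position pairing miRNA nucleotide 10", {
  expect_equal(predict_cleavage(c(378, 398)), 389)
  expect_equal(predict_cleavage(c(19, 39)), 30)
  expect_equal(predict_cleavage(c(101, 120)), 111)
  expect_error(predict_cleavage(c(10, 20)), "shorter")
})

test_that("degradome tag preparation applies length and polyN rules", {
  ad <- "TGGAATTCTCGGGTGCCAAGG"
  keep20 <- random_dna(20); keep21 <- random_dna(21)
  too_short <- random_dna(19); too_long <- random_dna(22)
  polyA20 <- paste0(strrep("A", 19), "G")          # 95% A -> polyN
  boundary <- paste0(strrep("A", 14), "GTCGTC")    # 14/20 = 70% exactly, kept
  reads <- paste0(c(keep20, keep21, too_short, too_long, polyA20, boundary), ad)
  lib <- prepare_degradome_tags(reads, ad)
  expect_setequal(names(lib$counts), c(keep20, keep21, boundary))
  drops <- attr(lib, "dropped")
  expect_equal(unname(drops["length"]), 2L)
  expect_equal(unname(drops["polyN"]), 1L)
})

test_that("profiles use sense-strand exact matches at the 5' position", {
  tx <- c(t1 = random_dna(300))
  tag <- substr(tx[["t1"]], 100, 119)
  anti <- revcomp(substr(tx[["t1"]], 200, 219))
  lib <- tag_library("degradome", setNames(c(7L, 5L), c(tag, anti)))
  profs <- build_profile(lib, tx)
  expect_equal(profs$t1$positions, 100L)
  expect_equal(profs$t1$abundance, 7)
})

test_that("profile equals a brute-force substring scan over many transcripts", {
  set.seed(42)
  txs <- setNames(vapply(1:50, function(i) random_dna(150), ""),
                  paste0("t", 1:50))
  tags <- unlist(lapply(sample(names(txs), 20), function(id) {
    p <- sample(1:120, 2)
    substr(txs[[id]], p, p + 19)
  }))
  counts <- setNames(sample(1:9, length(unique(tags)), replace = TRUE),
                     unique(tags))
  lib <- tag_library("degradome", counts)
  profs <- build_profile(lib, txs)
  # oracle: scan every transcript for every tag at every offset
  oracle <- list()
  for (id in names(txs)) {
    s <- txs[[id]]
    hits <- integer(0)
    for (tg in names(counts)) {
      w <- nchar(tg)
      for (p in seq_len(nchar(s) - w + 1)) {
        if (substr(s, p, p + w - 1) == tg) {
          hits[as.character(p)] <- sum(hits[as.character(p)],
                                       counts[[tg]], na.rm = TRUE)
        }
      }
    }
    if (length(hits)) oracle[[id]] <- hits[order(as.integer(names(hits)))]
  }
  expect_setequal(names(profs), names(oracle))
  for (id in names(oracle)) {
    expect_equal(profs[[id]]$positions, as.integer(names(oracle[[id]])))
    expect_equal(profs[[id]]$abundance, unname(oracle[[id]]))
  }
})

test_that("categories follow the five clauses and partition events", {
  prof <- function(pos, ab) structure(list(transcript = "t", positions = pos,
                                           abundance = ab),
                                      class = "degradation_profile")
  expect_equal(assign_category(10, prof(c(10, 50, 80), c(12, 2, 1))), 0L)
  expect_equal(assign_category(10, prof(c(10, 50), c(12, 12))), 1L)
  expect_equal(assign_category(50, prof(c(10, 50, 80, 90), c(12, 6, 2, 2))), 2L)
  expect_equal(assign_category(80, prof(c(10, 50, 80, 90), c(12, 6, 2, 3))), 3L)
  expect_equal(assign_category(80, prof(c(10, 80), c(12, 1))), 4L)
  expect_error(assign_category(99, prof(10, 5)), "absent")
  # randomized profiles: rule equals an independent clause-by-clause oracle
  set.seed(43)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    pos <- sort(sample(1:200, n))
    ab <- sample(1:20, n, replace = TRUE)
    p <- prof(pos, ab)
    site <- sample(pos, 1)
    a <- ab[match(site, pos)]
    expected <- if (a == 1) 4L
      else if (a == max(ab) && sum(ab == max(ab)) == 1) 0L
      else if (a == max(ab)) 1L
      else if (a > median(ab)) 2L
      else 3L
    expect_equal(assign_category(site, p), expected)
  }
})

test_that("t-plot tables conserve abundance and mark the site", {
  prof <- structure(list(transcript = "t", positions = c(40L, 100L, 160L),
                         abundance = c(3, 7, 2)),
                    class = "degradation_profile")
  td <- tplot_data(100, prof)
  expect_equal(td$position, c(40, 100, 160))
  expect_equal(sum(td$abundance), 12)
  expect_equal(td$is_cleavage_site, c(FALSE, TRUE, FALSE))
})

test_that("planted cleavage events are recovered end to end", {
  sim <- default_benchmark()
  profiles <- lapply(sim$degradome, build_profile,
                     transcripts = sim$transcripts)
  mirnas <- setNames(vapply(sim$truth$mirnas, `[[`, "", "mature"),
                     vapply(sim$truth$mirnas, `[[`, "", "name"))
  mirnas <- c(mirnas, trigger = sim$truth$trigger)
  events <- call_targets(mirnas, profiles, sim$transcripts, max_score = 4.5)
  planted <- sim$truth$cleavages
  hit <- vapply(planted, function(ev) {
    any(events$mirna == ev$mirna & events$transcript == ev$transcript &
          events$cleavage_site == ev$cleavage_site)
  }, TRUE)
  expect_gte(mean(hit), 0.95)
  # two different miRNAs cleaving one site give two events
  key <- paste(events$transcript, events$cleavage_site)
  expect_true(all(table(paste(events$mirna, key)) == 1))
  # planted events sit at dominant positions: category 0 or 1 in >= 90%
  planted_ev <- events[paste(events$transcript, events$cleavage_site) %in%
                         vapply(planted, function(e)
                           paste(e$transcript, e$cleavage_site), ""), ]
  expect_gte(mean(planted_ev$category %in% c(0L, 1L)), 0.9)
})
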