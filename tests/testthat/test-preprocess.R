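# brute-force oracle: leftmost offset with >= 6 nt adapter-prefix match and
# at most one substitution, scanning every offset explicitly
oracle_adapter_pos <- function(read, adapter) {
  rv <- strsplit(read, "")[[1]]; av <- strsplit(adapter, "")[[1]]
  for (i in seq_len(nchar(read))) {
    k <- min(length(av), length(rv) - i + 1L)
    if (k < 6L) next
    if (sum(rv[i:(i + k - 1L)] != av[seq_len(k)]) <= 1L) return(i)
  }
  NA_integer_
}

test_that("adapter trimming keeps the insert before the left-most match", {
  ad <- "TGGAATTCTCGGGTGCCAAGG"
  insert <- "ACGTACGTACGTACGTACGTA"
  tr <- trim_adapter(paste0(insert, ad), ad)
  expect_true(tr$kept)
  expect_equal(tr$insert, insert)
  expect_equal(trim_adapter(ad, ad)$reason, "adapter_dimer")
  expect_equal(trim_adapter(random_dna(30), ad)$reason, "no_adapter")
})

test_that("adapter matching tolerates one substitution, not two", {
  ad <- "TGGAATTCTCGGGTGCCAAGG"
  insert <- "CCCTTTGGGAAACCCTTTGG"
  ad1 <- ad; substr(ad1, 3, 3) <- "C"
  expect_equal(trim_adapter(paste0(insert, ad1), ad)$insert, insert)
  ad2 <- ad1; substr(ad2, 5, 5) <- "C"
  expect_false(trim_adapter(paste0(insert, substr(ad2, 1, 12)), ad)$kept)
})

test_that("adapter position equals the brute-force scan oracle", {
  set.seed(11)
  ad <- "TCGTATGCCGTCTTCTGCTTG"
  for (i in 1:60) {
    read <- paste0(random_dna(sample(10:30, 1)), substr(ad, 1, sample(4:21, 1)))
    if (runif(1) < 0.5) {
      p <- sample(nchar(read), 1)
      substr(read, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    expect_equal(saltSRNA:::adapter_match_position(read, ad),
                 oracle_adapter_pos(read, ad), info = read)
  }
})

test_that("length filter bounds are inclusive at 15 and 30", {
  expect_false(filter_length(strrep("A", 14)))
  expect_true(filter_length(strrep("A", 15)))
  expect_true(filter_length(strrep("A", 30)))
  expect_false(filter_length(strrep("A", 31)))
})

test_that("annotation follows the fixed priority order and is single-class", {
  refs <- annotation_set(list(
    rRNA = c(r1 = "AACCGGTTAACCGGTTAACCGGTT"),
    tRNA = c(t1 = "GGGGTTTTCCCCAAAAGGGGTTTT"),
    known_miRNA = c(m1 = "AACCGGTTAACCGGTTAACC")))
  tags <- c("AACCGGTTAACCGGTTAACC",        # in rRNA host and known_miRNA
            "GGGGTTTTCCCCAAAA",            # tRNA only
            "TTTTTTTTTTGGGGGGGGGG",        # nothing
            "AAAAAAAAAAAAAAAAAAAA")        # polyA
  ann <- annotate_tags(tags, refs)
  expect_equal(ann$class,
               c("rRNA", "tRNA", "unannotated", "polyA"))
  expect_equal(anyDuplicated(ann$tag), 0L)
})

test_that("polyA rule requires the 3' A-run to reach 80% of the tag", {
  refs <- annotation_set(list(rRNA = c(r = "CCCCCGGGGGCCCCCGGGGG")))
  t80 <- paste0("GTAC", strrep("A", 16))   # 16/20 = 80%
  t75 <- paste0("GTACG", strrep("A", 15))  # 75%
  ann <- annotate_tags(c(t80, t75), refs)
  expect_equal(ann$class, c("polyA", "unannotated"))
})

test_that("the preprocessing cascade is monotone and accounts for rejects", {
  ad <- "TGGAATTCTCGGGTGCCAAGG"
  good <- paste0(vapply(1:40, function(i) random_dna(21), ""), ad)
  dimer <- rep(ad, 5)
  lowq <- data.frame(sequence = paste0(random_dna(21), ad),
                     quality = strrep("#", 42), stringsAsFactors = FALSE)
  reads <- rbind(data.frame(sequence = c(good, dimer),
                            quality = strrep("I", 42),
                            stringsAsFactors = FALSE), lowq)
  res <- preprocess_reads(reads, ad, "CK")
  expect_equal(res$stats$total_reads, 46)
  expect_equal(res$stats$high_quality, 45)
  expect_equal(res$stats$clean_reads, 40)
  expect_true(res$stats$unique_tags <= res$stats$clean_reads)
  expect_equal(unname(res$rejections[c("low_quality", "adapter_dimer")]),
               c(1L, 5L))
})

test_that("simulated reads survive preprocessing at the expected rate", {
  cfg <- simulation_config(seed = 5, n_mirna = 5, n_target = 3,
                           n_transcripts = 20, depth = 3000,
                           n_background = 80)
  sim <- simulate_experiment(cfg)
  reads <- expand_library_to_reads(sim$srna$CK, cfg$adapter3)
  res <- preprocess_reads(reads, cfg$adapter3, "CK")
  # inserts longer than 28 nt leave < 21 nt of adapter but still >= 6 nt,
  # so nearly all reads with 15-28 nt inserts are recovered
  lens <- nchar(names(sim$srna$CK$counts))
  expected <- sum(sim$srna$CK$counts[lens <= 28])
  expect_gt(res$stats$clean_reads, 0.95 * expected)
  # recovered tag counts match the library for 21-nt tags
  t21 <- names(sim$srna$CK$counts)[lens == 21]
  expect_equal(unname(res$library$counts[t21]),
               unname(sim$srna$CK$counts[t21]))
})
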