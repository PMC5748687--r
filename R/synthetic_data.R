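# Seeded synthetic-data generator: transcripts with planted miRNA hairpins,
# two-hit TAS3-like loci and repeat elements; three-condition small-RNA tag
# libraries with log-skewed abundance, planted fold changes and substitution
# errors; and degradome libraries concentrated at planted cleavage positions.
# Every planted feature is recorded in a ground-truth object so downstream
# detectors can be scored without external data.

#' Simulation configuration
#'
#' Defaults describe a desk-scale three-condition salt-stress experiment:
#' control plus two treatment time points, 21-nt and 24-nt read-length modes,
#' log-normal tag abundance, and planted differential expression at
#' `de_log2fc` (>= 1 so planted effects clear the |log2 ratio| > 1 call
#' threshold).
#'
#' @param seed master RNG seed; every stage derives its own stream from it.
#' @param n_transcripts background transcript count.
#' @param n_mirna planted hairpin count.
#' @param n_tas3 planted two-hit locus count.
#' @param n_repeat repeat element count (each embedded in two transcripts).
#' @param n_duplex_per_repeat planted siRNA duplex pairs per repeat element.
#' @param n_target planted miRNA cleavage events (degradome truth).
#' @param depth small-RNA reads per library.
#' @param degradome_depth degradome reads per library.
#' @param de_fraction fraction of planted miRNAs that are differentially
#'   expressed under treatment.
#' @param de_log2fc absolute planted log2 fold change (>= 1).
#' @param adapter3 3' adapter appended when raw reads are emitted.
#' @param error_rate per-base substitution probability.
#' @param length_mode_weights named weights for the 21-nt and 24-nt background
#'   length modes (remainder spread uniformly over 15--30 nt).
#' @param mirna_meanlog,mirna_sdlog log-normal abundance prior for planted
#'   miRNAs.
#' @param star_rel miRNA* abundance relative to its mature.
#' @param n_background distinct background tags per run.
#' @param max_star_mismatch planted duplex mismatches are drawn from
#'   `0:max_star_mismatch` (<= 5).
#' @param tas3_jitter_nt absolute inter-site spacing jitter (<= 3 nt).
#' @param trigger trigger miRNA sequence for the two-hit loci (21 nt).
#' @param libraries condition labels.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_transcripts = 120L,
                              n_mirna = 30L,
                              n_tas3 = 2L,
                              n_repeat = 3L,
                              n_duplex_per_repeat = 25L,
                              n_target = 10L,
                              depth = 50000L,
                              degradome_depth = 20000L,
                              de_fraction = 0.3,
                              de_log2fc = 2,
                              adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                              error_rate = 0.005,
                              length_mode_weights = c("21" = 0.55, "24" = 0.30),
                              mirna_meanlog = log(150),
                              mirna_sdlog = 1,
                              star_rel = 0.1,
                              n_background = 400L,
                              max_star_mismatch = 2L,
                              tas3_jitter_nt = 0L,
                              trigger = "AAGCTCAGGAGGGATAGCGCC",
                              libraries = c("CK", "T4h", "T5d")) {
  cfg <- list(seed = as.integer(seed), n_transcripts = as.integer(n_transcripts),
              n_mirna = as.integer(n_mirna), n_tas3 = as.integer(n_tas3),
              n_repeat = as.integer(n_repeat),
              n_duplex_per_repeat = as.integer(n_duplex_per_repeat),
              n_target = as.integer(n_target), depth = as.integer(depth),
              degradome_depth = as.integer(degradome_depth),
              de_fraction = de_fraction, de_log2fc = de_log2fc,
              adapter3 = adapter3, error_rate = error_rate,
              length_mode_weights = length_mode_weights,
              mirna_meanlog = mirna_meanlog, mirna_sdlog = mirna_sdlog,
              star_rel = star_rel, n_background = as.integer(n_background),
              max_star_mismatch = as.integer(max_star_mismatch),
              tas3_jitter_nt = as.integer(tas3_jitter_nt),
              trigger = trigger, libraries = libraries)
  stopifnot(cfg$depth >= 1L, cfg$de_fraction >= 0, cfg$de_fraction <= 1,
            cfg$error_rate >= 0, cfg$error_rate <= 1, cfg$de_log2fc >= 1,
            cfg$max_star_mismatch <= 5L, abs(cfg$tas3_jitter_nt) <= 3L,
            nchar(cfg$trigger) == 21L)
  if (cfg$n_target > cfg$n_mirna) stop("n_target cannot exceed n_mirna")
  structure(cfg, class = "simulation_config")
}

# Independent RNG stream per stage/library, derived from the master seed.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_base <- function(seq, pos) {
  old <- substr(seq, pos, pos)
  new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  substr(seq, pos, pos) <- new
  seq
}

#' Simulate a transcript set with planted features
#'
#' Background transcripts are random-composition. Each planted hairpin is a
#' mature + loop + near-reverse-complement star with 2-nt 3' overhang
#' geometry, embedded in a host transcript. Each TAS3-like locus carries two
#' perfect antisense trigger sites spaced an integer number of 21-nt phases
#' apart (plus optional jitter) with planted D7/D8 phase content. Repeat
#' elements appear in two transcript copies. A subset of planted miRNAs gets a
#' complementary target site in a background transcript (the degradome
#' ground-truth cleavage events); the 3'-proximal TAS3 site is a cleavage
#' event too (the two-hit model's cleaved site).
#'
#' @param cfg a [simulation_config()].
#' @return list `(transcripts, truth)`: named character vector of transcripts
#'   and a `ground_truth` list with elements `mirnas`, `de_labels` (filled by
#'   the library simulator), `duplexes`, `repeats`, `tas3`, `cleavages`,
#'   `tasi_targets`.
#' @export
simulate_transcriptome <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(derive_seed(cfg$seed, "transcriptome"))
  tx <- list()

  for (i in seq_len(cfg$n_transcripts)) {
    tx[[sprintf("bg_tx_%04d", i)]] <- rand_seq(sample(400:1200, 1L))
  }

  # --- planted miRNA hairpins -----------------------------------------------
  mirnas <- list()
  for (i in seq_len(cfg$n_mirna)) {
    repeat {
      mature <- rand_seq(21L)
      if (gc_percent(mature) >= 20 && gc_percent(mature) <= 80) break
    }
    star <- paste0(revcomp(substr(mature, 1L, 19L)), substr(mature, 20L, 21L))
    n_mm <- sample(0:cfg$max_star_mismatch, 1L)
    if (n_mm > 0L) {
      for (p in sample(2:18, n_mm)) star <- mutate_base(star, p)
    }
    loop <- rand_seq(15L)
    arm <- sample(c("5'", "3'"), 1L)
    hair <- if (arm == "5'") paste0(mature, loop, star) else paste0(star, loop, mature)
    fl <- rand_seq(sample(80:150, 1L))
    fr <- rand_seq(sample(80:150, 1L))
    host <- paste0(fl, hair, fr)
    id <- sprintf("mir_tx_%03d", i)
    tx[[id]] <- host
    mstart <- nchar(fl) + (if (arm == "5'") 1L else nchar(star) + 15L + 1L)
    mirnas[[i]] <- list(name = sprintf("planted-mir-%03d", i),
                        mature = mature, star = star, arm = arm,
                        transcript = id,
                        mature_span = c(mstart, mstart + 20L),
                        precursor_span = c(nchar(fl) + 1L, nchar(fl) + nchar(hair)),
                        star_mismatches = n_mm)
  }

  # --- TAS3-like two-hit loci ------------------------------------------------
  d7_pool <- c("TTCTTGACCTTGTAAGACCCA", "TTCTTGACCTTGTAAGACCCC",
               "TTCTTGACCTTGTAAGACCCT", "TTCTTGACCTTGTAAGACCCG")
  d8_pool <- c("TTCTTGACCTTGTAAGACCTT", "TTCTTGACCTTGTAAGGCCTT",
               "TTCTTGACCTTGTAAGACCTA", "TTCTTGACCTTGTAAGACCTC")
  site_seq <- revcomp(cfg$trigger)
  tas3 <- list()
  for (j in seq_len(cfg$n_tas3)) {
    phases <- sample(8:12, 1L)
    jit <- if (cfg$tas3_jitter_nt > 0L)
      sample(-cfg$tas3_jitter_nt:cfg$tas3_jitter_nt, 1L) else 0L
    gap_len <- phases * 21L + jit
    left <- rand_seq(150L); right <- rand_seq(150L)
    gap <- rand_seq(gap_len)
    s5_start <- 151L
    s5 <- c(s5_start, s5_start + 20L)
    s3_start <- s5[2] + gap_len + 1L
    s3 <- c(s3_start, s3_start + 20L)
    seqstr <- paste0(left, site_seq, gap, site_seq, right)
    cleavage <- s3[2] - 9L
    d7 <- d7_pool[(j - 1L) %% length(d7_pool) + 1L]
    d8 <- d8_pool[(j - 1L) %% length(d8_pool) + 1L]
    d7_span <- c(cleavage - 7L * 21L, cleavage - 7L * 21L + 20L)
    d8_span <- c(cleavage - 8L * 21L, cleavage - 8L * 21L + 20L)
    substr(seqstr, d7_span[1], d7_span[2]) <- d7
    substr(seqstr, d8_span[1], d8_span[2]) <- d8
    id <- sprintf("tas3_tx_%02d", j)
    tx[[id]] <- seqstr
    tas3[[j]] <- list(transcript = id, site5_span = s5, site3_span = s3,
                      spacing_nt = gap_len, phases = phases, jitter = jit,
                      cleavage_site = cleavage,
                      d7 = d7, d7_span = d7_span, d8 = d8, d8_span = d8_span)
  }

  # --- repeat elements and planted siRNA duplexes ---------------------------
  repeats <- list(); duplexes <- list()
  for (k in seq_len(cfg$n_repeat)) {
    elem <- rand_seq(300L)
    eid <- sprintf("repeat_%02d", k)
    for (copy in 1:2) {
      id <- sprintf("rep_tx_%02d_%d", k, copy)
      tx[[id]] <- paste0(rand_seq(sample(100:200, 1L)), elem,
                         rand_seq(sample(100:200, 1L)))
    }
    lens <- sample(c(21L, 22L, 23L, 24L), cfg$n_duplex_per_repeat,
                   replace = TRUE, prob = c(0.2, 0.1, 0.1, 0.6))
    for (d in seq_len(cfg$n_duplex_per_repeat)) {
      L <- lens[d]
      p <- sample(3:(300L - L), 1L)
      tag_a <- substr(elem, p, p + L - 1L)
      tag_b <- revcomp(substr(elem, p - 2L, p + L - 3L))
      duplexes[[length(duplexes) + 1L]] <-
        list(tag_a = tag_a, tag_b = tag_b, element = eid,
             position = p, length = L)
    }
    repeats[[k]] <- list(id = eid, sequence = elem,
                         copies = sprintf("rep_tx_%02d_%d", k, 1:2))
  }

  # --- planted cleavage events (miRNA targets) ------------------------------
  cleavages <- list()
  target_idx <- seq_len(cfg$n_target)
  bg_ids <- sprintf("bg_tx_%04d", seq_len(cfg$n_transcripts))
  hosts <- sample(bg_ids, cfg$n_target)
  for (t in seq_along(target_idx)) {
    m <- mirnas[[target_idx[t]]]
    site <- revcomp(m$mature)
    if (runif(1) < 0.5) {
      # one G:U wobble: a site C (pairing a mature G) becomes T (G:T wobble)
      cpos <- which(strsplit(site, "")[[1]] == "C")
      cpos <- cpos[cpos >= 3 & cpos <= 19]
      if (length(cpos)) {
        p <- sample(cpos, 1L)
        substr(site, p, p) <- "T"
      }
    }
    host <- hosts[t]
    s <- tx[[host]]
    pos <- sample(50:(nchar(s) - 80L), 1L)
    substr(s, pos, pos + 20L) <- site
    tx[[host]] <- s
    cleavages[[t]] <- list(mirna = m$name, mature = m$mature,
                           transcript = host,
                           site_span = c(pos, pos + 20L),
                           cleavage_site = pos + 20L - 9L)
  }
  for (j in seq_len(cfg$n_tas3)) {
    cleavages[[length(cleavages) + 1L]] <-
      list(mirna = "trigger", mature = cfg$trigger,
           transcript = tas3[[j]]$transcript,
           site_span = tas3[[j]]$site3_span,
           cleavage_site = tas3[[j]]$cleavage_site)
  }

  # --- tasiRNA target genes (ARF-like, 1 or 2 sites) ------------------------
  tasi_targets <- list()
  if (cfg$n_tas3 > 0L) {
    d7 <- tas3[[1]]$d7
    for (g in 1:2) {
      n_sites <- g            # gene 1: one site; gene 2: two sites
      glen <- 900L
      s <- rand_seq(glen)
      spans <- list()
      starts <- if (n_sites == 1L) 300L else c(250L, 500L)
      for (st in starts) {
        substr(s, st, st + 20L) <- revcomp(d7)
        spans[[length(spans) + 1L]] <- c(st, st + 20L)
      }
      id <- sprintf("arf_tx_%02d", g)
      tx[[id]] <- s
      tasi_targets[[g]] <- list(gene = id, tasi = d7, sites = spans)
    }
  }

  truth <- structure(list(mirnas = mirnas, de_labels = NULL,
                          duplexes = duplexes, repeats = repeats,
                          tas3 = tas3, cleavages = cleavages,
                          tasi_targets = tasi_targets,
                          trigger = cfg$trigger),
                     class = "ground_truth")
  list(transcripts = unlist(tx), truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Synthetic ground truth:", length(x$mirnas), "miRNA hairpins,",
      length(x$duplexes), "siRNA duplexes,", length(x$tas3), "TAS3 loci,",
      length(x$cleavages), "cleavage events\n")
  invisible(x)
}

#' Simulate three-condition small-RNA tag libraries
#'
#' miRNA abundances follow a log-normal prior; DE-labelled miRNAs are scaled
#' by the configured fold change in the treatment libraries (alternating up
#' and down). miRNA* tags, pairwise siRNA duplex strands, planted D7/D8
#' phased tags, the trigger miRNA (declining across conditions) and a
#' heavy-tailed background fill the library; counts are drawn by multinomial
#' sampling so each library total equals `cfg$depth` exactly, then
#' substitution errors reassign reads to mutated tags.
#'
#' @param truth ground truth from [simulate_transcriptome()] (its `de_labels`
#'   element is filled in the returned copy).
#' @param transcripts the transcript set (background fragments are drawn from
#'   it; optional).
#' @param cfg the same [simulation_config()].
#' @return list `(libraries, truth)` where `libraries` is a named list of
#'   `tag_library` objects.
#' @export
simulate_small_rna_libraries <- function(truth, cfg, transcripts = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (cfg$depth < 1L) stop("depth must be >= 1")
  set.seed(derive_seed(cfg$seed, "abundance"))
  n_mir <- length(truth$mirnas)
  matures <- vapply(truth$mirnas, `[[`, "", "mature")
  stars <- vapply(truth$mirnas, `[[`, "", "star")
  base <- rlnorm(n_mir, cfg$mirna_meanlog, cfg$mirna_sdlog)

  # DE directions are assigned mass-balanced (greedy), so the treatment
  # library's total expected mass stays ~equal to the control's and realized
  # TPM ratios centre on the planted fold change instead of absorbing a
  # compositional shift
  n_de <- round(cfg$de_fraction * n_mir)
  de_label <- rep("ns", n_mir)
  if (n_de > 0L) {
    up_gain <- 2^cfg$de_log2fc - 1
    down_gain <- 2^-cfg$de_log2fc - 1
    delta <- 0
    for (i in seq_len(n_de)) {
      if (abs(delta + base[i] * up_gain) <= abs(delta + base[i] * down_gain)) {
        de_label[i] <- "up"; delta <- delta + base[i] * up_gain
      } else {
        de_label[i] <- "down"; delta <- delta + base[i] * down_gain
      }
    }
  }
  fc <- ifelse(de_label == "up", 2^cfg$de_log2fc,
               ifelse(de_label == "down", 2^-cfg$de_log2fc, 1))

  dup_a <- vapply(truth$duplexes, `[[`, "", "tag_a")
  dup_b <- vapply(truth$duplexes, `[[`, "", "tag_b")
  dup_base <- rlnorm(length(dup_a), log(30), 0.7)

  phased <- unlist(lapply(truth$tas3, function(l) c(l$d7, l$d8)))
  phased_base <- rep(c(2000, 80), length(truth$tas3))

  # background: random k-mers plus transcript fragments, log-skewed
  wl <- cfg$length_mode_weights
  draw_len <- function(n) {
    modes <- as.integer(names(wl))
    other <- setdiff(15:30, modes)
    probs <- c(wl, rep((1 - sum(wl)) / length(other), length(other)))
    sample(c(modes, other), n, replace = TRUE, prob = probs)
  }
  n_bg <- cfg$n_background
  bg_len <- draw_len(n_bg)
  bg <- character(n_bg)
  tx_pool <- if (!is.null(transcripts)) unname(transcripts) else character(0)
  for (i in seq_len(n_bg)) {
    if (length(tx_pool) && i %% 2L == 0L) {
      s <- tx_pool[[sample.int(length(tx_pool), 1L)]]
      p <- sample.int(max(1L, nchar(s) - bg_len[i]), 1L)
      bg[i] <- substr(s, p, p + bg_len[i] - 1L)
    } else {
      bg[i] <- rand_seq(bg_len[i])
    }
  }
  bg_base <- rlnorm(n_bg, log(3), 1.2)

  feats <- c(matures, stars, dup_a, dup_b, phased, cfg$trigger, bg)
  base_all <- c(base, base * cfg$star_rel, dup_base, dup_base, phased_base,
                3000, bg_base)
  trig_mult <- c(CK = 1, 0.5, 0.25)

  libs <- list()
  for (li in seq_along(cfg$libraries)) {
    lib_id <- cfg$libraries[li]
    set.seed(derive_seed(cfg$seed, paste0("lib_", lib_id)))
    mult <- rep(1, length(feats))
    if (li > 1L) {
      mult[seq_len(n_mir)] <- fc
      mult[2L * n_mir + 2L * length(dup_a) + length(phased) + 1L] <- trig_mult[li]
    }
    expected <- base_all * mult
    counts <- as.vector(rmultinom(1L, cfg$depth, expected / sum(expected)))
    keep <- counts > 0L
    tags <- feats[keep]; cts <- counts[keep]
    # merge duplicate sequences
    agg <- tapply(cts, tags, sum)
    tags <- names(agg); cts <- as.integer(agg)
    # substitution errors move reads onto mutated tags
    if (cfg$error_rate > 0) {
      err <- rbinom(length(cts), cts, 1 - (1 - cfg$error_rate)^nchar(tags))
      new_tags <- character(0); new_cts <- integer(0)
      for (i in which(err > 0L)) {
        cts[i] <- cts[i] - err[i]
        for (e in seq_len(err[i])) {
          mut <- mutate_base(tags[i], sample.int(nchar(tags[i]), 1L))
          new_tags <- c(new_tags, mut); new_cts <- c(new_cts, 1L)
        }
      }
      tags <- c(tags[cts > 0L], new_tags)
      cts <- c(cts[cts > 0L], new_cts)
      agg <- tapply(cts, tags, sum)
      tags <- names(agg); cts <- as.integer(agg)
    }
    libs[[lib_id]] <- tag_library(lib_id, setNames(cts, tags),
                                  total_clean_reads = cfg$depth)
  }

  truth$de_labels <- data.frame(
    name = vapply(truth$mirnas, `[[`, "", "name"),
    mature = matures, label = de_label, base_abundance = base,
    log2fc = ifelse(de_label == "up", cfg$de_log2fc,
                    ifelse(de_label == "down", -cfg$de_log2fc, 0)),
    stringsAsFactors = FALSE)
  list(libraries = libs, truth = truth)
}

#' Simulate degradome tag libraries
#'
#' For each planted cleavage event, 20--21 nt tags whose 5' end sits exactly
#' at the cleavage site dominate that transcript's tags (~85% expected mass,
#' so >= 70% holds with high probability after sampling); a uniform low-level
#' background of degradation tags covers other positions. Totals equal
#' `cfg$degradome_depth` per library by multinomial sampling.
#'
#' @param truth ground truth containing `cleavages`.
#' @param transcripts named transcript vector.
#' @param cfg the [simulation_config()].
#' @return named list of `tag_library` objects, one per condition.
#' @export
simulate_degradome <- function(truth, transcripts, cfg) {
  stopifnot(inherits(truth, "ground_truth"))
  tags <- character(0); wt <- numeric(0)
  set.seed(derive_seed(cfg$seed, "degradome"))
  for (ev in truth$cleavages) {
    s <- transcripts[[ev$transcript]]
    c0 <- ev$cleavage_site
    site_mass <- rlnorm(1, log(100), 0.4)
    for (L in 20:21) {
      if (c0 + L - 1L <= nchar(s)) {
        tags <- c(tags, substr(s, c0, c0 + L - 1L))
        wt <- c(wt, site_mass / 2)
      }
    }
    n_bgpos <- 6L
    bg_pos <- sample(setdiff(30:(nchar(s) - 30L), c0), n_bgpos)
    for (p in bg_pos) {
      tags <- c(tags, substr(s, p, p + 19L))
      wt <- c(wt, site_mass * 0.15 / n_bgpos)
    }
  }
  # background degradation on untargeted transcripts
  others <- sample(names(transcripts), min(20L, length(transcripts)))
  for (id in others) {
    s <- transcripts[[id]]
    p <- sample(30:(nchar(s) - 30L), 3L)
    tags <- c(tags, substr(s, p[1], p[1] + 19L), substr(s, p[2], p[2] + 20L),
              substr(s, p[3], p[3] + 19L))
    wt <- c(wt, rep(1.5, 3L))
  }
  agg <- tapply(wt, tags, sum)
  useq <- names(agg); uw <- as.numeric(agg)
  libs <- list()
  for (lib_id in cfg$libraries) {
    set.seed(derive_seed(cfg$seed, paste0("deg_", lib_id)))
    jitter <- rlnorm(length(uw), 0, 0.2)
    counts <- as.vector(rmultinom(1L, cfg$degradome_depth,
                                  uw * jitter / sum(uw * jitter)))
    keep <- counts > 0L
    libs[[lib_id]] <- tag_library(lib_id, setNames(as.integer(counts[keep]), useq[keep]),
                                  total_clean_reads = cfg$degradome_depth)
  }
  libs
}

#' Expand a tag library into raw FASTQ-style reads
#'
#' Appends the 3' adapter and pads with adapter+poly-A to a fixed read length,
#' emulating an un-trimmed sequencer output for preprocessing tests.
#'
#' @param lib a `tag_library`.
#' @param adapter3 adapter sequence to append.
#' @param read_length output read length (inserts + adapter are truncated or
#'   padded to this length).
#' @return data.frame with `id`, `sequence`, `quality` columns.
#' @export
expand_library_to_reads <- function(lib, adapter3, read_length = 49L) {
  seqs <- rep(names(lib$counts), lib$counts)
  full <- paste0(seqs, adapter3, strrep("A", read_length))
  full <- substr(full, 1L, read_length)
  data.frame(id = sprintf("%s_read_%06d", lib$library_id, seq_along(full)),
             sequence = full,
             quality = strrep("I", read_length),
             stringsAsFactors = FALSE)
}

#' Run the whole generator
#'
#' Convenience wrapper: transcriptome, small-RNA libraries and degradome
#' libraries from one configuration.
#'
#' @param cfg a [simulation_config()].
#' @return list `(transcripts, truth, srna, degradome, config)`.
#' @export
simulate_experiment <- function(cfg = simulation_config()) {
  txr <- simulate_transcriptome(cfg)
  sim <- simulate_small_rna_libraries(txr$truth, cfg, transcripts = txr$transcripts)
  deg <- simulate_degradome(sim$truth, txr$transcripts, cfg)
  list(transcripts = txr$transcripts, truth = sim$truth,
       srna = sim$libraries, degradome = deg, config = cfg)
}

#' Serialise ground truth to JSON
#'
#' Documented schema: top-level arrays `mirnas`, `de_labels`, `duplexes`,
#' `repeats`, `tas3`, `cleavages`, `tasi_targets` listing every planted
#' feature and label.
#'
#' @param truth a `ground_truth`.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
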