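# End-to-end orchestration: run every stage in dependency order on a
# configuration, write deterministic TSV outputs plus a digest manifest, and
# assemble a combined text report from the stage outputs alone.

#' Pipeline configuration
#'
#' Thresholds default to the study's stated values: raw p < 0.01 and
#' |log2 ratio| > 1 for differential expression, alignment score <= 4.5 for
#' degradome target calling, score <= 2.0 for tasiRNA target sites.
#'
#' @param sim a [simulation_config()] describing the synthetic input (the
#'   pipeline also accepts externally supplied data through `run_pipeline()`
#'   arguments).
#' @param p_threshold,lfc_threshold DE thresholds.
#' @param max_score degradome/trigger alignment-score threshold.
#' @param tasi_max_mismatch tasiRNA target-site score threshold.
#' @param stages character vector of stages to run, in dependency order.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            p_threshold = 0.01, lfc_threshold = 1,
                            max_score = 4.5, tasi_max_mismatch = 2.0,
                            stages = c("simulate", "preprocess", "mirna",
                                       "de", "sirna", "degradome", "tasi")) {
  stopifnot(p_threshold > 0, lfc_threshold > 0, max_score > 0,
            tasi_max_mismatch > 0)
  structure(list(sim = sim, p_threshold = p_threshold,
                 lfc_threshold = lfc_threshold, max_score = max_score,
                 tasi_max_mismatch = tasi_max_mismatch, stages = stages),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Stages run in dependency order (simulate, preprocess, mirna, de, sirna,
#' degradome, tasi); each writes its TSV outputs under `out_dir` and a run
#' manifest records the seed, thresholds, per-stage record counts and a
#' content digest for every file. Identical configuration and seed give
#' byte-identical outputs. Disabling the degradome stage degrades the tasi
#' cleaved flags to unvalidated.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list of in-memory stage results plus `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = tempfile("saltSRNA_")) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(out_dir = out_dir)
  counts <- list()
  run <- function(stage) stage %in% cfg$stages

  if (!run("simulate")) stop("stage failure in 'simulate': the synthetic run requires the simulate stage")
  sim <- simulate_experiment(cfg$sim)
  write_fasta(sim$transcripts, file.path(out_dir, "transcripts.fasta"))
  write_truth_json(sim$truth, file.path(out_dir, "truth.json"))
  for (id in names(sim$srna)) {
    write_tag_table(sim$srna[[id]], file.path(out_dir, paste0("tags_", id, ".tsv")))
  }
  res$sim <- sim
  counts$simulate <- length(sim$transcripts)

  ann <- NULL
  if (run("preprocess")) {
    # the generator emits already-clean tags; preprocessing here annotates
    # them and records cascade statistics per library
    stats <- do.call(rbind, lapply(sim$srna, function(l) {
      library_stats(l$total_clean_reads, l$total_clean_reads, l)
    }))
    write_tsv(stats, file.path(out_dir, "library_stats.tsv"))
    res$stats <- stats
    counts$preprocess <- nrow(stats)
  }

  if (run("mirna")) {
    # repeat-derived tags are annotated (both element strands) and excluded
    # from miRNA prediction, mirroring the annotation-priority cascade
    excl <- repeat_annotated_tags(sim$srna, sim$truth)
    novel <- call_novel_mirnas(sim$srna, sim$transcripts, exclude = excl)
    write_tsv(round_table_2dp(novel), file.path(out_dir, "novel_mirnas.tsv"))
    res$novel <- novel
    counts$mirna <- nrow(novel)
  }

  if (run("de")) {
    pairs <- list()
    libs <- sim$srna
    for (t in setdiff(names(libs), names(libs)[1])) {
      tab <- de_table(libs[[1]], libs[[t]], p_threshold = cfg$p_threshold,
                      lfc_threshold = cfg$lfc_threshold)
      write_tsv(tab, file.path(out_dir, paste0("de_", names(libs)[1], "_vs_", t, ".tsv")))
      pairs[[t]] <- tab
    }
    res$de <- pairs
    counts$de <- sum(vapply(pairs, nrow, 0L))
  }

  if (run("sirna")) {
    pooled <- unique(unlist(lapply(sim$srna, function(l) names(l$counts))))
    dup <- find_duplex_pairs(pooled)
    write_tsv(dup, file.path(out_dir, "duplexes.tsv"))
    elements <- setNames(vapply(sim$truth$repeats, `[[`, "", "sequence"),
                         vapply(sim$truth$repeats, `[[`, "", "id"))
    mapping <- map_duplexes_to_elements(dup, elements)
    cov <- do.call(rbind, lapply(names(mapping$coverage), function(el) {
      data.frame(element = el,
                 position = seq_along(mapping$coverage[[el]]),
                 depth = mapping$coverage[[el]], stringsAsFactors = FALSE)
    }))
    write_tsv(cov, file.path(out_dir, "element_coverage.tsv"))
    if (nrow(dup)) {
      ld <- duplex_length_distribution(dup)
      write_tsv(data.frame(length = names(ld), fraction = as.numeric(ld)),
                file.path(out_dir, "length_distribution.tsv"))
    }
    res$duplexes <- dup
    res$duplex_mapping <- mapping
    counts$sirna <- nrow(dup)
  }

  profiles <- NULL
  if (run("degradome")) {
    profiles <- lapply(sim$degradome, build_profile, transcripts = sim$transcripts)
    mirnas <- setNames(vapply(sim$truth$mirnas, `[[`, "", "mature"),
                       vapply(sim$truth$mirnas, `[[`, "", "name"))
    mirnas <- c(mirnas, trigger = sim$truth$trigger)
    targets <- call_targets(mirnas, profiles, sim$transcripts,
                            max_score = cfg$max_score)
    write_tsv(targets, file.path(out_dir, "targets.tsv"))
    res$targets <- targets
    counts$degradome <- nrow(targets)
  }

  if (run("tasi")) {
    pooled_prof <- if (!is.null(profiles)) pool_profiles(profiles) else NULL
    sites <- find_trigger_sites(sim$truth$trigger, sim$transcripts,
                                max_score = cfg$max_score,
                                profiles = pooled_prof)
    loci <- detect_two_hit_locus(sites)
    write_tsv(loci, file.path(out_dir, "loci.tsv"))
    phase_rows <- list()
    for (r in seq_len(nrow(loci))) {
      ph <- extract_phases(loci[r, ], sim$transcripts[[loci$transcript[r]]],
                           sim$srna)
      ph$transcript <- loci$transcript[r]
      phase_rows[[r]] <- ph
    }
    phases <- if (length(phase_rows)) do.call(rbind, phase_rows) else NULL
    if (!is.null(phases)) write_tsv(phases, file.path(out_dir, "phases.tsv"))
    tasi_tab <- NULL
    if (length(sim$truth$tas3)) {
      d7 <- sim$truth$tas3[[1]]$d7
      tasi_tab <- predict_tasi_targets(d7, sim$transcripts,
                                       max_mismatch = cfg$tasi_max_mismatch)
      write_tsv(tasi_tab, file.path(out_dir, "tasi_targets.tsv"))
    }
    res$loci <- loci
    res$phases <- phases
    res$tasi_targets <- tasi_tab
    counts$tasi <- nrow(loci)
  }

  manifest <- data.frame(
    key = c("seed", "p_threshold", "lfc_threshold", "max_score",
            "tasi_max_mismatch", "stages",
            paste0("n_", names(counts))),
    value = c(cfg$sim$seed, cfg$p_threshold, cfg$lfc_threshold, cfg$max_score,
              cfg$tasi_max_mismatch, paste(cfg$stages, collapse = ","),
              unlist(counts)),
    stringsAsFactors = FALSE)
  files <- setdiff(list.files(out_dir), "manifest.tsv")
  digests <- tools::md5sum(file.path(out_dir, files))
  manifest <- rbind(manifest,
                    data.frame(key = paste0("md5_", files),
                               value = unname(digests),
                               stringsAsFactors = FALSE))
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  res$manifest <- manifest
  invisible(res)
}

#' Tags annotated to the repeat reference
#'
#' Exact-substring annotation of pooled library tags against the repeat
#' elements (both strands), the exclusion set for miRNA prediction.
#'
#' @param libs list of `tag_library` objects.
#' @param truth ground truth carrying the repeat elements (or a named
#'   character vector of element sequences).
#' @return character vector of repeat-annotated tag sequences.
#' @export
repeat_annotated_tags <- function(libs, truth) {
  elems <- if (inherits(truth, "ground_truth")) {
    setNames(vapply(truth$repeats, `[[`, "", "sequence"),
             vapply(truth$repeats, `[[`, "", "id"))
  } else truth
  if (!length(elems)) return(character(0))
  both <- c(elems, setNames(revcomp(elems), paste0(names(elems), "_rc")))
  refs <- annotation_set(list("repeat" = both))
  pooled <- unique(unlist(lapply(libs, function(l) names(l$counts)),
                          use.names = FALSE))
  ann <- annotate_tags(pooled, refs)
  ann$tag[ann$class == "repeat"]
}

#' Build a combined text report from pipeline outputs
#'
#' Summarises the stage TSVs (library statistics, novel miRNAs, DE class
#' counts, duplexes, degradome targets, tasiRNA loci) without recomputing
#' anything; regeneration is idempotent.
#'
#' @param out_dir directory written by [run_pipeline()].
#' @param path optional output file for the report text.
#' @return the report lines, invisibly when `path` is given.
#' @export
build_report <- function(out_dir, path = NULL) {
  f <- function(name) file.path(out_dir, name)
  if (!length(list.files(out_dir))) stop("no stage outputs in ", out_dir)
  lines <- c("# Small RNA pipeline report", "")
  if (file.exists(f("library_stats.tsv"))) {
    st <- read_tsv(f("library_stats.tsv"))
    lines <- c(lines, "## Library statistics",
               sprintf("%s: total=%s clean=%s unique=%s", st$library_id,
                       st$total_reads, st$clean_reads, st$unique_tags), "")
  }
  if (file.exists(f("novel_mirnas.tsv"))) {
    nv <- read_tsv(f("novel_mirnas.tsv"))
    lines <- c(lines, "## Novel miRNAs",
               sprintf("%d novel miRNA(s) with miRNA* evidence", nrow(nv)))
    if (nrow(nv)) {
      lines <- c(lines, sprintf("MFEI range %.2f-%.2f",
                                min(nv$mfei), max(nv$mfei)))
    }
    lines <- c(lines, "")
  }
  de_files <- list.files(out_dir, pattern = "^de_.*\\.tsv$")
  for (df in de_files) {
    de <- read_tsv(f(df))
    cls <- table(factor(de$class, levels = c("up", "down", "ns",
                                             "specific_control",
                                             "specific_treatment")))
    lines <- c(lines, paste0("## DE classes (", sub("\\.tsv$", "", df), ")"),
               paste(names(cls), as.integer(cls), sep = "=", collapse = " "),
               "")
  }
  if (file.exists(f("duplexes.tsv"))) {
    dup <- read_tsv(f("duplexes.tsv"))
    lines <- c(lines, "## siRNA duplexes",
               sprintf("%d duplex pairs (%d tags)", nrow(dup),
                       length(unique(c(dup$tag_a, dup$tag_b)))), "")
  }
  if (file.exists(f("targets.tsv"))) {
    tg <- read_tsv(f("targets.tsv"))
    lines <- c(lines, "## Degradome targets",
               sprintf("%d cleavage events on %d transcripts", nrow(tg),
                       length(unique(tg$transcript))), "")
  }
  if (file.exists(f("loci.tsv"))) {
    lc <- read_tsv(f("loci.tsv"))
    lines <- c(lines, "## Two-hit tasiRNA loci",
               sprintf("%d loci; phases: %s", nrow(lc),
                       paste(lc$phase_count, collapse = ",")), "")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
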