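# Conserved-miRNA matching and novel-miRNA discovery: hairpin excision around
# transcript-mapped tags, mature/miRNA* duplex evaluation on the MFE fold, and
# the precursor statistics (LM, LP, arm, G+C%, dG, AMFE, MFEI).

#' G+C percentage of a sequence
#'
#' @param seq non-empty nucleotide string.
#' @return percentage in `[0, 100]`.
#' @export
gc_percent <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L) {
    stop("gc_percent() needs a single non-empty sequence")
  }
  ch <- strsplit(seq, "")[[1]]
  100 * sum(ch %in% c("G", "C")) / length(ch)
}

#' Adjusted minimal folding free energy (AMFE)
#'
#' AMFE = (-dG / length) x 100, in kcal/mol per 100 nt.
#'
#' @param delta_g folding free energy (kcal/mol, <= 0).
#' @param length precursor length in nt (> 0).
#' @return AMFE (>= 0).
#' @export
compute_amfe <- function(delta_g, length) {
  if (any(length <= 0)) stop("length must be positive")
  if (any(delta_g > 0)) stop("delta_g must be <= 0")
  (-delta_g / length) * 100
}

#' Minimal folding free energy index (MFEI)
#'
#' MFEI = AMFE / (G+C%), the dimensionless index that separates miRNA
#' precursors (typically ~1) from tRNA/rRNA/mRNA backgrounds (~0.6).
#'
#' @inheritParams compute_amfe
#' @param gc G+C content of the precursor expressed as a percentage (> 0).
#' @return the MFEI value (unrounded; tables report it half-up at 2 dp).
#' @export
compute_mfei <- function(delta_g, length, gc) {
  if (any(gc <= 0)) stop("gc percentage must be positive")
  compute_amfe(delta_g, length) / gc
}

#' Evaluate a mature/miRNA* duplex on a folded precursor
#'
#' Locates the expected miRNA* from the pairing table (partner of the mature
#' 5' end plus the canonical 2-nt 3' offset), counts structural duplex
#' mismatches (unpaired mature positions outside its own 2-nt 3' overhang;
#' G:U wobbles pair and do not count), and checks the novel-miRNA criteria:
#' fewer than six duplex mismatches, mature clear of the terminal loop,
#' miRNA* observed in the sequencing tags, and intact 2-nt 3' overhang
#' geometry.
#'
#' @param precursor precursor sequence (candidate window).
#' @param fold a `fold_result` for `precursor` (computed if `NULL`).
#' @param mature_span integer length-2 vector, 1-based inclusive mature span.
#' @param tag_index a `tag_library`, list of them, or character vector of
#'   observed tag sequences (miRNA* evidence).
#' @return an object of class `hairpin_evaluation`; `$pass` is TRUE/FALSE with
#'   `$reason` giving the first failed criterion.
#' @export
evaluate_duplex <- function(precursor, fold = NULL, mature_span, tag_index) {
  if (is.null(fold)) fold <- fold_hairpin(precursor)
  lp <- nchar(precursor)
  m1 <- mature_span[1]; m2 <- mature_span[2]
  stopifnot(m1 >= 1, m2 <= lp, m1 < m2)
  lm <- m2 - m1 + 1L
  pt <- pairing_table(fold$structure)
  tags <- tag_sequences(tag_index)

  res <- list(precursor = precursor, precursor_length = lp,
              mature_span = c(m1, m2), mature_length = lm,
              gc_percent = gc_percent(precursor),
              delta_g = fold$delta_g,
              amfe = compute_amfe(fold$delta_g, lp),
              mfei = if (gc_percent(precursor) > 0)
                compute_mfei(fold$delta_g, lp, gc_percent(precursor)) else NA_real_,
              backend = fold$backend)
  fail <- function(reason) {
    res$pass <- FALSE; res$reason <- reason
    class(res) <- "hairpin_evaluation"
    res
  }

  loops <- hairpin_loops(pt)
  if (!length(loops)) return(fail("no hairpin (fold has no terminal loop)"))

  # duplex region excludes the mature's own 2-nt 3' overhang
  duplex_idx <- m1:(m2 - 2L)
  partners <- pt[duplex_idx]
  if (all(is.na(partners))) return(fail("mature unpaired in fold"))
  res$duplex_mismatches <- sum(is.na(partners))

  # expected star from the helix register: in an antiparallel duplex
  # i + partner(i) is constant, so the median register is robust to bulges
  # at the duplex ends; the star 3' end is the partner of the mature 5' end
  # plus the canonical 2-nt offset
  paired <- duplex_idx[!is.na(partners)]
  register <- median(paired + pt[paired])
  star_end <- as.integer(round(register - m1 + 2L))
  star_start <- star_end - lm + 1L
  res$arm <- if (median(pt[paired]) > m2) "5'" else "3'"
  if (star_start < 1L || star_end > lp) return(fail("star span outside precursor"))
  if (star_start <= m2 && m1 <= star_end) return(fail("star span overlaps mature"))
  res$star_span <- c(star_start, star_end)
  res$star_sequence <- substr(precursor, star_start, star_end)

  # terminal loop between the duplex arms; the mature's 2-nt 3' overhang may
  # legitimately sit at the loop boundary, so overlap is tested against the
  # mature duplex region [m1, m2 - 2]
  lo <- min(m2 - 2L, star_end); hi <- max(m1, star_start)
  inner <- Filter(function(l) l[2] > lo && l[1] < hi, loops)
  if (!length(inner)) return(fail("no terminal loop between mature and star"))
  loop <- inner[[1]]
  res$terminal_loop <- loop
  res$in_terminal_loop <- (m1 <= loop[2] && loop[1] <= m2 - 2L)
  if (res$in_terminal_loop) return(fail("mature overlaps the terminal loop"))

  # 2-nt 3' overhang geometry: the overhang positions of each strand must not
  # pair into the other strand's span. A single such pairing is tolerated as a
  # terminal breathing pair of the MFE fold; two or more mean a blunt duplex.
  ov_m <- pt[(m2 - 1L):m2]
  ov_s <- pt[(star_end - 1L):star_end]
  in_span <- function(i, span) !is.na(i) & i >= span[1] & i <= span[2]
  n_blunt <- sum(in_span(ov_m, res$star_span)) + sum(in_span(ov_s, c(m1, m2)))
  res$overhang_ok <- n_blunt <= 1L
  if (!res$overhang_ok) return(fail("no 2-nt 3' overhang"))

  if (res$duplex_mismatches >= 6L) return(fail("six or more duplex mismatches"))

  if (!(res$star_sequence %in% tags)) return(fail("no miRNA* evidence"))

  res$pass <- TRUE; res$reason <- NA_character_
  class(res) <- "hairpin_evaluation"
  res
}

tag_sequences <- function(tag_index) {
  if (is.null(tag_index)) return(character(0))
  if (inherits(tag_index, "tag_library")) return(names(tag_index$counts))
  if (is.list(tag_index)) {
    return(unique(unlist(lapply(tag_index, tag_sequences), use.names = FALSE)))
  }
  as.character(tag_index)
}

tag_total_counts <- function(tag_index) {
  libs <- if (inherits(tag_index, "tag_library")) list(tag_index) else tag_index
  counts <- unlist(lapply(libs, function(l) l$counts), use.names = FALSE)
  tags <- unlist(lapply(libs, function(l) names(l$counts)), use.names = FALSE)
  vapply(split(counts, tags), sum, 0)
}

#' @export
print.hairpin_evaluation <- function(x, ...) {
  cat("Hairpin evaluation: ", if (isTRUE(x$pass)) "PASS" else
    paste0("FAIL (", x$reason, ")"), "\n", sep = "")
  cat("  LP = ", x$precursor_length, " nt, LM = ", x$mature_length,
      " nt, arm = ", x$arm %||% "?", "\n", sep = "")
  cat(sprintf("  G+C = %.2f%%, dG = %.2f kcal/mol, AMFE = %.2f, MFEI = %.2f\n",
              x$gc_percent, x$delta_g, x$amfe, x$mfei))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Match a tag against a known-miRNA reference
#'
#' End-to-end comparison against each reference mature miRNA allowing up to
#' two substitutions and a length difference of up to 2 nt at the termini.
#' Best (fewest-mismatch) family wins; ties break lexicographically.
#'
#' @param tag tag sequence (caller enforces the eligibility rule: shorter than
#'   24 nt with more than one copy in its library).
#' @param reference named character vector (or `id`/`sequence` data.frame) of
#'   known mature miRNAs; names are family labels.
#' @return a list `(family, mismatches)` or `NULL` when nothing matches.
#' @export
match_conserved <- function(tag, reference) {
  if (is.data.frame(reference)) {
    reference <- setNames(reference$sequence, reference$id)
  }
  if (length(reference) == 0L) stop("empty known-miRNA reference")
  lt <- nchar(tag)
  best_family <- NULL; best_mm <- Inf
  for (i in seq_along(reference)) {
    ref <- reference[[i]]
    lr <- nchar(ref)
    if (abs(lt - lr) > 2L) next
    mm <- terminal_variant_mismatches(tag, ref)
    if (is.na(mm) || mm > 2L) next
    fam <- names(reference)[i]
    if (mm < best_mm || (mm == best_mm && fam < best_family)) {
      best_mm <- mm; best_family <- fam
    }
  }
  if (is.null(best_family)) return(NULL)
  list(family = best_family, mismatches = as.integer(best_mm))
}

# Minimum substitution count over ungapped overlaps whose terminal overhangs
# total <= 2 nt (the shorter/longer-by-up-to-2 length-variant rule).
terminal_variant_mismatches <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- NA_integer_
  for (shift in -2:2) {
    # b[i + shift] aligned to a[i]
    i1 <- max(1L, 1L - shift); i2 <- min(la, lb - shift)
    if (i2 < i1) next
    overhang <- (la - (i2 - i1 + 1L)) + (lb - (i2 - i1 + 1L))
    if (overhang > 2L) next
    mm <- sum(av[i1:i2] != bv[(i1:i2) + shift])
    if (is.na(best) || mm < best) best <- mm
  }
  best
}

#' Identify conserved miRNAs in tag libraries
#'
#' Applies the eligibility rule (tag shorter than 24 nt with more than one
#' copy in at least one library) and [match_conserved()] against the reference.
#'
#' @param tags a `tag_library` or list of them.
#' @param reference known mature miRNAs (named vector or data.frame).
#' @param exclude tags to skip (e.g. structural-RNA annotated sequences).
#' @return data.frame with columns `tag`, `family`, `mismatches`.
#' @export
call_conserved_mirnas <- function(tags, reference, exclude = character(0)) {
  libs <- if (inherits(tags, "tag_library")) list(tags) else tags
  eligible <- unique(unlist(lapply(libs, function(l) {
    names(l$counts)[nchar(names(l$counts)) < 24L & l$counts > 1L]
  }), use.names = FALSE))
  eligible <- setdiff(eligible, exclude)
  rows <- lapply(sort(eligible), function(tg) {
    m <- match_conserved(tg, reference)
    if (is.null(m)) return(NULL)
    data.frame(tag = tg, family = m$family, mismatches = m$mismatches,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(tag = character(0), family = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call novel miRNAs from transcript-mapped tags
#'
#' For each eligible unannotated tag that maps exactly to a transcript,
#' candidate precursor windows extending the tag by {20, 60, 100, 150} nt on
#' each side are excised, folded, and evaluated with [evaluate_duplex()]; the
#' lowest-MFE passing window is kept. When two called tags are each other's
#' miRNA*, the more abundant is reported as the mature.
#'
#' @param tags a `tag_library` or list of them (all libraries pooled for
#'   miRNA* evidence).
#' @param transcripts named character vector or `id`/`sequence` data.frame.
#' @param exclude tag sequences to skip (annotated structural RNAs).
#' @param min_count minimum pooled tag count for a candidate (default 2).
#' @param backend folding backend passed to [fold_sequences()].
#' @return data.frame shaped like the novel-miRNA summary table: `name`,
#'   `mature`, `gene_id`, `lm`, `arm`, `lp`, `gc_percent`, `star`, `delta_g`,
#'   `mfei` (2 dp columns are reported unrounded; use [round_table_2dp()] for
#'   presentation), plus `mature_span` bookkeeping columns.
#' @export
call_novel_mirnas <- function(tags, transcripts, exclude = character(0),
                              min_count = 2L, backend = default_fold_backend()) {
  if (is.data.frame(transcripts)) {
    transcripts <- setNames(transcripts$sequence, transcripts$id)
  }
  libs <- if (inherits(tags, "tag_library")) list(tags) else tags
  totals <- tag_total_counts(libs)
  cand <- names(totals)[totals >= min_count]
  cand <- setdiff(cand, exclude)
  cand <- cand[nchar(cand) >= 18L & nchar(cand) <= 25L]
  if (!length(cand)) return(empty_novel_table())

  hits <- locate_exact(cand, transcripts)
  if (!nrow(hits)) return(empty_novel_table())

  # assemble all candidate windows, then fold them in one batch
  ext <- c(20L, 60L, 100L, 150L)
  windows <- list()
  for (r in seq_len(nrow(hits))) {
    tg <- hits$tag[r]; tid <- hits$subject_id[r]; st <- hits$start[r]
    tlen <- nchar(transcripts[[tid]]); w <- nchar(tg)
    for (L in ext) for (R in ext) {
      a <- max(1L, st - L); b <- min(tlen, st + w - 1L + R)
      lp <- b - a + 1L
      if (lp < 50L || lp > 400L) next
      wseq <- substr(transcripts[[tid]], a, b)
      # cheap pre-screen: a passing duplex needs an approximate reverse
      # complement of the mature core somewhere in the window, so skip
      # windows (and the expensive fold) without one
      if (!has_star_candidate(tg, wseq, st - a + 1L)) next
      windows[[length(windows) + 1L]] <- data.frame(
        tag = tg, transcript = tid, win_start = a, win_end = b,
        m1 = st - a + 1L, m2 = st - a + w,
        seq = wseq, stringsAsFactors = FALSE)
    }
  }
  if (!length(windows)) return(empty_novel_table())
  win <- do.call(rbind, windows)
  win <- win[!duplicated(win[c("tag", "seq", "m1")]), , drop = FALSE]
  folds <- fold_sequences(win$seq, backend = backend)

  all_tags <- tag_sequences(libs)
  records <- list()
  for (key in unique(win$tag)) {
    idx <- which(win$tag == key)
    best <- NULL
    for (r in idx) {
      fr <- structure(list(structure = folds$structure[r],
                           delta_g = folds$delta_g[r],
                           backend = folds$backend[r]), class = "fold_result")
      ev <- evaluate_duplex(win$seq[r], fr, c(win$m1[r], win$m2[r]), all_tags)
      if (isTRUE(ev$pass) && (is.null(best) || ev$delta_g < best$ev$delta_g)) {
        best <- list(ev = ev, row = r)
      }
    }
    if (!is.null(best)) {
      r <- best$row; ev <- best$ev
      records[[key]] <- data.frame(
        mature = key, gene_id = win$transcript[r],
        lm = ev$mature_length, arm = ev$arm, lp = ev$precursor_length,
        gc_percent = ev$gc_percent, star = ev$star_sequence,
        delta_g = ev$delta_g, mfei = ev$mfei,
        precursor_start = win$win_start[r], precursor_end = win$win_end[r],
        count = unname(totals[key]), stringsAsFactors = FALSE)
    }
  }
  if (!length(records)) return(empty_novel_table())
  out <- do.call(rbind, records)

  # mature/star symmetry: the duplex rules pass both strands, so two calls
  # whose precursor windows overlap on the same transcript at non-overlapping
  # mature positions describe one duplex -- keep the more abundant strand
  drop <- rep(FALSE, nrow(out))
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(nrow(out))) {
      if (i == j || drop[j]) next
      if (out$gene_id[i] != out$gene_id[j]) next
      overlap <- out$precursor_start[i] <= out$precursor_end[j] &&
        out$precursor_start[j] <= out$precursor_end[i]
      if (!overlap || out$mature[i] == out$mature[j]) next
      if (out$count[i] < out$count[j] ||
          (out$count[i] == out$count[j] && out$mature[i] > out$mature[j])) {
        drop[i] <- TRUE
      }
    }
  }
  out <- out[!drop, , drop = FALSE]
  out <- out[order(out$gene_id, out$mature), , drop = FALSE]
  out$name <- sprintf("novel-miR-%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[c("name", "mature", "gene_id", "lm", "arm", "lp", "gc_percent",
        "star", "delta_g", "mfei", "precursor_start", "precursor_end", "count")]
}

# TRUE when the window holds a region antisense-pairable (Watson-Crick or
# G:U) with the mature core at all but at most 5 positions, outside the
# mature span itself. A duplex with fewer than six structural mismatches
# cannot exist without one, so windows failing this skip the expensive fold.
has_star_candidate <- function(tag, window_seq, m1, max_unpairable = 5L) {
  core <- substr(tag, 1L, min(19L, nchar(tag)))
  mm <- slide_unpairable(core, window_seq)
  if (!length(mm)) return(FALSE)
  m2 <- m1 + nchar(tag) - 1L
  starts <- seq_along(mm)
  outside <- starts + nchar(core) - 1L < m1 | starts > m2
  any(mm[outside] <= max_unpairable)
}

# Per-start count of core positions that cannot pair (neither Watson-Crick
# nor G:U wobble) with the antisense-facing window bases.
slide_unpairable <- function(core, window_seq) {
  L <- nchar(core); n <- nchar(window_seq)
  if (n < L) return(integer(0))
  mv <- strsplit(core, "")[[1]]
  tv <- strsplit(window_seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "X")
  n_win <- n - L + 1L
  mm <- integer(n_win)
  for (i in seq_len(L)) {
    faced <- tv[(L - i + 1L):(n - i + 1L)]
    pairable <- faced == comp[mv[i]] |
      (mv[i] == "G" & faced == "T") | (mv[i] == "T" & faced == "G")
    mm <- mm + !pairable
  }
  mm
}

empty_novel_table <- function() {
  data.frame(name = character(0), mature = character(0), gene_id = character(0),
             lm = integer(0), arm = character(0), lp = integer(0),
             gc_percent = numeric(0), star = character(0), delta_g = numeric(0),
             mfei = numeric(0), precursor_start = integer(0),
             precursor_end = integer(0), count = numeric(0),
             stringsAsFactors = FALSE)
}

#' Round the presentation columns of a novel-miRNA table at 2 dp (half-up)
#'
#' @param tab output of [call_novel_mirnas()].
#' @return the table with `gc_percent` and `mfei` rounded half-up to 2 dp.
#' @export
round_table_2dp <- function(tab) {
  for (col in intersect(c("gc_percent", "mfei", "amfe"), names(tab))) {
    tab[[col]] <- round_half_up(tab[[col]], 2)
  }
  tab
}

#' Load the bundled cotton novel-miRNA reference table
#'
#' A 24-row reference set of published cotton novel miRNA precursor statistics
#' (mature and star sequences, source gene, LM, arm, LP, G+C%, dG, MFEI) used
#' for regression checks of the MFEI machinery. Two rows (miR1348, miR1356)
#' carry printed MFEI values inconsistent with their own printed dG/LP/G+C%
#' and are flagged in the `mfei_consistent` column rather than corrected.
#'
#' @return data.frame with one row per reference miRNA.
#' @export
novel_mirna_reference <- function() {
  path <- system.file("extdata", "novel_mirna_reference.tsv",
                      package = "saltSRNA", mustWork = TRUE)
  tab <- read_tsv(path)
  recomputed <- round_half_up(compute_mfei(tab$delta_g, tab$lp, tab$gc_percent), 2)
  tab$mfei_consistent <- abs(recomputed - tab$mfei) < 0.005
  tab
}
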