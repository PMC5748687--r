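# miR390/TAS3 two-hit locus detection, 21-nt phase register and phased
# small-RNA (Dk) extraction, tasiRNA-ARF target prediction and the
# regulator/target expression anti-correlation classifier.

#' Find trigger-miRNA recognition sites on transcripts
#'
#' All antisense sites scored with the degradome alignment scorer
#' (G:U = 0.5); a site is flagged `cleaved` when a degradome profile carries
#' signal at its predicted cleavage position.
#'
#' @param trigger trigger miRNA sequence (21 nt).
#' @param transcripts named character vector or `id`/`sequence` data.frame.
#' @param max_score score threshold (default 4.5).
#' @param profiles optional degradome profiles from [build_profile()].
#' @return data.frame `transcript`, `start`, `end`, `score`, `cleaved`.
#' @export
find_trigger_sites <- function(trigger, transcripts, max_score = 4.5,
                               profiles = NULL) {
  if (nchar(trigger) != 21L) stop("trigger must be 21 nt")
  if (is.data.frame(transcripts)) {
    transcripts <- setNames(transcripts$sequence, transcripts$id)
  }
  out <- list()
  for (tid in names(transcripts)) {
    sc <- slide_scores(trigger, transcripts[[tid]])
    hits <- which(sc <= max_score)
    for (p in hits) {
      e <- p + 20L
      site <- predict_cleavage(c(p, e))
      cleaved <- FALSE
      if (!is.null(profiles) && !is.null(profiles[[tid]])) {
        i <- match(site, profiles[[tid]]$positions)
        cleaved <- !is.na(i) && profiles[[tid]]$abundance[i] >= 1
      }
      out[[length(out) + 1L]] <- data.frame(
        transcript = tid, start = p, end = e, score = sc[p],
        cleaved = cleaved, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(transcript = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      cleaved = logical(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect two-hit trigger loci
#'
#' Transcripts carrying at least two non-overlapping trigger sites yield one
#' locus from their closest compliant site pair. Overlapping sites are
#' resolved by discarding the higher-scoring one (ties keep the 5'-most).
#' `spacing_nt` counts nucleotides strictly between the two site spans;
#' `phase_count = round(spacing_nt / 21)`. A locus is `validated` when
#' exactly one of its sites is degradome-cleaved.
#'
#' @param sites data.frame from [find_trigger_sites()].
#' @return data.frame of loci: `transcript`, `site5_start`, `site5_end`,
#'   `site3_start`, `site3_end`, `spacing_nt`, `phase_count`, `validated`,
#'   plus score and cleaved columns per site.
#' @export
detect_two_hit_locus <- function(sites) {
  loci <- list()
  for (tid in unique(sites$transcript)) {
    s <- sites[sites$transcript == tid, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    # resolve overlaps: drop the higher-scoring site; tie keeps the 5'-most
    keep <- rep(TRUE, nrow(s))
    for (i in seq_len(nrow(s))) {
      if (!keep[i]) next
      for (j in seq_len(nrow(s))) {
        if (i >= j || !keep[j]) next
        if (s$start[j] <= s$end[i]) {
          if (s$score[i] > s$score[j]) keep[i] <- FALSE
          else keep[j] <- FALSE
        }
      }
    }
    s <- s[keep, , drop = FALSE]
    if (nrow(s) < 2L) next
    gaps <- s$start[-1] - s$end[-nrow(s)] - 1L
    k <- which.min(gaps)
    s5 <- s[k, ]; s3 <- s[k + 1L, ]
    spacing <- s3$start - s5$end - 1L
    loci[[length(loci) + 1L]] <- data.frame(
      transcript = tid,
      site5_start = s5$start, site5_end = s5$end, site5_score = s5$score,
      site5_cleaved = s5$cleaved,
      site3_start = s3$start, site3_end = s3$end, site3_score = s3$score,
      site3_cleaved = s3$cleaved,
      spacing_nt = spacing,
      phase_count = as.integer(round(spacing / 21)),
      validated = xor(isTRUE(s5$cleaved), isTRUE(s3$cleaved)),
      stringsAsFactors = FALSE)
  }
  if (!length(loci)) {
    return(data.frame(transcript = character(0), site5_start = integer(0),
                      site5_end = integer(0), site5_score = numeric(0),
                      site5_cleaved = logical(0), site3_start = integer(0),
                      site3_end = integer(0), site3_score = numeric(0),
                      site3_cleaved = logical(0), spacing_nt = integer(0),
                      phase_count = integer(0), validated = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, loci)
  rownames(out) <- NULL
  out
}

#' Number of 21-nt phases for an inter-site spacing
#'
#' @param spacing_nt nucleotides strictly between the two trigger sites.
#' @return `round(spacing_nt / 21)`.
#' @export
phase_count <- function(spacing_nt) {
  as.integer(round(spacing_nt / 21))
}

#' Extract phased small RNAs (Dk) from a two-hit locus
#'
#' Consecutive 21-nt windows counted from the phase anchor toward the other
#' site. With the default `site3_cleavage` anchor (the canonical two-hit
#' model) D1 is the 21-mer immediately 5' of the 3'-proximal site's cleavage
#' position and windows run toward the 5' site; with `site5_end` they run 3'
#' from the 5'-proximal site's end. Windows are reported as (+)-strand
#' sequences with summed abundances of exactly matching tags; unsupported
#' windows keep abundance 0. Windows truncated by the locus boundary are
#' flagged, not dropped.
#'
#' @param locus one row of [detect_two_hit_locus()] output.
#' @param transcript_seq the locus transcript sequence.
#' @param tags a `tag_library` or list of them (per-library abundance
#'   columns).
#' @param anchor `"site3_cleavage"` (default) or `"site5_end"`.
#' @param max_k highest phase index to report (default: the locus
#'   `phase_count`).
#' @return data.frame `name` (`Dk(+)`), `k`, `start`, `end`, `sequence`,
#'   `truncated`, one `abundance_*` column per library.
#' @export
extract_phases <- function(locus, transcript_seq, tags,
                           anchor = c("site3_cleavage", "site5_end"),
                           max_k = NULL) {
  anchor <- match.arg(anchor)
  if (is.null(max_k)) max_k <- locus$phase_count
  libs <- if (inherits(tags, "tag_library")) list(tags) else tags
  lib_ids <- vapply(libs, function(l) l$library_id, "")
  rows <- list()
  for (k in seq_len(max_k)) {
    if (anchor == "site3_cleavage") {
      cpos <- locus$site3_end - 9L
      a <- cpos - 21L * k; b <- a + 20L
    } else {
      a <- locus$site5_end + 21L * (k - 1L) + 1L; b <- a + 20L
    }
    truncated <- a < 1L || b > nchar(transcript_seq)
    sq <- if (truncated) NA_character_ else substr(transcript_seq, a, b)
    row <- data.frame(name = sprintf("D%d(+)", k), k = k, start = a, end = b,
                      sequence = sq, truncated = truncated,
                      stringsAsFactors = FALSE)
    for (li in seq_along(libs)) {
      cnt <- if (is.na(sq)) 0 else {
        i <- match(sq, names(libs[[li]]$counts))
        if (is.na(i)) 0 else as.numeric(libs[[li]]$counts[i])
      }
      row[[paste0("abundance_", lib_ids[li])]] <- cnt
    }
    rows[[k]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Predict tasiRNA target genes
#'
#' Genes carrying one or two antisense recognition sites for a 21-nt tasiRNA
#' at alignment score (G:U = 0.5) at most `max_mismatch`.
#'
#' @param tasi tasiRNA sequence (21 nt).
#' @param genes named character vector or `id`/`sequence` data.frame.
#' @param max_mismatch score threshold (default 2.0).
#' @return data.frame `gene`, `n_sites`, `site1_start`, `site1_end`,
#'   `site2_start`, `site2_end` (NA when absent), `score1`, `score2`.
#' @export
predict_tasi_targets <- function(tasi, genes, max_mismatch = 2.0) {
  if (nchar(tasi) != 21L) stop("tasiRNA must be 21 nt")
  sites <- find_trigger_sites(tasi, genes, max_score = max_mismatch)
  out <- list()
  for (gid in unique(sites$transcript)) {
    s <- sites[sites$transcript == gid, , drop = FALSE]
    s <- s[order(s$score, s$start), , drop = FALSE]
    s <- utils::head(s, 2L)
    s <- s[order(s$start), , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      gene = gid, n_sites = nrow(s),
      site1_start = s$start[1], site1_end = s$end[1], score1 = s$score[1],
      site2_start = if (nrow(s) > 1L) s$start[2] else NA_integer_,
      site2_end = if (nrow(s) > 1L) s$end[2] else NA_integer_,
      score2 = if (nrow(s) > 1L) s$score[2] else NA_real_,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(gene = character(0), n_sites = integer(0),
                      site1_start = integer(0), site1_end = integer(0),
                      score1 = numeric(0), site2_start = integer(0),
                      site2_end = integer(0), score2 = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Correlate regulator and target expression across conditions
#'
#' Pearson correlation over a condition series (length >= 3), classified as
#' `negative` (r < -0.5), `positive` (r > 0.5) or `flat`.
#'
#' @param a,b numeric expression series of equal length.
#' @return list `(r, class)`.
#' @export
correlate_series <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L) {
    stop("series must have equal length >= 3")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined for a constant series")
  }
  r <- cor(a, b, method = "pearson")
  cls <- if (r < -0.5) "negative" else if (r > 0.5) "positive" else "flat"
  list(r = r, class = cls)
}
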