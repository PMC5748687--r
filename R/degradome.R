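# Degradome (PARE) machinery: tag preparation, per-transcript degradation
# profiles, miRNA:target antisense alignment scoring (G:U wobble = 0.5),
# cleavage-site prediction at the position pairing miRNA nucleotide 10, and
# the five-category signal classification with t-plot tables.

#' Prepare degradome tags from raw reads
#'
#' Adapter-trimmed fragments are kept at 20--21 nt; tags where a single base
#' exceeds 70% of positions are discarded as polyN (strictly over 70%);
#' structural-RNA annotation with the standard priority is applied before
#' transcript mapping when references are supplied.
#'
#' @param reads character vector of raw reads or a record data.frame.
#' @param adapter3 3' adapter sequence (`NULL` if reads are pre-trimmed).
#' @param refs optional [annotation_set()]; annotated tags are excluded.
#' @return a `tag_library` (library id `"degradome"`) of retained tags plus a
#'   `dropped` attribute of reason counts.
#' @export
prepare_degradome_tags <- function(reads, adapter3 = NULL, refs = NULL) {
  if (is.data.frame(reads)) reads <- reads$sequence
  dropped <- c(no_adapter = 0L, length = 0L, polyN = 0L, annotated = 0L)
  frags <- character(0)
  if (!is.null(adapter3)) {
    for (rd in reads) {
      tr <- trim_adapter(rd, adapter3)
      if (!tr$kept) { dropped["no_adapter"] <- dropped["no_adapter"] + 1L; next }
      frags[length(frags) + 1L] <- tr$insert
    }
  } else frags <- reads
  keep_len <- nchar(frags) %in% c(20L, 21L)
  dropped["length"] <- sum(!keep_len)
  frags <- frags[keep_len]
  if (length(frags)) {
    poly <- vapply(frags, is_polyN, TRUE)
    dropped["polyN"] <- sum(poly)
    frags <- frags[!poly]
  }
  if (!is.null(refs) && length(frags)) {
    ann <- annotate_tags(unique(frags), refs)
    bad <- ann$tag[ann$class != "unannotated"]
    dropped["annotated"] <- sum(frags %in% bad)
    frags <- frags[!frags %in% bad]
  }
  lib <- collapse_reads(frags, "degradome")
  attr(lib, "dropped") <- dropped
  lib
}

# a single base strictly over 70% of positions -> polyN
is_polyN <- function(tag) {
  ch <- strsplit(tag, "")[[1]]
  max(table(ch)) / length(ch) > 0.70
}

#' Build per-transcript degradation profiles
#'
#' Exact sense-strand substring matches only; a tag mapping to several
#' transcripts contributes its full count to each. Profiles are keyed by the
#' tag's 5'-most matched position.
#'
#' @param tags a degradome `tag_library`.
#' @param transcripts named character vector or `id`/`sequence` data.frame.
#' @return named list of `degradation_profile` objects (position -> summed
#'   abundance), one per transcript with at least one mapped tag.
#' @export
build_profile <- function(tags, transcripts) {
  if (is.data.frame(transcripts)) {
    transcripts <- setNames(transcripts$sequence, transcripts$id)
  }
  stopifnot(inherits(tags, "tag_library"))
  hits <- locate_exact(names(tags$counts), transcripts)
  if (!nrow(hits)) return(list())
  hits$count <- as.numeric(tags$counts[hits$tag])
  profs <- list()
  for (tid in unique(hits$subject_id)) {
    h <- hits[hits$subject_id == tid, , drop = FALSE]
    ab <- tapply(h$count, h$start, sum)
    pos <- as.integer(names(ab))
    o <- order(pos)
    profs[[tid]] <- structure(
      list(transcript = tid, positions = pos[o],
           abundance = as.numeric(ab)[o],
           length = nchar(transcripts[[tid]])),
      class = "degradation_profile")
  }
  profs
}

#' @export
print.degradation_profile <- function(x, ...) {
  cat("Degradation profile for", x$transcript, "-", length(x$positions),
      "positions, total abundance", sum(x$abundance), "\n")
  invisible(x)
}

# Pairing cost between a miRNA base and the transcript (target) base it faces:
# 0 for Watson-Crick, 0.5 for G:U wobble, 1 otherwise.
pair_cost <- function(mir_base, target_base) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ifelse(comp[mir_base] == target_base, 0,
         ifelse((mir_base == "G" & target_base == "T") |
                  (mir_base == "T" & target_base == "G"), 0.5, 1))
}

#' Score a miRNA:target-site alignment
#'
#' Antisense orientation (the miRNA 5' end pairs toward the site's 3'
#' boundary). Score = non-G:U mispairs + 0.5 x G:U pairs + gap positions,
#' minimised over the ungapped alignment (equal lengths) or all placements of
#' a single gap run absorbing the length difference (site/miRNA length
#' difference up to 2).
#'
#' @param mirna miRNA sequence (DNA alphabet).
#' @param site transcript subsequence (sense strand).
#' @return the alignment score (>= 0, multiples of 0.5).
#' @export
score_alignment <- function(mirna, site) {
  lm <- nchar(mirna); ls <- nchar(site)
  d <- ls - lm
  if (abs(d) > 2L) stop("site and miRNA lengths differ by more than 2")
  mv <- strsplit(mirna, "")[[1]]
  sv <- rev(strsplit(site, "")[[1]])   # site read 3' -> 5', facing miRNA 5' -> 3'
  if (d == 0L) return(sum(pair_cost(mv, sv)))
  # single gap of |d| positions: in the miRNA when the site is longer
  # (unpaired site bases), in the site when the miRNA is longer (bulged
  # miRNA bases); each gap position costs 1
  k <- abs(d)
  long <- if (d > 0L) sv else mv
  short <- if (d > 0L) mv else sv
  n <- length(short)
  best <- Inf
  for (g in 0:n) {
    aligned_long <- long[-(seq_len(k) + g)]
    cost <- k + if (d > 0L) sum(pair_cost(short, aligned_long)) else
      sum(pair_cost(aligned_long, short))
    if (cost < best) best <- cost
  }
  best
}

#' Predict the cleavage site from an alignment range
#'
#' The cleavage position is the transcript nucleotide pairing with miRNA
#' nucleotide 10 from its 5' end -- the first nucleotide of the 3' cleavage
#' fragment -- i.e. `range_end - 9`.
#'
#' @param alignment_range integer length-2 vector (1-based inclusive).
#' @return cleavage position.
#' @export
predict_cleavage <- function(alignment_range) {
  a <- alignment_range[1]; b <- alignment_range[2]
  if (b - a + 1L < 15L) stop("alignment range shorter than 15 nt")
  b - 9L
}

#' Call miRNA cleavage targets supported by degradome signal
#'
#' Slides each miRNA over every profiled transcript (equal-length antisense
#' windows), keeps candidate sites with alignment score <= `max_score`, and
#' emits one cleavage event per miRNA x site whose predicted cleavage
#' position carries degradome abundance of at least 1. Cleavages guided by
#' different miRNAs at the same site are distinct events.
#'
#' @param mirnas named character vector of miRNA sequences.
#' @param profiles output of [build_profile()], or a named list of them (one
#'   per condition library) for per-library abundance columns.
#' @param transcripts named transcript vector.
#' @param max_score score threshold (default 4.5).
#' @return data.frame of cleavage events: `mirna`, `transcript`, `score`,
#'   `range_start`, `range_end`, `cleavage_site`, `category`, one
#'   `abundance_*` column per library.
#' @export
call_targets <- function(mirnas, profiles, transcripts, max_score = 4.5) {
  if (is.data.frame(transcripts)) {
    transcripts <- setNames(transcripts$sequence, transcripts$id)
  }
  multi <- !inherits(profiles[[1]], "degradation_profile")
  prof_sets <- if (multi) profiles else list(degradome = profiles)
  lib_ids <- names(prof_sets)
  # union of transcripts with any signal
  tids <- unique(unlist(lapply(prof_sets, names)))
  events <- list()
  for (mi in seq_along(mirnas)) {
    mir <- mirnas[[mi]]
    mname <- names(mirnas)[mi]
    for (tid in tids) {
      s <- transcripts[[tid]]
      if (is.null(s) || is.na(s)) next
      sc <- slide_scores(mir, s)
      hits <- which(sc <= max_score)
      for (p in hits) {
        rng <- c(p, p + nchar(mir) - 1L)
        site <- predict_cleavage(rng)
        ab <- vapply(prof_sets, function(ps) {
          pr <- ps[[tid]]
          if (is.null(pr)) return(0)
          i <- match(site, pr$positions)
          if (is.na(i)) 0 else pr$abundance[i]
        }, 0)
        if (sum(ab) < 1) next
        ev <- data.frame(mirna = mname, transcript = tid, score = sc[p],
                         range_start = rng[1], range_end = rng[2],
                         cleavage_site = site, stringsAsFactors = FALSE)
        for (li in lib_ids) ev[[paste0("abundance_", li)]] <- ab[[li]]
        events[[length(events) + 1L]] <- ev
      }
    }
  }
  if (!length(events)) {
    out <- data.frame(mirna = character(0), transcript = character(0),
                      score = numeric(0), range_start = integer(0),
                      range_end = integer(0), cleavage_site = integer(0),
                      stringsAsFactors = FALSE)
    for (li in lib_ids) out[[paste0("abundance_", li)]] <- numeric(0)
    out$category <- integer(0)
    return(out)
  }
  out <- do.call(rbind, events)
  # category against the pooled profile
  pooled <- pool_profiles(prof_sets)
  out$category <- vapply(seq_len(nrow(out)), function(r) {
    assign_category(out$cleavage_site[r], pooled[[out$transcript[r]]])
  }, 0L)
  out <- out[order(out$mirna, out$transcript, out$range_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Vectorised antisense sliding-window scores of a miRNA over a transcript
# (ungapped, equal window length); returns one score per start position.
slide_scores <- function(mirna, transcript) {
  L <- nchar(mirna); n <- nchar(transcript)
  if (n < L) return(numeric(0))
  mv <- strsplit(mirna, "")[[1]]
  tv <- strsplit(transcript, "")[[1]]
  n_win <- n - L + 1L
  sc <- numeric(n_win)
  # miRNA position i faces transcript position p + L - i
  for (i in seq_len(L)) {
    sc <- sc + pair_cost(rep(mv[i], n_win), tv[(L - i + 1L):(n - i + 1L)])
  }
  sc
}

pool_profiles <- function(prof_sets) {
  tids <- unique(unlist(lapply(prof_sets, names)))
  out <- list()
  for (tid in tids) {
    pos <- integer(0); ab <- numeric(0)
    for (ps in prof_sets) {
      pr <- ps[[tid]]
      if (is.null(pr)) next
      pos <- c(pos, pr$positions); ab <- c(ab, pr$abundance)
    }
    agg <- tapply(ab, pos, sum)
    p <- as.integer(names(agg)); o <- order(p)
    out[[tid]] <- structure(list(transcript = tid, positions = p[o],
                                 abundance = as.numeric(agg)[o]),
                            class = "degradation_profile")
  }
  out
}

#' Assign the degradome signal category of a cleavage site
#'
#' Standard five-category convention relative to the transcript's profile:
#' 0 -- site abundance equals the transcript maximum (> 1 read) and the
#' maximum is unique; 1 -- equals a shared maximum (> 1 read); 2 -- below the
#' maximum but above the median of non-zero positions; 3 -- at or below the
#' median (> 1 read); 4 -- exactly one read.
#'
#' @param site cleavage position (must carry signal in the profile).
#' @param profile a `degradation_profile`.
#' @return integer category 0--4.
#' @export
assign_category <- function(site, profile) {
  i <- match(site, profile$positions)
  if (is.na(i)) stop("cleavage site absent from the degradation profile")
  a <- profile$abundance[i]
  mx <- max(profile$abundance)
  med <- median(profile$abundance)
  if (a == 1) return(4L)
  if (a == mx) {
    if (sum(profile$abundance == mx) == 1L) return(0L) else return(1L)
  }
  if (a > med) return(2L)
  3L
}

#' T-plot table for a cleavage event
#'
#' Per-position degradome abundance with the predicted cleavage site marked,
#' ready for plotting; rows sorted by position.
#'
#' @param site predicted cleavage position.
#' @param profile a `degradation_profile`.
#' @return data.frame `position`, `abundance`, `is_cleavage_site`.
#' @export
tplot_data <- function(site, profile) {
  data.frame(position = profile$positions,
             abundance = profile$abundance,
             is_cleavage_site = profile$positions == site)
}

#' Plot a t-plot
#'
#' Base-graphics rendering of [tplot_data()]: abundance by position with the
#' candidate cleavage site highlighted.
#'
#' @inheritParams tplot_data
#' @param ... passed to [graphics::plot()].
#' @export
plot_tplot <- function(site, profile, ...) {
  td <- tplot_data(site, profile)
  graphics::plot(td$position, td$abundance, type = "h",
                 xlab = "transcript position (nt)",
                 ylab = "degradome abundance",
                 main = profile$transcript, ...)
  graphics::points(site, td$abundance[td$is_cleavage_site],
                   col = "red", pch = 19)
  invisible(td)
}
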