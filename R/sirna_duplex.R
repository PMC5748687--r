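# siRNA duplex detection by the Dicer signature (each strand carrying a 2-nt
# 3' overhang over a perfectly complementary core) and mapping of duplexes
# onto repeat/retrotransposon elements.

#' Find siRNA duplex pairs in a tag library
#'
#' A pair (a, b) is a duplex when b's core (all but its last two bases) is the
#' exact reverse complement of a's core, which leaves exactly a 2-nt unpaired
#' 3' overhang on each strand. Under this ungapped rule both strands have
#' equal length. The search is indexed by core sequence (linear time); each
#' unordered pair is reported once and tags may join multiple pairs.
#'
#' @param tags a `tag_library` or character vector of tag sequences
#'   (length-filtered to 21--24 nt for the search).
#' @return data.frame `tag_a`, `tag_b`, `paired_length`, `overhang_a`,
#'   `overhang_b` with `tag_a <= tag_b` lexicographically.
#' @export
find_duplex_pairs <- function(tags) {
  seqs <- if (inherits(tags, "tag_library")) names(tags$counts) else
    as.character(tags)
  seqs <- unique(seqs[nchar(seqs) >= 21L & nchar(seqs) <= 24L])
  if (!length(seqs)) return(empty_duplex_table())
  core <- substr(seqs, 1L, nchar(seqs) - 2L)
  rc_core <- revcomp(core)
  # b is a partner of a iff core(a) == revcomp(core(b))
  grp <- split(seq_along(seqs), core)
  out <- list()
  for (i in seq_along(seqs)) {
    js <- grp[[rc_core[i]]]
    if (is.null(js)) next
    for (j in js) {
      if (seqs[i] <= seqs[j]) {
        out[[length(out) + 1L]] <- data.frame(
          tag_a = seqs[i], tag_b = seqs[j],
          paired_length = nchar(seqs[i]) - 2L,
          overhang_a = substr(seqs[i], nchar(seqs[i]) - 1L, nchar(seqs[i])),
          overhang_b = substr(seqs[j], nchar(seqs[j]) - 1L, nchar(seqs[j])),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty_duplex_table())
  res <- unique(do.call(rbind, out))
  res <- res[order(res$tag_a, res$tag_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_duplex_table <- function() {
  data.frame(tag_a = character(0), tag_b = character(0),
             paired_length = integer(0), overhang_a = character(0),
             overhang_b = character(0), stringsAsFactors = FALSE)
}

#' Map duplexes onto repeat elements
#'
#' A duplex maps to an element when both strands match it perfectly, one on
#' each strand of the element (tag_a sense and tag_b antisense, or the
#' reverse). Per-position small-RNA coverage is accumulated over the matched
#' spans.
#'
#' @param pairs output of [find_duplex_pairs()].
#' @param elements named character vector (or `id`/`sequence` data.frame) of
#'   repeat elements.
#' @return list with `mappings` (data.frame `element`, `tag_a`, `tag_b`,
#'   `start_a`, `start_b`), `coverage` (named list of per-position integer
#'   vectors), and `unmapped` (row indices of unmapped duplexes).
#' @export
map_duplexes_to_elements <- function(pairs, elements) {
  if (is.data.frame(elements)) {
    elements <- setNames(elements$sequence, elements$id)
  }
  coverage <- lapply(elements, function(e) integer(nchar(e)))
  maps <- list(); mapped <- rep(FALSE, nrow(pairs))
  if (nrow(pairs)) {
    sense_hits <- locate_exact(unique(c(pairs$tag_a, pairs$tag_b)), elements)
    anti_hits <- locate_exact(unique(revcomp(c(pairs$tag_a, pairs$tag_b))), elements)
    hit_key <- function(df) paste(df$tag, df$subject_id)
    for (r in seq_len(nrow(pairs))) {
      a <- pairs$tag_a[r]; b <- pairs$tag_b[r]
      for (ori in 1:2) {
        s_tag <- if (ori == 1L) a else b
        as_tag <- if (ori == 1L) b else a
        sh <- sense_hits[sense_hits$tag == s_tag, , drop = FALSE]
        ah <- anti_hits[anti_hits$tag == revcomp(as_tag), , drop = FALSE]
        common <- intersect(sh$subject_id, ah$subject_id)
        for (el in common) {
          sa <- sh$start[sh$subject_id == el][1]
          sb <- ah$start[ah$subject_id == el][1]
          maps[[length(maps) + 1L]] <- data.frame(
            element = el, tag_a = a, tag_b = b,
            start_a = if (ori == 1L) sa else sb,
            start_b = if (ori == 1L) sb else sa,
            stringsAsFactors = FALSE)
          coverage[[el]][sa:(sa + nchar(s_tag) - 1L)] <-
            coverage[[el]][sa:(sa + nchar(s_tag) - 1L)] + 1L
          coverage[[el]][sb:(sb + nchar(as_tag) - 1L)] <-
            coverage[[el]][sb:(sb + nchar(as_tag) - 1L)] + 1L
          mapped[r] <- TRUE
        }
        if (mapped[r]) break
      }
    }
  }
  mappings <- if (length(maps)) {
    m <- do.call(rbind, maps); rownames(m) <- NULL; m
  } else {
    data.frame(element = character(0), tag_a = character(0),
               tag_b = character(0), start_a = integer(0),
               start_b = integer(0), stringsAsFactors = FALSE)
  }
  list(mappings = mappings, coverage = coverage, unmapped = which(!mapped))
}

#' Length distribution of duplex pairs
#'
#' Histogram over the longer strand's length; fractions sum to 1.
#'
#' @param pairs output of [find_duplex_pairs()].
#' @return named numeric vector of fractions per length class.
#' @export
duplex_length_distribution <- function(pairs) {
  if (!nrow(pairs)) stop("empty duplex set")
  len <- pmax(nchar(pairs$tag_a), nchar(pairs$tag_b))
  tab <- table(len)
  setNames(as.numeric(tab) / sum(tab), names(tab))
}
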