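# Raw-read -> clean-tag cascade: 3' adapter trimming, quality filtering,
# the [15, 30] nt insert window, and structural-RNA annotation with the fixed
# priority rule (Rfam-style classes > GenBank-style > polyA).

#' Trim the 3' adapter from a small-RNA read
#'
#' The insert is the read prefix before the left-most adapter match; a match
#' requires at least 6 nt of the adapter prefix with at most one mismatch.
#' Reads whose adapter starts at position 1 are adapter dimers; reads with no
#' adapter match never covered the insert junction. Both are rejections, not
#' errors.
#'
#' @param read read sequence (character) or a record row.
#' @param adapter3 3' adapter sequence (>= 6 nt).
#' @return list `(kept, insert, reason)`; `reason` is `NA`, `"adapter_dimer"`
#'   or `"no_adapter"`.
#' @export
trim_adapter <- function(read, adapter3) {
  if (is.data.frame(read) || is.list(read)) read <- read$sequence
  if (nchar(adapter3) < 6L) stop("adapter must be at least 6 nt")
  pos <- adapter_match_position(read, adapter3)
  if (is.na(pos)) return(list(kept = FALSE, insert = NA_character_, reason = "no_adapter"))
  if (pos == 1L) return(list(kept = FALSE, insert = NA_character_, reason = "adapter_dimer"))
  list(kept = TRUE, insert = substr(read, 1L, pos - 1L), reason = NA_character_)
}

# Left-most offset where >= 6 nt of the adapter prefix matches with <= 1
# mismatch; NA when none.
adapter_match_position <- function(read, adapter) {
  lr <- nchar(read); la <- nchar(adapter)
  rv <- strsplit(read, "")[[1]]; av <- strsplit(adapter, "")[[1]]
  for (i in seq_len(max(0L, lr - 5L))) {
    k <- min(la, lr - i + 1L)
    if (k < 6L) break
    if (sum(rv[i:(i + k - 1L)] != av[1:k]) <= 1L) return(i)
  }
  NA_integer_
}

#' Insert length filter
#'
#' Keep trimmed inserts of 15--30 nt inclusive.
#'
#' @param tag trimmed insert sequence(s).
#' @return logical vector.
#' @export
filter_length <- function(tag) {
  n <- nchar(tag)
  n >= 15L & n <= 30L
}

# TRUE when the read fails the quality rule: any N, or more than 10% of bases
# below Q20 (Phred+33).
low_quality <- function(sequence, quality = NULL) {
  if (grepl("N", sequence, fixed = TRUE)) return(TRUE)
  if (is.null(quality) || is.na(quality)) return(FALSE)
  q <- utf8ToInt(quality) - 33L
  mean(q < 20L) > 0.10
}

#' Build an annotation reference set
#'
#' @param refs named list of character vectors of reference sequences, one per
#'   class; recognised class names: `rRNA`, `tRNA`, `snRNA`, `snoRNA`,
#'   `known_miRNA`, `repeat`.
#' @return an `annotation_set` object with the fixed priority order.
#' @export
annotation_set <- function(refs) {
  if (!length(refs) || is.null(names(refs))) {
    stop("annotation references must be a non-empty named list")
  }
  order <- c("rRNA", "tRNA", "snRNA", "snoRNA", "known_miRNA", "repeat")
  unknown <- setdiff(names(refs), order)
  if (length(unknown)) stop("unknown annotation class: ", unknown[1])
  refs <- refs[intersect(order, names(refs))]
  refs <- lapply(refs, function(x) {
    if (is.data.frame(x)) x$sequence else as.character(x)
  })
  structure(refs, class = "annotation_set")
}

#' Annotate tags by exact substring match with the priority rule
#'
#' Classes are tried in a fixed total order (rRNA, tRNA, snRNA, snoRNA --
#' the Rfam-style structural classes -- then known_miRNA and repeat, then
#' polyA); the first class containing the tag as an exact substring wins.
#' The polyA rule: the tag's 3'-terminal A-run covers at least 80% of its
#' length.
#'
#' @param tags character vector of tag sequences.
#' @param refs an [annotation_set()].
#' @return data.frame with columns `tag`, `class`, `source` (matched reference
#'   index or `NA`).
#' @export
annotate_tags <- function(tags, refs) {
  stopifnot(inherits(refs, "annotation_set"))
  cls <- rep("unannotated", length(tags))
  src <- rep(NA_character_, length(tags))
  remaining <- rep(TRUE, length(tags))
  for (class_name in names(refs)) {
    seqs <- refs[[class_name]]
    ids <- names(seqs)
    if (is.null(ids)) ids <- paste0(class_name, "_", seq_along(seqs))
    if (!any(remaining) || !length(seqs)) next
    hit <- locate_exact(tags[remaining], setNames(seqs, ids))
    if (nrow(hit)) {
      first <- hit[!duplicated(hit$tag), , drop = FALSE]
      m <- match(tags, first$tag)
      sel <- remaining & !is.na(m)
      cls[sel] <- class_name
      src[sel] <- first$subject_id[m[sel]]
      remaining <- remaining & !sel
    }
  }
  # polyA: 3' A-run >= 80% of tag length
  if (any(remaining)) {
    arun <- nchar(sub("^.*?(A*)$", "\\1", tags))
    sel <- remaining & (arun / nchar(tags) >= 0.8)
    cls[sel] <- "polyA"
    remaining <- remaining & !sel
  }
  data.frame(tag = tags, class = cls, source = src, stringsAsFactors = FALSE)
}

#' Run the full preprocessing cascade on raw reads
#'
#' @param reads data.frame from [read_fastq()] (columns `sequence`, optional
#'   `quality`) or a character vector of raw read sequences.
#' @param adapter3 3' adapter sequence.
#' @param library_id condition label for the resulting tag library.
#' @param refs optional [annotation_set()]; when given, annotated structural
#'   tags are reported separately from the clean unannotated library.
#' @return list with `library` (clean `tag_library`), `stats`
#'   (a `clean_read_stats` row), `annotation` (per-tag class table or `NULL`),
#'   and `rejections` (reason counts).
#' @export
preprocess_reads <- function(reads, adapter3, library_id, refs = NULL) {
  if (is.character(reads)) {
    reads <- data.frame(sequence = reads, quality = NA_character_,
                        stringsAsFactors = FALSE)
  }
  if (is.null(reads$quality)) reads$quality <- NA_character_
  total <- nrow(reads)
  hq <- !mapply(low_quality, reads$sequence, reads$quality)
  n_hq <- sum(hq)
  inserts <- character(0)
  reasons <- c(low_quality = total - n_hq, adapter_dimer = 0L,
               no_adapter = 0L, length = 0L)
  for (i in which(hq)) {
    tr <- trim_adapter(reads$sequence[i], adapter3)
    if (!tr$kept) {
      reasons[tr$reason] <- reasons[tr$reason] + 1L
      next
    }
    if (!filter_length(tr$insert)) {
      reasons["length"] <- reasons["length"] + 1L
      next
    }
    inserts[length(inserts) + 1L] <- tr$insert
  }
  lib <- collapse_reads(inserts, library_id)
  ann <- if (!is.null(refs)) annotate_tags(names(lib$counts), refs) else NULL
  stats <- library_stats(total, n_hq, lib)
  list(library = lib, stats = stats, annotation = ann, rejections = reasons)
}

#' Per-library cascade statistics
#'
#' The dataset-summary columns: total reads, high-quality reads, clean reads
#' and unique tags, monotone non-increasing along the cascade.
#'
#' @param total_reads raw read count.
#' @param high_quality reads surviving the quality rule.
#' @param processed the clean `tag_library`.
#' @return one-row data.frame of class `clean_read_stats`.
#' @export
library_stats <- function(total_reads, high_quality, processed) {
  clean <- sum(processed$counts)
  stats <- data.frame(library_id = processed$library_id,
                      total_reads = as.numeric(total_reads),
                      high_quality = as.numeric(high_quality),
                      clean_reads = as.numeric(clean),
                      unique_tags = length(processed$counts))
  if (stats$total_reads < stats$high_quality ||
      stats$high_quality < stats$clean_reads ||
      stats$unique_tags > stats$clean_reads && stats$clean_reads > 0) {
    stop("cascade counts must be monotone non-increasing")
  }
  class(stats) <- c("clean_read_stats", class(stats))
  stats
}
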