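#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor median pnbinom rbinom rlnorm rmultinom runif sd setNames
#' @importFrom utils read.delim write.table head
NULL

#' Round half-up
#'
#' Tables in this field are presented with half-up rounding; base `round()`
#' rounds half to even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded values.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Reverse complement of DNA sequences
#'
#' Vectorised reverse complement over the `{A,C,G,T,N}` alphabet.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Normalize a nucleotide string: uppercase, U -> T.
normalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

valid_alphabet <- function(x) {
  !grepl("[^ACGTN]", x)
}

# Locate exact (sense-strand) occurrences of short tags in a set of subject
# sequences. Uses Biostrings PDict per tag width. Returns a data.frame with
# columns tag, subject_id, start (1-based).
locate_exact <- function(tags, subjects) {
  stopifnot(is.character(tags), is.character(subjects))
  if (length(tags) == 0L || length(subjects) == 0L) {
    return(data.frame(tag = character(0), subject_id = character(0),
                      start = integer(0), stringsAsFactors = FALSE))
  }
  subj_ids <- names(subjects)
  if (is.null(subj_ids)) subj_ids <- as.character(seq_along(subjects))
  sset <- Biostrings::DNAStringSet(subjects)
  tags <- unique(tags)
  out <- vector("list", 0L)
  for (w in sort(unique(nchar(tags)))) {
    tw <- tags[nchar(tags) == w]
    pd <- Biostrings::PDict(tw)
    hit_subjects <- which(colSums(Biostrings::vcountPDict(pd, sset)) > 0L)
    for (j in hit_subjects) {
      m <- Biostrings::matchPDict(pd, sset[[j]])
      starts <- Biostrings::startIndex(m)
      n_hit <- vapply(starts, length, 0L)
      if (sum(n_hit) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        tag = rep(tw, n_hit),
        subject_id = subj_ids[j],
        start = unlist(starts, use.names = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(tag = character(0), subject_id = character(0),
                      start = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Deterministic write of a data.frame as TSV with header.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
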