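# Readers/writers for FASTA/FASTQ and the collapsed-tag library container
# shared by all pipeline stages.

#' Read a FASTA file into a normalized record table
#'
#' Sequences are uppercased and U is normalized to T (the package's canonical
#' comparison alphabet is DNA). Gzip-compressed input is accepted by extension.
#'
#' @param path path to a FASTA file.
#' @return a data.frame with columns `id` and `sequence`, input order preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(set))
  seqs <- normalize_seq(as.character(set))
  if (any(duplicated(ids))) {
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  bad <- which(nchar(seqs) == 0L)
  if (length(bad)) stop("empty sequence for record '", ids[bad[1]], "' in ", path)
  bad <- which(!valid_alphabet(seqs))
  if (length(bad)) {
    stop("record '", ids[bad[1]], "' contains characters outside {A,C,G,T,N,U}")
  }
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Read a FASTQ file (Phred+33) into a record table
#'
#' @param path path to a FASTQ file (optionally gzipped).
#' @return a data.frame with columns `id`, `sequence`, `quality` (Phred+33
#'   strings).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  ids <- sub("\\s.*$", "", names(set))
  if (any(duplicated(ids))) {
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  data.frame(id = ids,
             sequence = normalize_seq(as.character(set)),
             quality = as.character(S4Vectors::mcols(set)$qualities),
             stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param records data.frame with columns `id`, `sequence` (or a named
#'   character vector).
#' @param path output path.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), sequence = unname(records),
                          stringsAsFactors = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", records$id, "\n", records$sequence), con)
  invisible(path)
}

#' Construct a collapsed-tag library
#'
#' A tag library holds one condition's unique small-RNA tags with raw counts
#' and the library's clean-read total (the denominator for per-million
#' normalisation).
#'
#' @param library_id condition label (e.g. `"CK"`, `"T4h"`).
#' @param counts named integer vector, tag sequence -> count (all >= 1).
#' @param total_clean_reads library total; defaults to `sum(counts)`.
#' @return an object of class `tag_library`.
#' @export
tag_library <- function(library_id, counts, total_clean_reads = sum(counts)) {
  counts <- counts[order(-counts, names(counts))]
  storage.mode(counts) <- "integer"
  if (length(counts) && any(counts < 1L)) stop("all tag counts must be >= 1")
  if (any(duplicated(names(counts)))) stop("duplicate tag sequences")
  if (total_clean_reads < sum(counts)) {
    stop("total_clean_reads smaller than the sum of tag counts")
  }
  structure(list(library_id = as.character(library_id),
                 counts = counts,
                 total_clean_reads = as.numeric(total_clean_reads)),
            class = "tag_library")
}

#' @export
print.tag_library <- function(x, ...) {
  cat("Tag library '", x$library_id, "': ", length(x$counts),
      " unique tags, ", format(x$total_clean_reads, big.mark = ","),
      " clean reads\n", sep = "")
  invisible(x)
}

#' Collapse reads into a tag library
#'
#' Counts the multiplicity of each distinct sequence. The library total is the
#' number of input reads; an empty input yields a valid empty library with
#' total 0, which is flagged unusable for normalisation.
#'
#' @param reads character vector of read/tag sequences (or a record data.frame
#'   with a `sequence` column).
#' @param library_id condition label.
#' @return a `tag_library`.
#' @export
collapse_reads <- function(reads, library_id) {
  if (is.data.frame(reads)) reads <- reads$sequence
  n <- length(reads)
  if (n == 0L) {
    lib <- structure(list(library_id = as.character(library_id),
                          counts = setNames(integer(0), character(0)),
                          total_clean_reads = 0),
                     class = "tag_library")
    return(lib)
  }
  tab <- table(reads)
  tag_library(library_id, setNames(as.integer(tab), names(tab)),
              total_clean_reads = n)
}

#' Write a tag library as a deterministic TSV table
#'
#' Rows are ordered by descending count, ties broken lexicographically by tag.
#' The library id and total are kept in `#`-prefixed header comments so that a
#' read-back round-trips the library exactly.
#'
#' @param lib a `tag_library`.
#' @param path output path.
#' @export
write_tag_table <- function(lib, path) {
  stopifnot(inherits(lib, "tag_library"))
  o <- order(-lib$counts, names(lib$counts))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# library_id=", lib$library_id),
               paste0("# total_clean_reads=", format(lib$total_clean_reads, scientific = FALSE)),
               "tag\tcount"), con)
  if (length(lib$counts)) {
    writeLines(paste0(names(lib$counts)[o], "\t", lib$counts[o]), con)
  }
  invisible(path)
}

#' Read a tag-library TSV written by [write_tag_table()]
#'
#' @param path path to the TSV.
#' @return a `tag_library`.
#' @export
read_tag_table <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(paste0("^# ", key, "="), meta, value = TRUE)
    if (!length(hit)) stop("missing '", key, "' header in ", path)
    sub(paste0("^# ", key, "="), "", hit[1])
  }
  body <- lines[!grepl("^#", lines)]
  df <- read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                   stringsAsFactors = FALSE)
  counts <- setNames(as.integer(df$count), df$tag)
  lid <- get_meta("library_id")
  total <- as.numeric(get_meta("total_clean_reads"))
  if (length(counts) == 0L) {
    return(structure(list(library_id = lid, counts = setNames(integer(0), character(0)),
                          total_clean_reads = total), class = "tag_library"))
  }
  tag_library(lid, counts, total)
}
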