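# Secondary-structure folding contract. The default backend shells out to
# ViennaRNA's RNAfold (batched over stdin); a pure-R base-pair-maximisation
# fallback with a simplified stacking-free energy model keeps the package
# functional without the external binary. The backend identity is recorded in
# every FoldResult.

fold_backend_available <- function() {
  nzchar(Sys.which("RNAfold"))
}

default_fold_backend <- function() {
  opt <- getOption("saltSRNA.fold_backend", NULL)
  if (!is.null(opt)) return(opt)
  if (fold_backend_available()) "viennarna" else "internal"
}

#' Fold RNA/DNA sequences and return minimum-free-energy structures
#'
#' Batch interface used by the hairpin machinery. Each result carries a
#' dot-bracket `structure`, the folding free energy `delta_g` (kcal/mol) and
#' the `backend` that produced it.
#'
#' @param seqs character vector of sequences (DNA alphabet; T is treated as U).
#' @param backend `"viennarna"` (RNAfold CLI) or `"internal"`
#'   (base-pair maximisation with a simplified energy model).
#' @return a data.frame with columns `sequence`, `structure`, `delta_g`,
#'   `backend`.
#' @export
fold_sequences <- function(seqs, backend = default_fold_backend()) {
  stopifnot(is.character(seqs))
  if (length(seqs) == 0L) {
    return(data.frame(sequence = character(0), structure = character(0),
                      delta_g = numeric(0), backend = character(0)))
  }
  backend <- match.arg(backend, c("viennarna", "internal"))
  if (backend == "viennarna" && !fold_backend_available()) backend <- "internal"
  if (backend == "viennarna") {
    res <- fold_viennarna(seqs)
  } else {
    res <- data.frame(structure = vapply(seqs, nussinov_structure, ""),
                      stringsAsFactors = FALSE)
    res$delta_g <- mapply(simple_energy, seqs, res$structure)
  }
  data.frame(sequence = seqs, structure = res$structure,
             delta_g = res$delta_g, backend = backend,
             stringsAsFactors = FALSE)
}

#' Fold a candidate precursor window
#'
#' Single-sequence wrapper around [fold_sequences()] enforcing the candidate
#' window contract (50--400 nt, at most 10% N).
#'
#' @param seq candidate precursor sequence.
#' @inheritParams fold_sequences
#' @return a list of class `fold_result` with `structure`, `delta_g`,
#'   `backend`.
#' @export
fold_hairpin <- function(seq, backend = default_fold_backend()) {
  n <- nchar(seq)
  if (n < 50 || n > 400) stop("candidate window must be 50-400 nt, got ", n)
  n_frac <- lengths(regmatches(seq, gregexpr("N", seq))) / n
  if (n_frac > 0.10) stop("sequence rejected: N fraction exceeds 10%")
  r <- fold_sequences(seq, backend = backend)
  structure(list(structure = r$structure[1], delta_g = r$delta_g[1],
                 backend = r$backend[1]), class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat("MFE structure (", x$backend, "): dG = ", x$delta_g, " kcal/mol\n",
      x$structure, "\n", sep = "")
  invisible(x)
}

fold_viennarna <- function(seqs) {
  rna <- chartr("T", "U", seqs)
  input <- paste0(">s", seq_along(rna), "\n", rna)
  out <- suppressWarnings(
    system2("RNAfold", c("--noPS"), input = input, stdout = TRUE))
  # output: >id / sequence / structure (energy) triplets
  struct_lines <- out[seq(3, length(out), by = 3)]
  m <- regmatches(struct_lines,
                  regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", struct_lines))
  bad <- which(lengths(m) != 3L)
  if (length(bad)) stop("unparseable RNAfold output: ", struct_lines[bad[1]])
  data.frame(structure = vapply(m, `[`, "", 2),
             delta_g = as.numeric(vapply(m, `[`, "", 3)),
             stringsAsFactors = FALSE)
}

# --- internal fallback -------------------------------------------------------

# Nussinov-style maximum base pairing (min hairpin loop 3) with traceback.
# G:U wobbles allowed. O(n^2) memory; candidate windows are <= 400 nt.
nussinov_structure <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  can_pair <- function(a, b) {
    (a == "A" && b == "T") || (a == "T" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G") ||
      (a == "G" && b == "T") || (a == "T" && b == "G")
  }
  if (n < 5L) return(paste(rep(".", n), collapse = ""))
  M <- matrix(0L, n, n)
  for (span in 4:(n - 1)) {
    for (i in 1:(n - span)) {
      j <- i + span
      best <- M[i, j - 1L]
      # j pairs with some k in [i, j-4]
      for (k in i:(j - 4L)) {
        if (can_pair(s[k], s[j])) {
          left <- if (k > i) M[i, k - 1L] else 0L
          v <- left + M[k + 1L, j - 1L] + 1L
          if (v > best) best <- v
        }
      }
      M[i, j] <- best
    }
  }
  db <- rep(".", n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (j - i < 4L) next
    if (M[i, j] == M[i, j - 1L]) {
      stack[[length(stack) + 1L]] <- c(i, j - 1L)
      next
    }
    done <- FALSE
    for (k in i:(j - 4L)) {
      if (can_pair(s[k], s[j])) {
        left <- if (k > i) M[i, k - 1L] else 0L
        if (left + M[k + 1L, j - 1L] + 1L == M[i, j]) {
          db[k] <- "("; db[j] <- ")"
          if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
          stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
          done <- TRUE
          break
        }
      }
    }
    if (!done) stack[[length(stack) + 1L]] <- c(i, j - 1L)
  }
  paste(db, collapse = "")
}

# Simplified energy: -3 kcal/mol per G:C pair, -2 per A:U, -1 per G:U.
# Not a thermodynamic model; only orders structures sensibly for the fallback.
simple_energy <- function(seq, structure) {
  pt <- pairing_table(structure)
  s <- strsplit(seq, "")[[1]]
  idx <- which(!is.na(pt) & seq_along(pt) < pt)
  if (!length(idx)) return(0)
  e <- 0
  for (i in idx) {
    p <- sort(c(s[i], s[pt[i]]))
    e <- e - switch(paste(p, collapse = ""),
                    "CG" = 3, "AT" = 2, "GT" = 1, 0)
  }
  e
}

# Dot-bracket -> pairing partner vector (NA when unpaired).
pairing_table <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  n <- length(ch)
  pt <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  pt
}

# Hairpin (terminal) loops of a structure: maximal unpaired runs [a, b] whose
# flanking positions pair with each other (pt[a-1] == b+1).
hairpin_loops <- function(pt) {
  n <- length(pt)
  unp <- is.na(pt)
  loops <- list()
  i <- 1L
  while (i <= n) {
    if (unp[i]) {
      j <- i
      while (j < n && unp[j + 1L]) j <- j + 1L
      if (i > 1L && j < n && !is.na(pt[i - 1L]) && pt[i - 1L] == j + 1L) {
        loops[[length(loops) + 1L]] <- c(i, j)
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  loops
}
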