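# TPM normalisation, the exact two-library digital-expression test
# (Audic-Claverie conditional test), DE classification at the raw p < 0.01,
# |log2 ratio| > 1 thresholds, and the 2^(-ddCt) qRT-PCR helper.

#' Tags per million clean reads
#'
#' @param count raw tag/miRNA count (>= 0).
#' @param total library clean-read total (>= 1).
#' @return TPM value(s).
#' @export
tpm <- function(count, total) {
  if (any(total < 1)) stop("library total must be >= 1")
  if (any(count < 0)) stop("counts must be non-negative")
  1e6 * count / total
}

#' Exact two-library count test
#'
#' Two-sided p-value of the Audic-Claverie conditional test for a feature
#' observed `x` times in a library of `n1` reads and `y` times in a library
#' of `n2` reads. Conditional on `x`, `y` follows a negative binomial with
#' size `x + 1` and success probability `n1 / (n1 + n2)`; the two-sided
#' p-value doubles the smaller tail, capped at 1. The conditional test is not
#' symmetric in which library is conditioned on, so the reported p-value is
#' the smaller of the two orientations, making `p(x, y) = p(y, x)` exact.
#' Evaluated through `pnbinom()`, stable for counts up to 1e7.
#'
#' @param x,y counts in the two libraries.
#' @param n1,n2 library totals (>= 1).
#' @return p-value in (0, 1].
#' @export
exact_count_test <- function(x, y, n1, n2) {
  if (any(c(x, y) < 0)) stop("counts must be non-negative")
  if (any(c(n1, n2) < 1)) stop("library totals must be >= 1")
  pmin(ac_directed(x, y, n1, n2), ac_directed(y, x, n2, n1))
}

# one orientation of the Audic-Claverie conditional test
ac_directed <- function(x, y, n1, n2) {
  p <- n1 / (n1 + n2)
  lower <- pnbinom(y, size = x + 1, prob = p)
  upper <- 1 - pnbinom(y - 1, size = x + 1, prob = p)
  pmin(1, 2 * pmin(lower, upper))
}

#' Classify a feature's differential expression between two libraries
#'
#' A feature with one zero count and the other at or above `min_specific` is
#' library-specific; otherwise the log2 TPM ratio (treatment over control) and
#' the exact-test p-value decide `up`/`down` at p < `p_threshold` and
#' |log2 ratio| strictly greater than `lfc_threshold`, else `ns`. Features
#' with both counts zero are excluded upstream.
#'
#' @param count_c,count_t raw counts in control and treatment.
#' @param total_c,total_t clean-read totals.
#' @param p_threshold raw p-value threshold (default 0.01).
#' @param lfc_threshold |log2 ratio| threshold (default 1, strict).
#' @param min_specific minimal non-zero count for a `specific_*` call
#'   (default 2).
#' @return one-row data.frame: `count_c`, `count_t`, `tpm_c`, `tpm_t`,
#'   `log2_ratio`, `p_value`, `class`.
#' @export
classify_de <- function(count_c, count_t, total_c, total_t,
                        p_threshold = 0.01, lfc_threshold = 1,
                        min_specific = 2L) {
  if (count_c == 0 && count_t == 0) {
    stop("feature with zero counts in both libraries must be excluded")
  }
  tc <- tpm(count_c, total_c); tt <- tpm(count_t, total_t)
  p <- exact_count_test(count_c, count_t, total_c, total_t)
  lr <- NA_real_
  cls <- "ns"
  if (xor(count_c == 0, count_t == 0) &&
      max(count_c, count_t) >= min_specific) {
    cls <- if (count_c == 0) "specific_treatment" else "specific_control"
  } else if (count_c > 0 && count_t > 0) {
    lr <- log2(tt / tc)
    if (p < p_threshold && abs(lr) > lfc_threshold) {
      cls <- if (lr > 0) "up" else "down"
    }
  }
  data.frame(count_c = count_c, count_t = count_t, tpm_c = tc, tpm_t = tt,
             log2_ratio = lr, p_value = p, class = cls,
             stringsAsFactors = FALSE)
}

#' Differential-expression table for a control/treatment library pair
#'
#' @param lib_c,lib_t control and treatment `tag_library` objects.
#' @param features optional named character vector (feature id -> tag
#'   sequence); defaults to all tags present in either library.
#' @param ... thresholds passed to [classify_de()].
#' @return data.frame with one row per feature (both-zero features dropped),
#'   ordered by feature id, plus a `summary` attribute of per-class counts.
#' @export
de_table <- function(lib_c, lib_t, features = NULL, ...) {
  stopifnot(inherits(lib_c, "tag_library"), inherits(lib_t, "tag_library"))
  if (lib_c$total_clean_reads < 1 || lib_t$total_clean_reads < 1) {
    stop("library with zero total is unusable for normalisation")
  }
  if (is.null(features)) {
    seqs <- sort(union(names(lib_c$counts), names(lib_t$counts)))
    features <- setNames(seqs, seqs)
  }
  xc <- unname(ifelse(is.na(lib_c$counts[features]), 0L, lib_c$counts[features]))
  xt <- unname(ifelse(is.na(lib_t$counts[features]), 0L, lib_t$counts[features]))
  keep <- xc + xt > 0
  rows <- mapply(function(c0, t0) classify_de(c0, t0, lib_c$total_clean_reads,
                                              lib_t$total_clean_reads, ...),
                 xc[keep], xt[keep], SIMPLIFY = FALSE)
  out <- cbind(data.frame(feature = names(features)[keep],
                          stringsAsFactors = FALSE),
               do.call(rbind, rows))
  out <- out[order(out$feature), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "summary") <- table(factor(out$class,
    levels = c("up", "down", "ns", "specific_control", "specific_treatment")))
  out
}

#' Relative expression by the 2^(-ddCt) method
#'
#' @param dct_treatment,dct_control delta-Ct values (target Ct minus reference
#'   Ct) for treatment and control.
#' @return fold change `2^-(dct_treatment - dct_control)`.
#' @export
ddct <- function(dct_treatment, dct_control) {
  2^(-(dct_treatment - dct_control))
}
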