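# Shared fixtures. The default synthetic benchmark is generated once per test
# run and cached; individual tests derive smaller configurations as needed.

benchmark_env <- new.env(parent = emptyenv())

# Default-condition benchmark (seeded): transcripts, truth, three small-RNA
# libraries, degradome libraries.
default_benchmark <- function() {
  if (is.null(benchmark_env$sim)) {
    benchmark_env$sim <- simulate_experiment(simulation_config(seed = 101))
  }
  benchmark_env$sim
}

# Novel-miRNA calls on the default benchmark (the most expensive stage),
# cached alongside.
benchmark_novel_calls <- function() {
  if (is.null(benchmark_env$novel)) {
    sim <- default_benchmark()
    excl <- repeat_annotated_tags(sim$srna, sim$truth)
    benchmark_env$novel <- call_novel_mirnas(sim$srna, sim$transcripts,
                                             exclude = excl)
  }
  benchmark_env$novel
}

# Construct a perfect hairpin: mature + loop + (star core = revcomp of the
# mature minus its 2-nt 3' overhang) + star overhang, with optional flanks.
make_hairpin <- function(mature = "TGAGGTAGTAGGTTGTATAGT",
                         loop = "GAATCGCATTCAGGA",
                         flank5 = "", flank3 = "") {
  star <- paste0(revcomp(substr(mature, 1, nchar(mature) - 2)),
                 substr(mature, nchar(mature) - 1, nchar(mature)))
  seq <- paste0(flank5, mature, loop, star, flank3)
  list(sequence = seq, mature = mature, star = star,
       mature_span = c(nchar(flank5) + 1L, nchar(flank5) + nchar(mature)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force frequency count oracle for collapse_reads.
oracle_collapse <- function(reads) {
  u <- unique(reads)
  setNames(vapply(u, function(s) sum(reads == s), 0L), u)
}
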