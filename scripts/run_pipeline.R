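#!/usr/bin/env Rscript
# Thin shell entry point over the package pipeline:
#   Rscript scripts/run_pipeline.R --seed 1 --out results/run1 [--depth N]
#   [--stages simulate,preprocess,mirna,de,sirna,degradome,tasi] [--report]

suppressPackageStartupMessages({
  library(optparse)
  library(saltSRNA)
})

opt_list <- list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "pipeline_out"),
  make_option("--depth", type = "integer", default = 50000L),
  make_option("--stages", type = "character",
              default = "simulate,preprocess,mirna,de,sirna,degradome,tasi"),
  make_option("--max-score", type = "double", default = 4.5, dest = "max_score"),
  make_option("--p-threshold", type = "double", default = 0.01, dest = "p_threshold"),
  make_option("--report", action = "store_true", default = FALSE)
)
opts <- parse_args(OptionParser(option_list = opt_list))

status <- tryCatch({
  cfg <- pipeline_config(
    sim = simulation_config(seed = opts$seed, depth = opts$depth),
    p_threshold = opts$p_threshold, max_score = opts$max_score,
    stages = strsplit(opts$stages, ",")[[1]])
  run_pipeline(cfg, opts$out)
  if (opts$report) {
    writeLines(build_report(opts$out, file.path(opts$out, "report.txt")))
  }
  0L
}, error = function(e) {
  message("pipeline error: ", conditionMessage(e))
  if (grepl("stage failure", conditionMessage(e))) 2L else 1L
})
quit(status = status)
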