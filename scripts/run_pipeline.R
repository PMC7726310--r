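#!/usr/bin/env Rscript
# Thin command-line wrapper around petmsm::run_pipeline().
#
# Usage:
#   Rscript scripts/run_pipeline.R --scenario dog --n 5000 --seed 1 \
#       --models 1,7 --out-dir results/demo [--sensitivity]
#   Rscript scripts/run_pipeline.R --tables-dir path/to/registry \
#       --models 1,7 --out-dir results/from_tables

suppressPackageStartupMessages(library(petmsm))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1L]
}

tables_dir <- get_arg("--tables-dir")
if (is.null(tables_dir)) {
  config <- demo_truth_config(get_arg("--scenario", "dog"),
                              n_households = as.integer(get_arg("--n", "5000")),
                              seed = as.integer(get_arg("--seed", "1")))
} else {
  config <- tables_dir
}
models <- strsplit(get_arg("--models", "1,7"), ",")[[1]]
out <- run_pipeline(config,
                    out_dir = get_arg("--out-dir", "results/pipeline"),
                    models = models,
                    sensitivity = "--sensitivity" %in% args,
                    verbose = TRUE)
print(out$ladder)
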