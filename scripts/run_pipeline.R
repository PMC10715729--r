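#!/usr/bin/env Rscript

# Thin shell wrapper around brumate::run_all(). Usage:
#   Rscript scripts/run_pipeline.R --input data_dir --out results_dir \
#       [--buffer 0] [--n-boot 100] [--n-perm 999] [--seed 1]
# or, to rehearse on synthetic data at the study's scale:
#   Rscript scripts/run_pipeline.R --simulate --out results_dir --seed 1

suppressMessages(library(brumate))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
seed <- as.integer(get_arg("--seed", "1"))
out <- get_arg("--out", "pipeline_out")
buffer <- as.numeric(get_arg("--buffer", "0"))
n_boot <- as.integer(get_arg("--n-boot", "100"))
n_perm <- as.integer(get_arg("--n-perm", "999"))
input <- get_arg("--input")
benchmark <- get_arg("--benchmark")

study <- NULL
if ("--simulate" %in% args) {
  message("simulating a study-scale dataset (seed ", seed, ")")
  study <- simulate_study(seed = seed)
} else if (is.null(input)) {
  stop("provide --input <dir> or --simulate")
}

cfg <- pipeline_config(study = study, input_dir = input, out_dir = out,
                       buffer = buffer, n_boot = n_boot, n_perm = n_perm,
                       seed = seed, benchmark_dir = benchmark)
run_all(cfg)
message("outputs written to ", out)
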