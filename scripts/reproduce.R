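#!/usr/bin/env Rscript

# Thin command-line wrapper over singletone::reproduce_experiment():
# plan, simulate, analyze one design and write all artifacts.
# Usage: Rscript scripts/reproduce.R --experiment exp2 --seed 1 \
#          --out results/exp2 [--participants 20] [--audio] [--no-figures]

suppressPackageStartupMessages(library(singletone))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1]
}
experiment <- get_arg("--experiment", "exp1")
seed <- as.integer(get_arg("--seed", "1"))
out <- get_arg("--out", file.path("results", experiment))
n <- get_arg("--participants", NA)
n <- if (is.na(n)) NULL else as.integer(n)

analysis <- reproduce_experiment(
  experiment, seed = seed, out_dir = out, n_participants = n,
  write_audio = "--audio" %in% args,
  figures = !("--no-figures" %in% args)
)
print(analysis)
message("artifacts written to ", out)
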