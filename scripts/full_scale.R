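#!/usr/bin/env Rscript
# Full-scale reproduction run: 1000 synthetic sequences of 125 frames at
# 128x128, AlexNet-geometry encoder (256x13x13 feature maps), C-GRU,
# 43264 -> 4096 -> 1024 -> 1 head, Adam lr 1e-4, lambda = 1e-6, 100 epochs.
# This is a multi-hour computation (days on a single CPU; the architecture
# is sized for GPU-class throughput) and needs several GiB of disk for the
# dataset; it is provided for completeness and is not part of any test run.
#
# Usage: Rscript scripts/full_scale.R [--seed S] [--data DIR] [--out RUNDIR]

suppressPackageStartupMessages(library(vesseltrace))

args <- commandArgs(trailingOnly = TRUE)
flag <- function(name, default) {
  i <- which(args == paste0("--", name))
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
seed <- as.integer(flag("seed", 1))
data_dir <- flag("data", "scratch/full_scale_data")
out_dir <- flag("out", "scratch/full_scale_run")

if (!file.exists(file.path(data_dir, "manifest.json"))) {
  message("generating 1000 sequences under ", data_dir, " ...")
  generate_dataset(sim_config(), 1000, seed = seed, dir = data_dir)
}

seqs <- load_dataset(data_dir)
sp <- split_dataset(seqs, seed = seed)
message(sprintf("split: %d train / %d val / %d test",
                length(sp$train), length(sp$val), length(sp$test)))

model <- init_model(model_config("alexnet"), seed = seed)
fit <- train_model(model, sp$train, sp$val,
                   train_config(learning_rate = 1e-4, epochs = 100,
                                lambda = 1e-6, seed = seed, verbose = TRUE))

dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
save_model(fit, file.path(out_dir, "checkpoint.rds"))
readr::write_csv(fit$history, file.path(out_dir, "history.csv"))

met <- evaluate_model(fit, sp$test, units = "pixel")
print(met)
jsonlite::write_json(list(aggregate = met$aggregate,
                          per_sequence = met$per_sequence),
                     file.path(out_dir, "metrics.json"),
                     auto_unbox = TRUE, digits = NA, dataframe = "rows")
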