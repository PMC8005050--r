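#!/usr/bin/env Rscript
# Simulate one observation campaign on three giraffes and export it through
# both device models in their on-disk dialects, plus the observers' ethogram.
# The raw exports are large and go under scratch/; later steps read them back
# through the package's ingestion path, exactly as real logger files would be.

suppressPackageStartupMessages(library(ethoacc))

data_dir <- "scratch/data"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- scenario_config(seed = 1)  # 3 animals, 8 behaviors + STA_STILL, 8 h
truth <- generate_truth(cfg)
write_ethogram_csv(truth$ethogram, file.path(data_dir, "ethogram.csv"))

cat(sprintf("scenario seed %d: %d individuals, %d behavior codes, %.0f s sessions\n",
            cfg$seed, length(cfg$individuals), length(cfg$signatures),
            cfg$session_length))
cat(sprintf("ethogram: %d bouts (mean dwell %.0f s)\n",
            nrow(truth$ethogram),
            mean(truth$ethogram$end - truth$ethogram$start)))

for (ind in cfg$individuals) {
  bursts <- render_device(truth, ind, burst_device())
  write_burst_csv(bursts, file.path(data_dir, paste0(ind, "_burst.csv")),
                  burst_device())
  stream <- render_device(truth, ind, continuous_device())
  write_continuous_csv(stream,
                       file.path(data_dir, paste0(ind, "_continuous.csv")))
  cat(sprintf("%s: %d bursts (82 samples each), %d continuous samples (%.1f%% dropout)\n",
              ind, length(bursts), nrow(stream$samples),
              100 * (1 - nrow(stream$samples) / cfg$session_length)))
}
cat("wrote device exports and ethogram to", data_dir, "\n")
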