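#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic longitudinal experiment.
#
# Seven developmental stages (DIV3..DIV28) under two indicator conditions:
# "healthy" (GCaMP-X-like, low toxicity) and "toxic" (unprotected sensor).
# Each stage x condition gets one field of view of spontaneous-activity
# traces plus a cohort of rendered neuron images. Everything downstream
# reads the files written here, so the whole analysis is reproducible from
# this seed.

library(catrace)

seed <- 20260926
out <- "results/run"

cfg <- list(
  seed = seed, out_dir = out, stages = "simulate",
  simulate = list(n_cells = 15, duration_s = 600, fs = 5, n_images = 8)
)
run_pipeline(cfg)

n_files <- length(list.files(file.path(out, "simulated")))
cat("Simulated 7 stages x 2 conditions (15 cells x 600 s @ 5 Hz each,\n",
    "8 images per view);", n_files, "files under", file.path(out, "simulated"),
    "\n")
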