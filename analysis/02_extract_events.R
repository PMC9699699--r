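#!/usr/bin/env Rscript
# Stage 2 — dF/F0 extraction and 3-SD event detection.
#
# For every simulated view: subtract the background, find F0 as the
# minimal-mean 5-sample rest window, convert to dF/F0, detect events by the
# three-standard-deviations rule and fill the waveform metrics (amplitude,
# FWHM, 50% rise/decay times). Writes per-view event CSVs next to the
# traces, plus a per-view functional summary used by stage 5.

library(catrace)

run <- "results/run"
files <- list.files(file.path(run, "simulated"), pattern = "_traces\\.csv$",
                    full.names = TRUE)
rows <- list(); cell_rows <- list()
for (f in files) {
  tr <- read_traces_csv(f)
  parts <- strsplit(tr$stage, ":")[[1]]
  tabs <- list(); dffs <- list()
  for (ci in seq_len(nrow(tr$traces))) {
    x <- tr$traces[ci, ] - tr$background
    dff <- to_dff(x, f0 = compute_f0(x), fs = tr$fs)
    tabs[[ci]] <- waveform_metrics(dff, detect_events(dff))
    dffs[[ci]] <- dff
  }
  names(tabs) <- rownames(tr$traces)
  write_events_csv(tabs, sub("_traces", "_events", f))
  freq <- vapply(tabs, event_frequency_mHz, numeric(1))
  cell_rows[[f]] <- data.frame(
    div = as.integer(sub("DIV", "", parts[1])), condition = parts[2],
    cell = names(tabs), frequency_mHz = freq,
    amplitude = vapply(tabs, function(t) mean(t$amplitude), numeric(1)),
    fwhm = vapply(tabs, function(t) mean(t$fwhm, na.rm = TRUE), numeric(1)))
  rows[[f]] <- data.frame(
    div = as.integer(sub("DIV", "", parts[1])), condition = parts[2],
    frequency_mHz = mean(freq),
    amplitude = mean(unlist(lapply(tabs, `[[`, "amplitude")), na.rm = TRUE),
    fwhm = mean(unlist(lapply(tabs, `[[`, "fwhm")), na.rm = TRUE),
    n_events = sum(vapply(tabs, nrow, integer(1))))
}
summary <- do.call(rbind, rows); rownames(summary) <- NULL
write.csv(summary, file.path(run, "functional_summary.csv"), row.names = FALSE)
cells <- do.call(rbind, cell_rows); rownames(cells) <- NULL
write.csv(cells, file.path(run, "cell_metrics.csv"), row.names = FALSE)

cat("Per-view functional metrics:\n")
print(summary, digits = 3)
cat("\nHealthy frequency falls ~150 -> ~20 mHz across DIV while amplitude",
    "rises;\nthe toxic condition collapses after DIV10 with",
    sprintf("%.1f-fold longer FWHM at DIV28.\n",
            summary$fwhm[summary$div == 28 & summary$condition == "toxic"] /
              summary$fwhm[summary$div == 28 & summary$condition == "healthy"]))
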