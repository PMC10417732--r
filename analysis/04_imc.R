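#!/usr/bin/env Rscript

# Targeted proteomics on the detected candidates: simulated ion counts with
# additive background, negative-mask background subtraction, WBC-anchored
# z-scores, and per-marker positivity calls.

suppressPackageStartupMessages(library(crcdeconv))

in_sim <- "results/sim"
in_det <- "results/detect"
out_dir <- "results/imc"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 20260925

meta <- read.delim(file.path(in_sim, "draw_metadata.tsv"))
panel <- default_panel()
write.csv(panel, file.path(out_dir, "panel.csv"), row.names = FALSE)

for (d in meta$draw_id) {
  cand <- read.delim(file.path(in_det, paste0("candidates_", d, ".tsv")))
  cfg <- sim_config(seed = child_seed(seed, paste0("imc:", d)),
                    n_rare = nrow(cand),
                    composition = c(EPI.CTC = 1 / 3, pEMT.CTC = 1 / 3, CEC = 1 / 3))
  labels <- setNames(cand$truth_label, cand$cell_id)
  sim <- simulate_imc(labels, cfg, panel = panel, roi = paste0("ROI_", d))
  corr <- subtract_background(sim$ions, sim$background)
  z <- zscore_normalize(corr, population = "reference")
  pos <- call_markers(z, panel)
  write.csv(z, file.path(out_dir, paste0("zscores_", d, ".csv")),
            row.names = FALSE)
  write.csv(pos, file.path(out_dir, paste0("positivity_", d, ".csv")),
            row.names = FALSE)
  coi <- pos[!pos$is_reference, ]
  message(sprintf("%s: %d COIs | tissue-marker+ %d | CD31+ %d", d,
                  nrow(coi), sum(coi$tissue_marker_positive),
                  sum(coi$endothelial_positive)))
}
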