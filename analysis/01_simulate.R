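#!/usr/bin/env Rscript

# Simulates the longitudinal index-patient scenario: four blood draws at
# 4-week spacing, three taken at active disease (CTC-dominant, ~90% tumor
# cells) and one at stable disease (CEC-dominant, ~75% endothelial cells),
# plus the endothelial cell-line spike-in experiment. Writes the raw cell
# tables that the downstream steps consume.

suppressPackageStartupMessages(library(crcdeconv))

out_dir <- "results/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 20260925

draws <- list(
  D1 = list(weeks = 0, status = "AD",
            comp = c(EPI.CTC = 0.54, pEMT.CTC = 0.36, CEC = 0.10), n_rare = 60L),
  D2 = list(weeks = 8, status = "AD",
            comp = c(EPI.CTC = 0.52, pEMT.CTC = 0.38, CEC = 0.10), n_rare = 45L),
  D3 = list(weeks = 16, status = "SD",
            comp = c(EPI.CTC = 0.15, pEMT.CTC = 0.10, CEC = 0.75), n_rare = 40L),
  D4 = list(weeks = 28, status = "AD",
            comp = c(EPI.CTC = 0.55, pEMT.CTC = 0.35, CEC = 0.10), n_rare = 70L)
)

meta <- do.call(rbind, lapply(names(draws), function(d) {
  data.frame(draw_id = d, timepoint_weeks = draws[[d]]$weeks,
             disease_status = draws[[d]]$status, n_rare = draws[[d]]$n_rare)
}))
write.table(meta, file.path(out_dir, "draw_metadata.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

for (d in names(draws)) {
  cfg <- sim_config(seed = child_seed(seed, d), n_wbc_per_frame = 5000L,
                    n_rare = draws[[d]]$n_rare, composition = draws[[d]]$comp,
                    n_bins = 500L)
  cells <- generate_frame(cfg, frame_id = d)
  write.table(cells, file.path(out_dir, paste0("cells_", d, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s (%s, week %d): %d cells, %d rare", d,
                  draws[[d]]$status, draws[[d]]$weeks, nrow(cells),
                  sum(cells$truth_label != "WBC")))
}

# spike-in frames: cultured endothelial cells at 430 and 100 cells/mL
cfg_sp <- sim_config(seed = child_seed(seed, "spike"))
for (conc in c(430, 100)) {
  sp <- generate_spike_in(conc, 1, cfg_sp)
  write.table(sp, file.path(out_dir, sprintf("spike_%d.tsv", conc)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("spike-in %d cells/mL: %d cells written", conc, nrow(sp)))
}
message("done: ", out_dir)
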