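#!/usr/bin/env Rscript

# Single-cell copy-number profiling of the detected candidates: in-silico
# sequencing at ~500k reads/cell, GC normalization, CBS segmentation,
# gain/loss calls and clonality by shared breakpoints. Writes per-draw
# ratio/segment/clonality tables and a multi-cell heatmap ordered by
# clonal group (gain = red, loss = blue, neutral = white).

suppressPackageStartupMessages(library(crcdeconv))

in_sim <- "results/sim"
in_det <- "results/detect"
out_dir <- "results/cnv"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 20260925

meta <- read.delim(file.path(in_sim, "draw_metadata.tsv"))
all_ratios <- list()
all_clonality <- list()

for (d in meta$draw_id) {
  cand <- read.delim(file.path(in_det, paste0("candidates_", d, ".tsv")))
  cfg <- sim_config(seed = child_seed(seed, d), n_bins = 500L,
                    n_rare = nrow(cand),
                    composition = c(EPI.CTC = 1 / 3, pEMT.CTC = 1 / 3, CEC = 1 / 3))
  bins <- make_bins(cfg$chrom_lengths, cfg$n_bins, seed = cfg$seed)
  labels <- setNames(cand$truth_label, cand$cell_id)
  profiles <- simulate_profiles(labels, cfg)
  counts <- simulate_read_counts(profiles, bins, cfg)
  ratios <- gc_normalize(counts, bins$gc)
  set.seed(child_seed(seed, paste0("cbs:", d)))
  segs <- lapply(rownames(ratios), function(id) {
    call_states(segment_cbs(ratios[id, ], n_perm = 200, cell_id = id))
  })
  names(segs) <- rownames(ratios)
  seg_tab <- do.call(rbind, segs)
  clo <- detect_clonality(segs)
  clo$draw_id <- d
  write.table(seg_tab, file.path(out_dir, paste0("segments_", d, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(clo, file.path(out_dir, paste0("clonality_", d, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  all_ratios[[d]] <- ratios
  all_clonality[[d]] <- clo
  message(sprintf("%s: %d cells segmented, %d altered, %d in clonal groups",
                  d, nrow(clo), sum(clo$is_altered),
                  sum(!is.na(clo$clonal_group))))
}

# heatmap across all draws, rows ordered by clonal group
if (requireNamespace("pheatmap", quietly = TRUE)) {
  mat <- do.call(rbind, all_ratios)
  clo <- do.call(rbind, all_clonality)
  ord <- order(!is.na(clo$clonal_group), clo$clonal_group, clo$cell_id,
               decreasing = TRUE)
  m <- log2(pmax(mat[clo$cell_id[ord], ], 1 / 8))
  m[m > 1.5] <- 1.5; m[m < -1.5] <- -1.5
  png(file.path(out_dir, "cnv_heatmap.png"), width = 1400, height = 900)
  pheatmap::pheatmap(
    m, cluster_rows = FALSE, cluster_cols = FALSE,
    color = colorRampPalette(c("blue", "white", "red"))(51),
    breaks = seq(-1.5, 1.5, length.out = 52),
    show_colnames = FALSE, main = "Ratio-to-median copy-number profiles")
  dev.off()
  message("heatmap: ", file.path(out_dir, "cnv_heatmap.png"))
}
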