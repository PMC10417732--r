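#!/usr/bin/env Rscript

# Group comparisons in the figure style: CK SDOM, vimentin RFI and
# eccentricity across the classified rare-cell types (Kruskal-Wallis with
# Dunn's correction, star annotations), plus enumeration and spike-in
# recovery summaries.

suppressPackageStartupMessages(library(crcdeconv))

out_dir <- "results/report"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cls <- read.delim("results/classify/classifications.tsv")
meta <- read.delim("results/sim/draw_metadata.tsv")
cand <- do.call(rbind, lapply(meta$draw_id, function(d) {
  read.delim(sprintf("results/detect/candidates_%s.tsv", d))
}))
feat <- merge(cls, cand[c("cell_id", "ck_sdom", "vim_rfi")], by = "cell_id")
feat <- feat[feat$label %in% c("EPI.CTC", "pEMT.CTC", "CEC"), ]

rows <- list()
for (metric in c("ck_sdom", "vim_rfi", "eccentricity")) {
  groups <- split(feat[[metric]], feat$label)
  res <- compare_groups(groups)
  cat(sprintf("\n== %s ==\n", metric))
  print(res)
  pw <- res$pairwise
  pw$metric <- metric
  pw$omnibus_p <- res$omnibus_p
  rows[[metric]] <- pw
}
comp <- do.call(rbind, rows)
write.table(comp, file.path(out_dir, "group_comparisons.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# enumeration-style summary of rare-cell concentrations per draw (one frame
# corresponds to one mL of processed blood in the simulation)
conc <- vapply(meta$draw_id, function(d) {
  nrow(read.delim(sprintf("results/detect/candidates_%s.tsv", d)))
}, 0)
enum <- summarize_enumeration(conc)
write.table(enum, file.path(out_dir, "enumeration.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\nenumeration: mean %.1f (median %.1f, range %.1f-%.1f) cells/draw\n",
            enum$mean, enum$median, enum$min, enum$max))

rec <- read.delim("results/detect/spike_recovery.tsv")
cat("\nspike-in recovery:\n"); print(rec)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  feat$metric_ecc <- feat$eccentricity
  p <- ggplot(feat, aes(label, ck_sdom, colour = label)) +
    geom_jitter(width = 0.15, alpha = 0.7) +
    stat_summary(fun = median, geom = "crossbar", width = 0.4,
                 colour = "black", linewidth = 0.3) +
    labs(x = NULL, y = "CK SDOM",
         title = "Cytokeratin intensity by rare-cell type") +
    theme_minimal() + theme(legend.position = "none")
  ggsave(file.path(out_dir, "ck_sdom_by_type.png"), p, width = 5, height = 4,
         dpi = 150)
}
message("done: ", out_dir)
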