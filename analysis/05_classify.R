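#!/usr/bin/env Rscript

# Fuses IF, CNV and IMC evidence into the rare-cell taxonomy
# (EPI.CTC / pEMT.CTC / CEC), summarizes each draw and assembles the
# longitudinal composition table and stacked-composition figure.

suppressPackageStartupMessages(library(crcdeconv))

out_dir <- "results/classify"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

meta <- read.delim("results/sim/draw_metadata.tsv")
summaries <- list()
all_cls <- list()

for (i in seq_len(nrow(meta))) {
  d <- meta$draw_id[i]
  cand <- read.delim(sprintf("results/detect/candidates_%s.tsv", d))
  clo <- read.delim(sprintf("results/cnv/clonality_%s.tsv", d))
  pos <- read.csv(sprintf("results/imc/positivity_%s.csv", d))
  ci <- match(cand$cell_id, clo$cell_id)
  pi <- match(cand$cell_id, pos$cell_id)
  evidence <- tibble::tibble(
    cell_id = cand$cell_id,
    cd45_status = FALSE,
    vim_call = cand$vim_call,
    clonal_status = ifelse(!is.na(clo$clonal_group[ci]), "clonal",
                           ifelse(!clo$is_altered[ci], "non_altered", "unknown")),
    tissue_marker_positive = pos$tissue_marker_positive[pi],
    endothelial_positive = pos$endothelial_positive[pi],
    eccentricity = cand$eccentricity
  )
  cls <- classify_cells(evidence)
  cls$draw_id <- d
  cls$truth_label <- cand$truth_label
  all_cls[[d]] <- cls
  summaries[[d]] <- summarize_draw(cls, d, meta$timepoint_weeks[i],
                                   meta$disease_status[i])
  acc <- mean(cls$label == cand$truth_label)
  message(sprintf("%s: %d cells | EPI %d, pEMT %d, CEC %d | accuracy vs truth %.1f%%",
                  d, nrow(cls), sum(cls$label == "EPI.CTC"),
                  sum(cls$label == "pEMT.CTC"), sum(cls$label == "CEC"),
                  100 * acc))
}

cls_tab <- do.call(rbind, all_cls)
write.table(cls_tab, file.path(out_dir, "classifications.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
lt <- longitudinal_table(summaries)
write.table(lt, file.path(out_dir, "longitudinal.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(as.data.frame(lt[c("draw_id", "timepoint_weeks", "disease_status",
                         "frac_epi_ctc", "frac_pemt_ctc", "frac_cec")]))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  long <- do.call(rbind, lapply(seq_len(nrow(lt)), function(r) {
    data.frame(draw = lt$draw_id[r], weeks = lt$timepoint_weeks[r],
               status = lt$disease_status[r],
               label = c("EPI.CTC", "pEMT.CTC", "CEC"),
               fraction = c(lt$frac_epi_ctc[r], lt$frac_pemt_ctc[r],
                            lt$frac_cec[r]))
  }))
  p <- ggplot(long, aes(weeks, fraction, fill = label)) +
    geom_col(width = 3) +
    scale_x_continuous(breaks = seq(0, max(long$weeks), by = 4)) +
    scale_fill_manual(values = c(EPI.CTC = "#1b6ca8", pEMT.CTC = "#7fb3d5",
                                 CEC = "#c0392b")) +
    labs(x = "weeks (4-week ticks)", y = "fraction of classified rare cells",
         title = "Longitudinal rare-cell composition",
         subtitle = "labels above bars: disease status") +
    geom_text(data = lt, aes(timepoint_weeks, 1.04, label = disease_status),
              inherit.aes = FALSE, size = 3) +
    theme_minimal()
  ggsave(file.path(out_dir, "composition.png"), p, width = 7, height = 4.5,
         dpi = 150)
  message("figure: ", file.path(out_dir, "composition.png"))
}
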