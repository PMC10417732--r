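#' Run the full deconvolution pipeline on one synthetic blood draw
#'
#' Chains every stage end to end on generated data: simulate a slide frame,
#' detect DAPI+/CK+/CD45- candidates by the 6-SDOM rule, score vimentin and
#' eccentricity, sequence the candidates in silico (binned counts, GC
#' normalization, CBS segmentation, gain/loss calls, clonality), ablate
#' them in silico (ion counts, background subtraction, WBC-anchored
#' z-scores, marker positivity), fuse the evidence through the
#' classification ladder, and summarize the draw.
#'
#' @param config a [sim_config()] carrying composition, depth and panel
#'   settings for this draw.
#' @param draw_id draw identifier (also the frame id).
#' @param timepoint_weeks,disease_status metadata for [summarize_draw()].
#' @param run_cnv,run_imc toggle the genomic / proteomic layers.
#' @param alpha,n_perm,merge_tol CBS parameters (see [segment_cbs()]).
#' @param breakpoint_tol clonality breakpoint tolerance in bins.
#' @return list with `cells`, `candidates`, `segments`, `clonality`,
#'   `positivity`, `classifications`, `summary` and `truth` (the generated
#'   labels of the candidate cells).
#' @export
deconvolve_draw <- function(config, draw_id = "D1",
                            timepoint_weeks = NA_real_,
                            disease_status = "unknown",
                            run_cnv = TRUE, run_imc = TRUE,
                            alpha = 0.01, n_perm = 1000L, merge_tol = 0.1,
                            breakpoint_tol = 2L) {
  cells <- generate_frame(config, frame_id = draw_id)
  ref <- frame_reference(cells)
  cand <- detect_candidates(cells)
  vim <- score_vim(cand$vim, ref$wbc$vim)
  cand$vim_rfi <- vim$vim_rfi
  cand$vim_call <- vim$vim_call
  cand$eccentricity <- compute_eccentricity(cand$mu20, cand$mu02, cand$mu11)

  labels <- setNames(cand$truth_label, cand$cell_id)
  clonality <- NULL
  segments <- NULL
  clonal_status <- rep("unknown", nrow(cand))
  if (run_cnv && nrow(cand) > 0) {
    bins <- make_bins(config$chrom_lengths, config$n_bins, seed = config$seed)
    profiles <- simulate_profiles(labels, config)
    counts <- simulate_read_counts(profiles, bins, config)
    ratios <- gc_normalize(counts, bins$gc)
    set.seed(child_seed(config$seed, "cbs"))
    seg_list <- lapply(rownames(ratios), function(id) {
      call_states(segment_cbs(ratios[id, ], alpha = alpha, n_perm = n_perm,
                              merge_tol = merge_tol, cell_id = id))
    })
    names(seg_list) <- rownames(ratios)
    segments <- do.call(rbind, seg_list)
    clonality <- detect_clonality(seg_list, tol = breakpoint_tol)
    idx <- match(cand$cell_id, clonality$cell_id)
    clonal_status <- ifelse(!is.na(clonality$clonal_group[idx]), "clonal",
                            ifelse(!clonality$is_altered[idx], "non_altered",
                                   "unknown"))
  }

  positivity <- NULL
  tissue <- rep(NA, nrow(cand))
  endo <- rep(NA, nrow(cand))
  if (run_imc && nrow(cand) > 0) {
    imc <- simulate_imc(labels, config, roi = paste0("ROI_", draw_id))
    corrected <- subtract_background(imc$ions, imc$background)
    z <- zscore_normalize(corrected, population = "reference")
    positivity <- call_markers(z, imc$panel)
    idx <- match(cand$cell_id, positivity$cell_id)
    tissue <- positivity$tissue_marker_positive[idx]
    endo <- positivity$endothelial_positive[idx]
  }

  evidence <- tibble(
    cell_id = cand$cell_id,
    cd45_status = FALSE, # candidates passed the CD45 ceiling
    vim_call = cand$vim_call,
    clonal_status = clonal_status,
    tissue_marker_positive = tissue,
    endothelial_positive = endo,
    eccentricity = cand$eccentricity
  )
  cls <- classify_cells(evidence)
  summ <- summarize_draw(cls, draw_id, timepoint_weeks, disease_status)
  list(cells = cells, candidates = cand, segments = segments,
       clonality = clonality, positivity = positivity,
       classifications = cls, summary = summ,
       truth = tibble(cell_id = cand$cell_id, truth_label = cand$truth_label))
}
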