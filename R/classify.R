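#' Classify rare cells by fusing IF, genomic and proteomic evidence
#'
#' Applies a first-match-wins decision ladder per cell:
#' \enumerate{
#'   \item CD45-positive: `WBC`.
#'   \item clonal and vimentin-negative: `EPI.CTC`.
#'   \item clonal and vimentin-positive: `pEMT.CTC`.
#'   \item tissue-marker-positive and not endothelial-positive:
#'     `EPI.CTC` or `pEMT.CTC` by the vimentin call.
#'   \item (genomically non-altered or endothelial-positive), vimentin-
#'     positive and eccentricity at or above `elongation_cutoff`: `CEC`.
#'   \item endothelial-positive alone: `CEC`.
#'   \item otherwise `unclassified` — IF evidence alone cannot separate
#'     the cell types, so no guess is made.
#' }
#' Genomics outranks proteomics on conflict: a clonal, CD31-positive cell
#' is classified as a CTC with `conflict = TRUE`. The confidence tier
#' records which omics layers contributed.
#'
#' @param evidence data.frame with one row per cell and columns
#'   `cell_id`, `cd45_status` (logical), `vim_call` (logical or NA),
#'   `clonal_status` (`"clonal"`, `"non_altered"` or `"unknown"`),
#'   `tissue_marker_positive`, `endothelial_positive` (logical or NA),
#'   `eccentricity` (numeric or NA). Missing columns are treated as
#'   all-unknown.
#' @param elongation_cutoff eccentricity defining "morphologically
#'   consistent with an endothelial cell" (default 0.8).
#' @return tibble: `cell_id, label, tier, conflict` plus the evidence
#'   columns used. Labels are one of `EPI.CTC, pEMT.CTC, CEC, WBC,
#'   unclassified`.
#' @export
classify_cells <- function(evidence, elongation_cutoff = 0.8) {
  n <- nrow(evidence)
  get <- function(col, default) {
    if (col %in% names(evidence)) evidence[[col]] else rep(default, n)
  }
  cd45 <- get("cd45_status", FALSE)
  vim <- get("vim_call", NA)
  clonal <- get("clonal_status", "unknown")
  clonal[is.na(clonal)] <- "unknown"
  tissue <- get("tissue_marker_positive", NA)
  endo <- get("endothelial_positive", NA)
  ecc <- get("eccentricity", NA_real_)

  label <- character(n)
  conflict <- logical(n)
  tier <- character(n)
  for (r in seq_len(n)) {
    has_gen <- clonal[r] != "unknown"
    has_prot <- !is.na(tissue[r]) || !is.na(endo[r])
    tier[r] <- if (has_gen && has_prot) "genomic+proteomic"
      else if (has_gen) "genomic_only"
      else if (has_prot) "proteomic_only" else "morphology_only"
    vim_pos <- isTRUE(vim[r])
    if (isTRUE(cd45[r])) {
      label[r] <- "WBC"
    } else if (clonal[r] == "clonal") {
      label[r] <- if (vim_pos) "pEMT.CTC" else "EPI.CTC"
      conflict[r] <- isTRUE(endo[r])
    } else if (isTRUE(tissue[r]) && !isTRUE(endo[r])) {
      label[r] <- if (vim_pos) "pEMT.CTC" else "EPI.CTC"
    } else if ((clonal[r] == "non_altered" || isTRUE(endo[r])) && vim_pos &&
               !is.na(ecc[r]) && ecc[r] >= elongation_cutoff) {
      label[r] <- "CEC"
    } else if (isTRUE(endo[r])) {
      label[r] <- "CEC"
    } else {
      label[r] <- "unclassified"
    }
  }
  tibble(cell_id = evidence$cell_id, label = label, tier = tier,
         conflict = conflict, cd45_status = cd45, vim_call = vim,
         clonal_status = clonal, tissue_marker_positive = tissue,
         endothelial_positive = endo, eccentricity = ecc)
}

rare_labels <- c("EPI.CTC", "pEMT.CTC", "CEC")

#' Summarize one blood draw's classifications
#'
#' Counts and fractions per label among classified rare cells (WBCs and
#' unclassified cells are counted but excluded from the fraction
#' denominator). When a `characterized` flag is supplied, the summary also
#' reports fractions within the molecularly characterized subset, since
#' the sequenced/ablated population is a subset of all cells detected.
#'
#' @param classifications output of [classify_cells()].
#' @param draw_id draw identifier.
#' @param timepoint_weeks timepoint in weeks from first draw.
#' @param disease_status `"AD"` (active disease), `"SD"` (stable disease)
#'   or `"unknown"`.
#' @param characterized optional logical vector: cell had CNV/IMC data.
#' @return one-row tibble with counts `n_<label>`, fractions
#'   `frac_<label>`, totals and metadata; fractions are NA when no rare
#'   cell was classified.
#' @export
summarize_draw <- function(classifications, draw_id,
                           timepoint_weeks = NA_real_,
                           disease_status = c("unknown", "AD", "SD"),
                           characterized = NULL) {
  disease_status <- match.arg(disease_status)
  lab <- classifications$label
  counts <- vapply(c(rare_labels, "WBC", "unclassified"),
                   function(l) sum(lab == l), 0L)
  n_classified <- sum(counts[rare_labels])
  fracs <- if (n_classified > 0) counts[rare_labels] / n_classified
           else rep(NA_real_, 3)
  out <- tibble(
    draw_id = draw_id, timepoint_weeks = timepoint_weeks,
    disease_status = disease_status,
    n_total = nrow(classifications), n_classified_rare = n_classified,
    n_epi_ctc = counts[["EPI.CTC"]], n_pemt_ctc = counts[["pEMT.CTC"]],
    n_cec = counts[["CEC"]], n_wbc = counts[["WBC"]],
    n_unclassified = counts[["unclassified"]],
    frac_epi_ctc = fracs[[1]], frac_pemt_ctc = fracs[[2]], frac_cec = fracs[[3]]
  )
  if (!is.null(characterized)) {
    ch_lab <- lab[characterized]
    n_ch <- sum(ch_lab %in% rare_labels)
    out$n_characterized <- sum(characterized)
    for (l in rare_labels) {
      col <- paste0("frac_ch_", sub("\\.", "_", tolower(l)))
      out[[col]] <- if (n_ch > 0) sum(ch_lab == l) / n_ch else NA_real_
    }
  }
  out
}

#' Order draw summaries into a longitudinal time series
#'
#' @param summaries list of one-row tibbles from [summarize_draw()], or a
#'   combined tibble.
#' @return tibble sorted by `timepoint_weeks`, ready for plotting.
#' @export
longitudinal_table <- function(summaries) {
  if (is.data.frame(summaries)) tab <- summaries
  else tab <- do.call(rbind, summaries)
  as_tibble(tab[order(tab$timepoint_weeks), , drop = FALSE])
}
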