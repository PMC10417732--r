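#' Relocate cells of interest between IF and IMC coordinate systems
#'
#' Greedy one-to-one nearest-neighbour matching: all candidate pairs within
#' `max_dist` are sorted by distance and accepted while both endpoints are
#' unused. Cells of interest left without a partner are reported unmatched.
#'
#' @param if_coords data.frame `cell_id, x, y` from the IF scan.
#' @param imc_coords data.frame `cell_id, x, y` from the ablation ROI.
#' @param max_dist maximum pairing distance (same units as coordinates).
#' @return list with `pairs` (tibble `if_id, imc_id, dist`) and
#'   `unmatched` (character vector of IF cell ids).
#' @export
match_cois <- function(if_coords, imc_coords, max_dist) {
  stopifnot(max_dist > 0)
  dup <- c(if_coords$cell_id[duplicated(if_coords[c("x", "y")])],
           imc_coords$cell_id[duplicated(imc_coords[c("x", "y")])])
  if (length(dup) > 0) {
    warning("duplicate coordinates for: ", paste(dup, collapse = ", "))
  }
  d <- outer(if_coords$x, imc_coords$x, "-")^2 + outer(if_coords$y, imc_coords$y, "-")^2
  d <- sqrt(d)
  cand <- which(d <= max_dist, arr.ind = TRUE)
  ord <- order(d[cand])
  cand <- cand[ord, , drop = FALSE]
  used_if <- rep(FALSE, nrow(if_coords))
  used_imc <- rep(FALSE, nrow(imc_coords))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_if[i] && !used_imc[j]) {
      used_if[i] <- used_imc[j] <- TRUE
      keep[k] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  pairs <- tibble(if_id = if_coords$cell_id[cand[, 1]],
                  imc_id = imc_coords$cell_id[cand[, 2]],
                  dist = d[cand])
  list(pairs = pairs, unmatched = if_coords$cell_id[!used_if])
}

imc_marker_cols <- function(ions) {
  setdiff(names(ions), c("cell_id", "roi", "is_reference"))
}

#' Subtract negative-mask-space background from ion counts
#'
#' Per ROI and marker, the background ion count estimated over pixels
#' outside all cell masks is subtracted from each cell's mean ion count;
#' negative results are floored at 0 (ion counts are physical). Applying
#' the correction again with zero background is a no-op.
#'
#' @param ions ion-count tibble (`cell_id, roi, is_reference`, one column
#'   per marker channel).
#' @param background tibble with `roi` and matching marker columns.
#' @return corrected tibble, same shape as `ions`.
#' @export
subtract_background <- function(ions, background) {
  markers <- imc_marker_cols(ions)
  stopifnot(all(markers %in% names(background)))
  for (ch in markers) {
    bg <- background[[ch]][match(ions$roi, background$roi)]
    ions[[ch]] <- pmax(0, ions[[ch]] - bg)
  }
  ions
}

#' Z-score-normalize corrected ion counts
#'
#' Each marker column is centred and scaled by the mean and sample SD of a
#' normalization population. The default anchors to the reference WBC rows
#' (`is_reference`), so leukocyte columns come out mean 0 / SD 1 and cell-
#' of-interest expression is read in leukocyte SD units; `"pooled"` uses
#' COIs and WBCs together.
#'
#' @param ions corrected ion-count tibble (see [subtract_background()]).
#' @param population `"reference"` (default) or `"pooled"`.
#' @return z-score tibble, same shape; attribute `normalization` records
#'   the population used.
#' @export
zscore_normalize <- function(ions, population = c("reference", "pooled")) {
  population <- match.arg(population)
  markers <- imc_marker_cols(ions)
  rows <- if (population == "reference") which(ions$is_reference) else seq_len(nrow(ions))
  if (length(rows) < 2) stop_config("normalization population must have >= 2 cells")
  for (ch in markers) {
    mu <- mean(ions[[ch]][rows])
    s <- sd(ions[[ch]][rows])
    if (!is.finite(s) || s <= 0) {
      stop_config("marker %s is constant in the normalization population", ch)
    }
    ions[[ch]] <- (ions[[ch]] - mu) / s
  }
  attr(ions, "normalization") <- population
  ions
}

#' Call marker positivity from z-scores
#'
#' A marker target is positive when any of its channels reaches the cutoff
#' (z >= cutoff; default 1.5, per-target overridable). Channels are mapped
#' to targets through the panel sidecar, so duplicated targets (e.g. two
#' HER2 clones) collapse into one call. Targets missing from the slide's
#' panel are carried as NA, never imputed. Convenience flags:
#' `tissue_marker_positive` (any of ER/HER2/AR/PSA/PSMA) and
#' `endothelial_positive` (CD31).
#'
#' @param z z-score tibble from [zscore_normalize()].
#' @param panel panel tibble mapping `metal_tag` to `target`.
#' @param cutoff default z cutoff (default 1.5).
#' @param cutoffs optional named per-target cutoff overrides.
#' @param tissue_markers targets counting as tissue-of-origin evidence.
#' @param endothelial_marker target counting as endothelial evidence.
#' @return tibble: `cell_id, is_reference`, one logical column per target
#'   (NA when absent from the panel), `tissue_marker_positive`,
#'   `endothelial_positive`.
#' @export
call_markers <- function(z, panel, cutoff = 1.5, cutoffs = NULL,
                         tissue_markers = c("ER", "HER2", "AR", "PSA", "PSMA"),
                         endothelial_marker = "CD31") {
  channels <- imc_marker_cols(z)
  targets <- unique(c(panel$target, tissue_markers, endothelial_marker))
  out <- tibble(cell_id = z$cell_id, is_reference = z$is_reference)
  for (tg in targets) {
    tags <- intersect(panel$metal_tag[panel$target == tg], channels)
    cut_tg <- if (!is.null(cutoffs) && tg %in% names(cutoffs)) cutoffs[[tg]] else cutoff
    if (length(tags) == 0) {
      out[[tg]] <- NA # not in this slide's panel
    } else {
      zz <- as.matrix(z[tags])
      out[[tg]] <- apply(zz >= cut_tg, 1, any)
    }
  }
  tissue_present <- intersect(tissue_markers, names(out))
  tm <- as.matrix(out[tissue_present])
  out$tissue_marker_positive <- apply(tm, 1, function(v) any(v %in% TRUE))
  eo <- out[[endothelial_marker]]
  out$endothelial_positive <- !is.na(eo) & eo
  out
}
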