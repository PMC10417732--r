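#' Standard deviations over the mean (SDOM) of a cell's intensity
#'
#' Expresses a candidate cell's cytokeratin intensity in units of the
#' surrounding leukocytes' spread: `(cell - mean(reference)) / sd(reference)`
#' with the sample (n-1) standard deviation. CK positivity for rare-cell
#' detection is defined as SDOM >= 6 against the frame's leukocytes, which
#' act as the negative control for CK.
#'
#' @param cell_intensity numeric vector of cell intensities.
#' @param reference numeric vector of reference leukocyte intensities
#'   (length >= 2, SD > 0).
#' @return numeric SDOM score(s), unitless.
#' @export
compute_sdom <- function(cell_intensity, reference) {
  if (length(reference) < 2) {
    stop_config("reference population must have >= 2 cells")
  }
  s <- sd(reference)
  if (!is.finite(s) || s <= 0) {
    stop_config("degenerate reference: SD of reference intensities is 0")
  }
  (cell_intensity - mean(reference)) / s
}

#' Split a frame's cells into leukocyte reference and the rest
#'
#' The reference population is every CD45-positive cell in the frame.
#' CD45 positivity is taken as intensity above the frame's `frac` quantile:
#' leukocytes dominate a monolayer frame, so any quantile comfortably above
#' the rare-cell fraction lands inside the leukocyte distribution.
#'
#' @param cells frame cell table (needs `cd45`, `ck`, `vim`, `dapi`).
#' @param frac quantile defining the CD45 threshold (default 0.1).
#' @return list with `wbc` (reference rows) and `threshold_cd45`.
#' @export
frame_reference <- function(cells, frac = 0.1) {
  thr <- quantile(cells$cd45, frac, names = FALSE)
  list(wbc = cells[cells$cd45 > thr, , drop = FALSE], threshold_cd45 = thr)
}

#' Detect candidate rare cells (DAPI+ / CK+ / CD45-) in cell tables
#'
#' For each frame, computes the CK SDOM of every cell against the frame's
#' leukocyte reference and returns cells satisfying all three gates:
#' DAPI above the floor (leukocyte mean - 2 SD), CK SDOM at or above
#' `sdom_threshold` (ties pass: the comparison is closed), and CD45 below
#' the ceiling (the 10th percentile of leukocyte CD45). Returned records
#' carry their `ck_sdom`.
#'
#' @param cells cell table with `frame_id, dapi, ck, cd45` (and any other
#'   columns, which are carried through).
#' @param sdom_threshold CK positivity threshold in SDOM units (default 6).
#' @param dapi_sd_floor DAPI floor = mean - `dapi_sd_floor` * SD (default 2).
#' @param cd45_quantile CD45 ceiling quantile of leukocyte CD45 (default 0.1).
#' @param reference_frac quantile passed to [frame_reference()].
#' @return tibble of candidate cells with an added `ck_sdom` column.
#' @export
detect_candidates <- function(cells, sdom_threshold = 6,
                              dapi_sd_floor = 2, cd45_quantile = 0.1,
                              reference_frac = 0.1) {
  stopifnot(all(c("frame_id", "dapi", "ck", "cd45") %in% names(cells)))
  frames <- split(seq_len(nrow(cells)), cells$frame_id)
  picked <- lapply(names(frames), function(fid) {
    idx <- frames[[fid]]
    fr <- cells[idx, , drop = FALSE]
    ref <- frame_reference(fr, reference_frac)
    if (nrow(ref$wbc) < 2) {
      stop_config("frame %s has no usable leukocyte reference", fid)
    }
    sdom <- compute_sdom(fr$ck, ref$wbc$ck)
    dapi_floor <- mean(ref$wbc$dapi) - dapi_sd_floor * sd(ref$wbc$dapi)
    cd45_ceiling <- quantile(ref$wbc$cd45, cd45_quantile, names = FALSE)
    keep <- fr$dapi >= dapi_floor & sdom >= sdom_threshold & fr$cd45 < cd45_ceiling
    out <- fr[keep, , drop = FALSE]
    out$ck_sdom <- sdom[keep]
    out
  })
  out <- do.call(rbind, picked)
  as_tibble(out[order(out$cell_id), , drop = FALSE])
}

#' Score vimentin in CK+ candidate cells
#'
#' Vimentin is reported as raw fluorescent intensity (RFI) and called
#' positive or negative against a leukocyte-derived cutoff. The default
#' rule mirrors the CK SDOM logic: positive iff the cell's vimentin RFI
#' exceeds mean + `n_sd` * SD of the frame leukocytes' vimentin.
#'
#' @param vim_rfi numeric vimentin intensities of the candidate cells.
#' @param wbc_vim numeric vimentin intensities of the reference leukocytes.
#' @param n_sd SDs over the leukocyte mean defining the cutoff (default 2).
#' @param cutoff absolute cutoff overriding the reference rule, if given.
#' @return tibble with `vim_rfi`, `vim_call` (logical) and the `cutoff` used.
#' @export
score_vim <- function(vim_rfi, wbc_vim = NULL, n_sd = 2, cutoff = NULL) {
  stopifnot(all(vim_rfi >= 0))
  if (is.null(cutoff)) {
    if (is.null(wbc_vim) || length(wbc_vim) < 2) {
      stop_config("score_vim needs either a reference population or a cutoff")
    }
    cutoff <- mean(wbc_vim) + n_sd * sd(wbc_vim)
  }
  tibble(vim_rfi = vim_rfi, vim_call = vim_rfi > cutoff, cutoff = cutoff)
}

#' Eccentricity of a cell mask from central second moments
#'
#' The cell's equivalent ellipse is the eigen-decomposition of the moment
#' matrix `[[mu20, mu11], [mu11, mu02]]`; with eigenvalues `l1 >= l2` the
#' eccentricity is `sqrt(1 - l2/l1)`, on a 0-1 scale where 0 is a circle
#' and 1 a degenerate ellipse. Invariant to rotation and uniform scaling.
#'
#' @param mu20,mu02,mu11 central second moments (mu20, mu02 > 0); vectors
#'   are processed elementwise.
#' @return eccentricity in `[0, 1]`.
#' @export
compute_eccentricity <- function(mu20, mu02, mu11) {
  if (any(mu20 <= 0) || any(mu02 <= 0)) {
    stop_config("mu20 and mu02 must be positive")
  }
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(pmax(0, tr^2 / 4 - det))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  if (any(l1 <= 0)) stop_config("degenerate moment matrix (zero leading eigenvalue)")
  sqrt(pmax(0, 1 - l2 / l1))
}
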