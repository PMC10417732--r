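#' Default per-label, per-channel immunofluorescence intensity parameters
#'
#' Intensities are log-normal (non-negative, right-skewed), parameterized by
#' arithmetic mean and coefficient of variation in arbitrary fluorescence
#' units. The leukocyte (WBC) cytokeratin baseline is mean 1.0, cv 0.15, so
#' the 6-SDOM detection cutoff sits near 1.9 and rare-cell CK means of
#' 2.8-3.2 clear it with high probability. Partial-EMT CTC vimentin is drawn
#' uniformly from the clonal Vim-positive RFI range 0.0032-0.0522 observed
#' on patient slides; the WBC vimentin baseline (mean 0.0012, cv 0.35) puts
#' the mean + 2 SD positivity cutoff near 0.0022, below that range.
#' Endothelial cells are CK dim-positive, vimentin-high and CD45-negative.
#'
#' @return nested list: label -> channel -> parameter vector. Log-normal
#'   channels carry `c(mean, cv)`; uniform channels carry `c(min, max)`.
#' @export
default_intensity_params <- function() {
  list(
    WBC = list(
      dapi = c(mean = 10, cv = 0.15), ck = c(mean = 1.0, cv = 0.15),
      vim = c(mean = 0.0012, cv = 0.35), cd45 = c(mean = 5, cv = 0.25)
    ),
    EPI.CTC = list(
      dapi = c(mean = 15, cv = 0.20), ck = c(mean = 3.2, cv = 0.15),
      vim = c(mean = 0.0012, cv = 0.35), cd45 = c(mean = 0.3, cv = 0.30)
    ),
    pEMT.CTC = list(
      dapi = c(mean = 15, cv = 0.20), ck = c(mean = 3.0, cv = 0.15),
      vim = c(min = 0.0032, max = 0.0522), cd45 = c(mean = 0.3, cv = 0.30)
    ),
    CEC = list(
      dapi = c(mean = 14, cv = 0.20), ck = c(mean = 2.8, cv = 0.12),
      vim = c(mean = 0.02, cv = 0.40), cd45 = c(mean = 0.3, cv = 0.30)
    )
  )
}

# eccentricity ranges per label: CECs are elongated, tumor cells and
# leukocytes rounder; sampled uniformly within the range.
default_shape_params <- function() {
  list(
    WBC     = list(area = c(mean = 80, cv = 0.20),  ecc = c(0.05, 0.45)),
    EPI.CTC = list(area = c(mean = 300, cv = 0.25), ecc = c(0.15, 0.60)),
    pEMT.CTC = list(area = c(mean = 300, cv = 0.25), ecc = c(0.20, 0.65)),
    CEC     = list(area = c(mean = 350, cv = 0.30), ecc = c(0.85, 0.97))
  )
}

#' Build a simulation configuration
#'
#' Bundles every knob the synthetic-data generators use: slide composition,
#' sequencing depth and noise, genome discretization, fluorescence intensity
#' parameters and ion-count background. Defaults emulate the assay's stated
#' operating point: ~500,000 mapped reads per cell (minimum 250,000), 5000
#' genome bins, and a 50% EpCAM co-expression rate among CTCs.
#'
#' @param seed integer master seed; each generator derives its own child
#'   stream via [child_seed()].
#' @param n_wbc_per_frame leukocytes per slide frame (default 5000).
#' @param composition named fractions over `EPI.CTC`, `pEMT.CTC`, `CEC`;
#'   must sum to 1 within 1e-9.
#' @param n_rare number of rare cells per frame.
#' @param reads_per_cell target sequencing depth per cell (default 5e5).
#' @param n_bins genome bins (default 5000).
#' @param gc_bias_strength unitless >= 0; 0 disables GC bias.
#' @param noise_model `"poisson"` or `"negative_binomial"`.
#' @param dispersion negative-binomial dispersion (var = mu + dispersion*mu^2).
#' @param intensity_params see [default_intensity_params()].
#' @param shape_params per-label area/eccentricity parameters.
#' @param imc_background_rate additive ion-count background, ions/pixel.
#' @param epcam_coexpression fraction of CTCs with elevated EpCAM.
#' @param cancer_type `"prostate"` (PSA/PSMA/AR) or `"breast"` (ER/HER2).
#' @param n_imc_reference reference WBCs ablated alongside cells of
#'   interest (default 150).
#' @param chrom_lengths named numeric, abstract genome used by [make_bins()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_wbc_per_frame = 5000L,
                       composition = c(EPI.CTC = 1 / 3, pEMT.CTC = 1 / 3, CEC = 1 / 3),
                       n_rare = 0L,
                       reads_per_cell = 500000L,
                       n_bins = 5000L,
                       gc_bias_strength = 8,
                       noise_model = c("negative_binomial", "poisson"),
                       dispersion = 0.1,
                       intensity_params = default_intensity_params(),
                       shape_params = default_shape_params(),
                       imc_background_rate = 0.5,
                       epcam_coexpression = 0.5,
                       cancer_type = c("prostate", "breast"),
                       n_imc_reference = 150L,
                       chrom_lengths = c(chrA = 2e8, chrB = 1.5e8, chrC = 1.2e8, chrD = 1e8)) {
  noise_model <- match.arg(noise_model)
  cancer_type <- match.arg(cancer_type)
  if (n_rare > 0) {
    if (is.null(names(composition)) ||
        !all(names(composition) %in% c("EPI.CTC", "pEMT.CTC", "CEC"))) {
      stop_config("composition must be named over EPI.CTC, pEMT.CTC, CEC")
    }
    if (any(composition < 0) || any(composition > 1) ||
        abs(sum(composition) - 1) > 1e-9) {
      stop_config("composition fractions must lie in [0,1] and sum to 1 (got %.6f)",
                  sum(composition))
    }
  }
  stopifnot(n_wbc_per_frame >= 0, n_rare >= 0, reads_per_cell >= 0,
            n_bins >= 1, gc_bias_strength >= 0, dispersion >= 0,
            imc_background_rate >= 0,
            epcam_coexpression >= 0, epcam_coexpression <= 1)
  structure(list(
    seed = as.integer(seed), n_wbc_per_frame = as.integer(n_wbc_per_frame),
    composition = composition, n_rare = as.integer(n_rare),
    reads_per_cell = as.integer(reads_per_cell), n_bins = as.integer(n_bins),
    gc_bias_strength = gc_bias_strength, noise_model = noise_model,
    dispersion = dispersion, intensity_params = intensity_params,
    shape_params = shape_params, imc_background_rate = imc_background_rate,
    epcam_coexpression = epcam_coexpression, cancer_type = cancer_type,
    n_imc_reference = as.integer(n_imc_reference), chrom_lengths = chrom_lengths
  ), class = "sim_config")
}

draw_channel <- function(n, par) {
  if (all(c("min", "max") %in% names(par))) {
    runif(n, par[["min"]], par[["max"]])
  } else {
    rlnorm_mean(n, par[["mean"]], par[["cv"]])
  }
}

# central second moments of an ellipse with given area, eccentricity and
# orientation; eigenvalues are a^2/4 and b^2/4 for semi-axes a >= b.
moments_from_shape <- function(area, ecc, theta) {
  ratio <- sqrt(1 - ecc^2)            # b / a
  a <- sqrt(area / (pi * ratio))
  b <- a * ratio
  l1 <- a^2 / 4
  l2 <- b^2 / 4
  cth <- cos(theta); sth <- sin(theta)
  tibble(
    mu20 = l1 * cth^2 + l2 * sth^2,
    mu02 = l1 * sth^2 + l2 * cth^2,
    mu11 = (l1 - l2) * cth * sth
  )
}

make_label_cells <- function(labels, frame_id, id_prefix, config, start_index = 1L) {
  n <- length(labels)
  ip <- config$intensity_params
  sp <- config$shape_params
  area <- ecc <- dapi <- ck <- vim <- cd45 <- numeric(n)
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    dapi[idx] <- draw_channel(length(idx), ip[[lab]]$dapi)
    ck[idx] <- draw_channel(length(idx), ip[[lab]]$ck)
    vim[idx] <- draw_channel(length(idx), ip[[lab]]$vim)
    cd45[idx] <- draw_channel(length(idx), ip[[lab]]$cd45)
    area[idx] <- rlnorm_mean(length(idx), sp[[lab]]$area[["mean"]], sp[[lab]]$area[["cv"]])
    ecc[idx] <- runif(length(idx), sp[[lab]]$ecc[1], sp[[lab]]$ecc[2])
  }
  theta <- runif(n, 0, pi)
  mom <- moments_from_shape(area, ecc, theta)
  tibble(
    cell_id = sprintf("%s%05d", id_prefix, seq.int(start_index, length.out = n)),
    frame_id = frame_id,
    x = runif(n, 0, 20000), y = runif(n, 0, 20000),
    area_px = area,
    mu20 = mom$mu20, mu02 = mom$mu02, mu11 = mom$mu11,
    dapi = dapi, ck = ck, vim = vim, cd45 = cd45,
    truth_label = labels
  )
}

#' Simulate one slide frame of leukocytes plus rare cells
#'
#' Emits a per-cell feature table matching the detection module's input
#' contract: centroid, area, central second moments and DAPI/CK/Vim/CD45
#' mean intensities, with a ground-truth label column. Rare-cell labels are
#' drawn multinomially from `config$composition`; rare-cell CK is generated
#' high enough that true rare cells exceed the 6-SDOM criterion against the
#' frame's leukocytes with high probability.
#'
#' @param config a [sim_config()].
#' @param frame_id frame identifier string.
#' @return tibble with columns `cell_id, frame_id, x, y, area_px, mu20,
#'   mu02, mu11, dapi, ck, vim, cd45, truth_label`.
#' @export
generate_frame <- function(config, frame_id = "F01") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, paste0("frame:", frame_id)))
  wbc <- make_label_cells(rep("WBC", config$n_wbc_per_frame), frame_id, "W", config)
  if (config$n_rare > 0) {
    comp <- config$composition[config$composition > 0]
    counts <- as.vector(rmultinom(1, config$n_rare, comp))
    labels <- sample(rep(names(comp), counts))
    rare <- make_label_cells(labels, frame_id, "R", config)
    out <- rbind(wbc, rare)
  } else {
    out <- wbc
  }
  out
}

#' Simulate ground-truth copy-number profiles for a set of labelled cells
#'
#' CTC-labelled cells (`EPI.CTC`, `pEMT.CTC`) share one clonal profile —
#' identical breakpoints and integer copy-number states — emulating a tumor
#' lineage; `CEC` and `WBC` cells are copy-number neutral at ploidy 2.
#' Altered segments take copy numbers in {1, 3, 4} on a diploid baseline so
#' every alteration clears the 1.25x gain / 0.75x loss ratio thresholds.
#'
#' @param labels named character vector of truth labels (names = cell ids),
#'   or a data.frame with `cell_id` and `truth_label` columns.
#' @param config a [sim_config()]; uses `n_bins` and the `"clone"` seed stream.
#' @param n_breakpoints breakpoints in the shared clone (default 8).
#' @return list of profiles, each `list(cell_id, cn, breakpoints, clone_id)`
#'   where `cn` is an integer vector over bins and `breakpoints` are 0-based
#'   bin indices at which a new segment starts.
#' @export
simulate_profiles <- function(labels, config, n_breakpoints = 8L) {
  stopifnot(inherits(config, "sim_config"))
  if (is.data.frame(labels)) labels <- setNames(labels$truth_label, labels$cell_id)
  n_bins <- config$n_bins
  set.seed(child_seed(config$seed, "clone"))
  min_gap <- max(5L, n_bins %/% 25L)
  # rejection-sample breakpoint positions with a minimum segment length
  repeat {
    bp <- sort(sample(seq_len(n_bins - 1L), n_breakpoints))
    if (all(diff(c(0L, bp, n_bins)) >= min_gap)) break
  }
  n_seg <- n_breakpoints + 1L
  cn <- integer(n_seg)
  cn[1] <- 2L
  for (s in seq.int(2L, n_seg)) {
    cn[s] <- sample(setdiff(c(1L, 2L, 3L, 4L), cn[s - 1L]), 1L)
  }
  if (all(cn == 2L)) cn[2] <- 3L # unreachable guard: clone must be altered
  clone_cn <- rep(cn, times = diff(c(0L, bp, n_bins)))
  lapply(names(labels), function(id) {
    if (labels[[id]] %in% c("EPI.CTC", "pEMT.CTC")) {
      list(cell_id = id, cn = clone_cn, breakpoints = bp, clone_id = "clone1")
    } else {
      list(cell_id = id, cn = rep(2L, n_bins), breakpoints = integer(0),
           clone_id = "neutral")
    }
  })
}

gc_bias_factor <- function(gc, strength, gc_opt = 0.45) {
  exp(-strength * (gc - gc_opt)^2)
}

#' Simulate binned read counts from ground-truth copy-number profiles
#'
#' Expected count per bin is proportional to copy number x bin width x a
#' unimodal GC bias factor `exp(-strength * (gc - 0.45)^2)`, scaled so the
#' expected total per cell equals `config$reads_per_cell`. Counts are drawn
#' Poisson or negative-binomial (var = mu + dispersion * mu^2), the latter
#' reflecting the overdispersion of whole-genome-amplified single cells.
#'
#' @param profiles list from [simulate_profiles()].
#' @param bins a bin table from [make_bins()] (needs `width` and `gc`).
#' @param config a [sim_config()].
#' @return integer matrix, cells x bins, rownames = cell ids.
#' @export
simulate_read_counts <- function(profiles, bins, config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(bins$width <= 0)) stop_config("zero-width bins are not allowed")
  n_bins <- nrow(bins)
  set.seed(child_seed(config$seed, "reads"))
  bias <- gc_bias_factor(bins$gc, config$gc_bias_strength)
  counts <- matrix(0L, nrow = length(profiles), ncol = n_bins,
                   dimnames = list(vapply(profiles, `[[`, "", "cell_id"), NULL))
  for (r in seq_along(profiles)) {
    cn <- profiles[[r]]$cn
    stopifnot(length(cn) == n_bins)
    w <- cn * bins$width * bias
    mu <- config$reads_per_cell * w / sum(w)
    counts[r, ] <- if (config$noise_model == "poisson" || config$dispersion == 0) {
      rpois(n_bins, mu)
    } else {
      rnbinom(n_bins, size = 1 / config$dispersion, mu = mu)
    }
  }
  counts
}

#' Default imaging-mass-cytometry antibody panel
#'
#' The metal-tagged panel used for targeted proteomics: CK8/18, EpCAM, ER,
#' two HER2 clones, CD45, PSMA, PSA and AR, plus a CD31 entry carried on
#' the slides where endothelial identification was run. Panels differ per
#' slide; markers absent from a slide's panel are carried as NA downstream.
#'
#' @param include_cd31 include the endothelial CD31 channel (default TRUE).
#' @return tibble with `metal_tag`, `target`, `dilution`.
#' @export
default_panel <- function(include_cd31 = TRUE) {
  p <- tibble(
    metal_tag = c("Yb174", "Pr141", "Dy163", "Tb159", "Nd148",
                  "Y89", "Tm169", "Gd160", "Sm154"),
    target = c("CK8/18", "EpCAM", "ER", "HER2", "HER2",
               "CD45", "PSMA", "PSA", "AR"),
    dilution = c("1:50", "1:100", "1:100", "1:100", "1:100",
                 "1:200", "1:100", "1:100", "1:100")
  )
  if (include_cd31) {
    p <- rbind(p, tibble(metal_tag = "Nd145", target = "CD31", dilution = "1:100"))
  }
  p
}

imc_expression_level <- function(label, target, config, epcam_high) {
  base <- 0.2
  lvl <- base
  is_ctc <- label %in% c("EPI.CTC", "pEMT.CTC")
  if (target == "CD45" && label == "WBC") lvl <- 20
  if (target == "CK8/18" && is_ctc) lvl <- 15
  if (target == "CK8/18" && label == "CEC") lvl <- 2
  if (target == "EpCAM" && is_ctc && epcam_high) lvl <- 15
  if (config$cancer_type == "prostate" && is_ctc &&
      target %in% c("PSA", "PSMA", "AR")) {
    lvl <- c(PSA = 12, PSMA = 12, AR = 10)[[target]]
  }
  if (config$cancer_type == "breast" && is_ctc && target %in% c("ER", "HER2")) {
    lvl <- c(ER = 12, HER2 = 10)[[target]]
  }
  if (target == "CD31" && label == "CEC") lvl <- 15
  lvl
}

#' Simulate an imaging-mass-cytometry ion-count table
#'
#' Cells of interest plus `config$n_imc_reference` reference WBCs receive
#' per-channel mean ion counts (ions/pixel over the cell mask): tumor cells
#' express CK8/18 and the tissue markers of `config$cancer_type`, a
#' configurable fraction co-expresses EpCAM, endothelial cells express CD31,
#' and WBCs express CD45. An additive Poisson background at
#' `config$imc_background_rate` ions/pixel contaminates every mask; the
#' ROI's negative mask space yields the per-channel background estimate.
#'
#' @param labels named character vector of truth labels (names = cell ids),
#'   or data.frame with `cell_id`, `truth_label`.
#' @param panel antibody panel tibble (see [default_panel()]).
#' @param config a [sim_config()].
#' @param roi ROI identifier.
#' @return list with `ions` (tibble: cell_id, roi, is_reference, one column
#'   per metal tag), `background` (tibble: roi, one column per metal tag),
#'   and `panel`.
#' @export
simulate_imc <- function(labels, config, panel = default_panel(), roi = "ROI1") {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(panel) == 0) stop_config("empty antibody panel")
  if (is.data.frame(labels)) labels <- setNames(labels$truth_label, labels$cell_id)
  set.seed(child_seed(config$seed, paste0("imc:", roi)))
  ids <- c(names(labels), sprintf("REF%04d", seq_len(config$n_imc_reference)))
  labs <- c(unname(labels), rep("WBC", config$n_imc_reference))
  is_ref <- c(rep(FALSE, length(labels)), rep(TRUE, config$n_imc_reference))
  n <- length(ids)
  is_ctc <- labs %in% c("EPI.CTC", "pEMT.CTC")
  epcam_high <- rep(FALSE, n)
  epcam_high[is_ctc] <- runif(sum(is_ctc)) < config$epcam_coexpression
  npx_cell <- 100   # pixels per cell mask
  npx_bg <- 10000   # negative mask space pixels
  out <- matrix(0, nrow = n, ncol = nrow(panel),
                dimnames = list(NULL, panel$metal_tag))
  for (k in seq_len(nrow(panel))) {
    lvl <- vapply(seq_len(n), function(r) {
      imc_expression_level(labs[r], panel$target[k], config, epcam_high[r])
    }, 0)
    signal <- rlnorm_mean(n, 1, 0.35) * lvl
    bg <- rpois(n, config$imc_background_rate * npx_cell) / npx_cell
    out[, k] <- signal + bg
  }
  bg_est <- rpois(nrow(panel), config$imc_background_rate * npx_bg) / npx_bg
  ions <- as_tibble(out)
  ions <- cbind(tibble(cell_id = ids, roi = roi, is_reference = is_ref), ions)
  background <- cbind(tibble(roi = roi),
                      as_tibble(as.list(setNames(bg_est, panel$metal_tag))))
  list(ions = as_tibble(ions), background = as_tibble(background), panel = panel)
}

#' Simulate an endothelial cell-line spike-in experiment
#'
#' Spikes `round(concentration * volume_ml)` cultured endothelial cells
#' (CK dim-positive, vimentin-high, CD45-negative — the CEC intensity
#' profile) into normal-donor blood frames, one frame per mL, each frame
#' carrying `config$n_wbc_per_frame` leukocytes.
#'
#' @param concentration spiked cells per mL.
#' @param volume_ml processed blood volume in mL.
#' @param config a [sim_config()].
#' @return tibble of cell records with `truth_label` and logical `spiked`.
#' @export
generate_spike_in <- function(concentration, volume_ml, config) {
  stopifnot(inherits(config, "sim_config"), concentration >= 0, volume_ml > 0)
  total <- round(concentration * volume_ml)
  n_frames <- max(1L, ceiling(volume_ml))
  per_frame <- diff(round(seq(0, total, length.out = n_frames + 1)))
  frames <- lapply(seq_len(n_frames), function(f) {
    fid <- sprintf("SPK%02d", f)
    set.seed(child_seed(config$seed, paste0("spike:", fid)))
    wbc <- make_label_cells(rep("WBC", config$n_wbc_per_frame), fid, "W", config)
    wbc$spiked <- FALSE
    if (per_frame[f] > 0) {
      sp <- make_label_cells(rep("CEC", per_frame[f]), fid, "S", config)
      sp$spiked <- TRUE
      rbind(wbc, sp)
    } else {
      wbc
    }
  })
  do.call(rbind, frames)
}
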