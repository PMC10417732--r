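#' Circular binary segmentation of a single-cell ratio profile
#'
#' Recursive change-point detection on `log2(ratio)`: at each step the arc
#' `(i, j]` maximizing a two-sample mean-shift statistic (arc vs complement)
#' is found by exhaustive scan; the split is accepted when its permutation
#' p-value — the fraction of within-window permutations whose maximal
#' statistic reaches the observed one, with the usual (1 + k)/(1 + n)
#' estimate — is below `alpha`. Accepted splits recurse into the resulting
#' sub-windows. Adjacent segments whose log2 means differ by less than
#' `merge_tol` are merged afterwards. No "undo" pruning beyond that merge
#' pass is applied.
#'
#' @param ratio per-bin ratio-to-median profile (from [gc_normalize()]).
#' @param alpha permutation significance level for accepting a split
#'   (default 0.01).
#' @param n_perm permutations per tested split (default 1000; below 100 a
#'   warning is raised).
#' @param min_width minimum bins on either side of a split (default 2).
#' @param merge_tol merge adjacent segments closer than this in log2 units
#'   (default 0.1).
#' @param seed optional seed for the permutation stream.
#' @param cell_id optional id attached to the output.
#' @return tibble of class `segset`: `cell_id, start_bin, end_bin,
#'   n_bins, mean_ratio` with 0-based half-open bin ranges partitioning
#'   the profile; breakpoints are `start_bin[-1]`.
#' @export
segment_cbs <- function(ratio, alpha = 0.01, n_perm = 1000L, min_width = 2L,
                        merge_tol = 0.1, seed = NULL, cell_id = NA_character_) {
  if (any(!is.finite(ratio)) || any(ratio < 0)) {
    stop_config("ratio profile must be finite and non-negative")
  }
  if (n_perm < 100) warning("n_perm < 100: permutation p-values are coarse")
  if (!is.null(seed)) set.seed(seed)
  x <- log2(pmax(ratio, .Machine$double.xmin))
  m <- length(x)
  stopifnot(m >= 2 * min_width)
  early <- ceiling(alpha * (1 + n_perm)) # count beyond which p >= alpha surely
  bps <- integer(0)
  recurse <- function(lo, hi) {
    mm <- hi - lo + 1L
    if (mm < 2L * min_width) return(invisible(NULL))
    res <- cbs_max_stat(x[lo:hi], min_width)
    if (res[3] <= 0) return(invisible(NULL))
    pc <- cbs_perm_count(x[lo:hi], min_width, res[3], n_perm, early)
    p <- (1 + pc[1]) / (1 + pc[2])
    if (p >= alpha) return(invisible(NULL))
    i <- as.integer(res[1]); j <- as.integer(res[2]) # 0-based window offsets
    cuts <- integer(0)
    if (i > 0) cuts <- c(cuts, lo - 1L + i)
    if (j < mm) cuts <- c(cuts, lo - 1L + j)
    bps <<- c(bps, cuts)
    bounds <- c(lo - 1L, cuts, hi)
    for (s in seq_len(length(bounds) - 1L)) {
      recurse(bounds[s] + 1L, bounds[s + 1L])
    }
    invisible(NULL)
  }
  recurse(1L, m)
  bps <- sort(unique(bps))
  segs <- segments_from_breakpoints(ratio, x, bps)
  # merge pass: repeatedly fuse the closest adjacent pair under merge_tol
  repeat {
    if (nrow(segs) < 2) break
    d <- abs(diff(segs$mean_log2))
    k <- which.min(d)
    if (d[k] >= merge_tol) break
    bps <- setdiff(bps, segs$start_bin[k + 1])
    segs <- segments_from_breakpoints(ratio, x, bps)
  }
  out <- tibble(cell_id = cell_id, start_bin = segs$start_bin,
                end_bin = segs$end_bin, n_bins = segs$end_bin - segs$start_bin,
                mean_ratio = segs$mean_ratio)
  class(out) <- c("segset", class(out))
  out
}

segments_from_breakpoints <- function(ratio, x, bps) {
  m <- length(ratio)
  bounds <- c(0L, bps, m)
  start <- bounds[-length(bounds)]
  end <- bounds[-1]
  tibble(
    start_bin = start, end_bin = end,
    mean_ratio = vapply(seq_along(start),
                        function(s) mean(ratio[(start[s] + 1):end[s]]), 0),
    mean_log2 = vapply(seq_along(start),
                       function(s) mean(x[(start[s] + 1):end[s]]), 0)
  )
}

#' Extract breakpoints from a segment set
#' @param segments output of [segment_cbs()].
#' @return integer vector of 0-based bin indices between segments.
#' @export
breakpoints <- function(segments) {
  segments$start_bin[segments$start_bin > 0]
}

#' Call gain / loss / neutral states on segments
#'
#' On the ratio-to-median scale, gains are segment means above 1.25 and
#' losses below 0.75; the neutral band 0.75-1.25 is closed, so a mean of
#' exactly 0.75 or 1.25 is neutral.
#'
#' @param segments segment table with `mean_ratio` (from [segment_cbs()]).
#' @param gain_threshold default 1.25.
#' @param loss_threshold default 0.75.
#' @return the segment table with an added `state` column
#'   (`gain` / `loss` / `neutral`). Breakpoints are never changed.
#' @export
call_states <- function(segments, gain_threshold = 1.25, loss_threshold = 0.75) {
  state <- rep("neutral", nrow(segments))
  state[segments$mean_ratio > gain_threshold] <- "gain"
  state[segments$mean_ratio < loss_threshold] <- "loss"
  segments$state <- state
  segments
}

# number of breakpoints of the sparser cell that find a partner within tol
shared_breakpoint_count <- function(bp_a, bp_b, tol) {
  if (length(bp_a) > length(bp_b)) { tmp <- bp_a; bp_a <- bp_b; bp_b <- tmp }
  if (length(bp_a) == 0) return(0L)
  sum(vapply(bp_a, function(b) any(abs(b - bp_b) <= tol), FALSE))
}

#' Group altered cells into clones by shared copy-number breakpoints
#'
#' A cell is "altered" if it carries at least one non-neutral called
#' segment. Two altered cells share a breakpoint when positions differ by
#' at most `tol` bins; a pair is clonally linked when it shares at least
#' `min_shared` breakpoints (or all breakpoints of the sparser cell, if it
#' has fewer). Clonal groups are the transitive closure of pairwise links.
#' A lone altered cell with no partner is still flagged clonal — rationale
#' `cancer_typical_single` — when at least one of its non-neutral segments
#' overlaps a supplied cancer-typical region, mirroring the single-altered-
#' cell rule used when only one altered cell is recovered from a draw.
#'
#' @param seg_list named list of called segment tables (one per cell, with
#'   `state`), or a single combined table with `cell_id`.
#' @param tol breakpoint matching tolerance in bins (default 2, >= 0).
#' @param min_shared breakpoints required to link a pair (default 2).
#' @param cancer_typical_regions optional data.frame `start_bin, end_bin`
#'   (0-based half-open bin ranges) of alterations typical for the cancer
#'   type; see [regions_to_bins()] to convert a genomic BED table.
#' @return tibble: `cell_id, is_altered, clonal_group, rationale` where
#'   `rationale` is `shared_breakpoints`, `cancer_typical_single` or `none`.
#' @export
detect_clonality <- function(seg_list, tol = 2L, min_shared = 2L,
                             cancer_typical_regions = NULL) {
  if (tol < 0) stop_config("breakpoint tolerance must be >= 0")
  if (is.data.frame(seg_list)) {
    seg_list <- split(seg_list, seg_list$cell_id)
  }
  ids <- names(seg_list)
  stopifnot(!is.null(ids))
  altered <- vapply(seg_list, function(s) any(s$state != "neutral"), FALSE)
  bps <- lapply(seg_list, breakpoints)
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  alt_idx <- which(altered)
  linked <- rep(FALSE, n)
  if (length(alt_idx) >= 2) {
    for (a in seq_along(alt_idx)[-1]) {
      for (b in seq_len(a - 1)) {
        i <- alt_idx[a]; j <- alt_idx[b]
        need <- min(min_shared, length(bps[[i]]), length(bps[[j]]))
        if (need == 0) next
        if (shared_breakpoint_count(bps[[i]], bps[[j]], tol) >= need) {
          linked[i] <- linked[j] <- TRUE
          parent[find(i)] <- find(j)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  group <- rep(NA_character_, n)
  rationale <- rep("none", n)
  grp_ids <- sort(unique(root[linked]))
  for (g in seq_along(grp_ids)) {
    members <- which(root == grp_ids[g] & linked)
    group[members] <- sprintf("clone%02d", g)
    rationale[members] <- "shared_breakpoints"
  }
  if (!is.null(cancer_typical_regions)) {
    solo <- which(altered & !linked)
    for (i in solo) {
      segs <- seg_list[[i]]
      alt_segs <- segs[segs$state != "neutral", , drop = FALSE]
      hit <- any(vapply(seq_len(nrow(alt_segs)), function(s) {
        any(alt_segs$start_bin[s] < cancer_typical_regions$end_bin &
              alt_segs$end_bin[s] > cancer_typical_regions$start_bin)
      }, FALSE))
      if (hit) {
        group[i] <- sprintf("single_%s", ids[i])
        rationale[i] <- "cancer_typical_single"
      }
    }
  }
  tibble(cell_id = ids, is_altered = unname(altered),
         clonal_group = group, rationale = rationale)
}

#' Convert genomic regions to bin-index ranges
#'
#' @param regions data.frame `chrom, start, end` (BED-like, 0-based).
#' @param bins bin table from [make_bins()].
#' @return tibble `start_bin, end_bin` (0-based half-open over bin indices).
#' @export
regions_to_bins <- function(regions, bins) {
  rows <- lapply(seq_len(nrow(regions)), function(r) {
    hit <- which(bins$chrom == regions$chrom[r] &
                   bins$start < regions$end[r] & bins$end > regions$start[r])
    if (length(hit) == 0) return(NULL)
    tibble(start_bin = min(hit) - 1L, end_bin = max(hit))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) tibble(start_bin = integer(0), end_bin = integer(0)) else out
}
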