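#' Partition an (abstract) genome into bins
#'
#' Allocates `n_bins` across chromosomes proportionally to length (largest
#' remainder rounding, total exactly `n_bins`), equal-width within a
#' chromosome with the final bin absorbing the remainder. GC fractions are
#' attached from `gc_track` when supplied, otherwise simulated as a smooth
#' long-range wave plus local noise, clipped to the 0.3-0.6 band.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param n_bins total bins across the genome (default 5000).
#' @param gc_track optional data.frame `chrom, start, end, gc` whose rows
#'   match the produced bins, or a numeric vector of length `n_bins`.
#' @param seed seed for the simulated GC track.
#' @return tibble: `chrom, start, end, width, gc` (0-based half-open).
#' @export
make_bins <- function(chrom_lengths, n_bins = 5000L, gc_track = NULL, seed = 1L) {
  stopifnot(length(chrom_lengths) >= 1, all(chrom_lengths > 0),
            !is.null(names(chrom_lengths)), n_bins >= length(chrom_lengths))
  share <- n_bins * chrom_lengths / sum(chrom_lengths)
  alloc <- floor(share)
  alloc[alloc == 0] <- 1
  rem <- n_bins - sum(alloc)
  if (rem > 0) {
    extra <- order(share - floor(share), decreasing = TRUE)
    alloc[extra[seq_len(rem)]] <- alloc[extra[seq_len(rem)]] + 1
  } else if (rem < 0) {
    shrink <- order(share - floor(share))
    for (i in shrink) {
      if (rem == 0) break
      if (alloc[i] > 1) { alloc[i] <- alloc[i] - 1; rem <- rem + 1 }
    }
  }
  rows <- lapply(names(chrom_lengths), function(ch) {
    k <- alloc[[ch]]
    w <- floor(chrom_lengths[[ch]] / k)
    start <- (seq_len(k) - 1) * w
    end <- c(start[-1], chrom_lengths[[ch]])
    tibble(chrom = ch, start = start, end = end, width = end - start)
  })
  bins <- do.call(rbind, rows)
  if (!is.null(gc_track)) {
    gc <- if (is.numeric(gc_track)) gc_track else gc_track$gc
    stopifnot(length(gc) == nrow(bins), all(gc >= 0 & gc <= 1))
    bins$gc <- gc
  } else {
    set.seed(child_seed(seed, "gc"))
    pos <- seq_len(nrow(bins))
    gc <- 0.45 + 0.08 * sin(2 * pi * pos / nrow(bins) * 7) +
      rnorm(nrow(bins), 0, 0.02)
    bins$gc <- pmin(0.6, pmax(0.3, gc))
  }
  as_tibble(bins)
}

#' Count aligned read positions into genome bins
#'
#' A read at position `p` on chromosome `c` increments the unique bin with
#' `start <= p < end` (half-open convention: a read exactly at a bin start
#' belongs to that bin). Reads outside every bin are dropped.
#'
#' @param reads data.frame with `cell_id, chrom, pos` (BED-like positions).
#' @param bins bin table from [make_bins()].
#' @param cells optional cell ids fixing the row set (cells without reads
#'   get an all-zero row); defaults to the ids present in `reads`.
#' @return integer matrix, cells x bins, rownames = cell ids.
#' @export
count_reads <- function(reads, bins, cells = NULL) {
  stopifnot(all(c("cell_id", "chrom", "pos") %in% names(reads)))
  cells <- cells %||% sort(unique(reads$cell_id))
  counts <- matrix(0L, nrow = length(cells), ncol = nrow(bins),
                   dimnames = list(cells, NULL))
  bin_index <- split(seq_len(nrow(bins)), bins$chrom)
  for (ch in names(bin_index)) {
    idx <- bin_index[[ch]]
    starts <- bins$start[idx]
    last_end <- bins$end[idx[length(idx)]]
    sel <- reads$chrom == ch & reads$pos >= starts[1] & reads$pos < last_end
    if (!any(sel)) next
    b <- idx[findInterval(reads$pos[sel], starts)]
    tab <- table(factor(reads$cell_id[sel], levels = cells), b)
    cols <- as.integer(colnames(tab))
    counts[, cols] <- counts[, cols, drop = FALSE] +
      matrix(as.integer(tab), nrow = length(cells))
  }
  counts
}

#' GC-normalize binned counts into ratio-to-median profiles
#'
#' Fits a locally weighted regression (lowess, configurable span) of
#' log(count + pseudocount) against per-bin GC fraction, divides the fitted
#' trend out, and rescales so the median ratio is exactly 1. The profile is
#' then on the "ratio to median" scale on which gains/losses are called.
#'
#' @param counts integer count vector (one cell) or cells x bins matrix.
#' @param gc per-bin GC fractions.
#' @param span lowess span (default 0.3).
#' @param pseudocount added to counts before the log fit (default 0.5),
#'   stabilizing sparse single-cell bins.
#' @param min_informative minimum bins with nonzero counts (default 100).
#' @return ratio vector, or matrix matching `counts`.
#' @export
gc_normalize <- function(counts, gc, span = 0.3, pseudocount = 0.5,
                         min_informative = 100L) {
  if (is.matrix(counts)) {
    out <- t(apply(counts, 1, gc_normalize, gc = gc, span = span,
                   pseudocount = pseudocount, min_informative = min_informative))
    dimnames(out) <- dimnames(counts)
    return(out)
  }
  stopifnot(length(counts) == length(gc))
  if (sum(counts > 0) < min_informative) {
    stop_config("cell has fewer than %d informative bins (all-zero or near-empty)",
                min_informative)
  }
  y <- log(counts + pseudocount)
  fit <- lowess(gc, y, f = span)
  trend <- approx(fit$x, fit$y, xout = gc, rule = 2, ties = mean)$y
  corrected <- (counts + pseudocount) / exp(trend - mean(trend))
  ratio <- corrected / median(corrected)
  ratio
}
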