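#' Kruskal-Wallis omnibus test with Dunn's pairwise post hoc comparisons
#'
#' Rank-based group comparison as used throughout the figure panels: a
#' tie-corrected Kruskal-Wallis omnibus test, followed by Dunn's z-tests on
#' mean ranks for every pair, with a multiplicity adjustment across pairs.
#' The Dunn z for groups i, j uses the pooled ranking of all N values:
#' `z = (Ri - Rj) / sqrt((N(N+1)/12 - T) (1/ni + 1/nj))` with tie term
#' `T = sum(t^3 - t) / (12 (N - 1))`.
#'
#' @param values named list of numeric vectors, one per group (>= 2 groups,
#'   each non-empty), or a data.frame with `value` and `group` columns.
#' @param adjust multiplicity adjustment over pairs, a [p.adjust()] method
#'   (default `"bonferroni"`).
#' @return list of class `group_comparison`: `omnibus_p`, `omnibus_stat`,
#'   `pairwise` (tibble: group1, group2, z, p, p_adj, annotation),
#'   `adjust_method`.
#' @export
compare_groups <- function(values, adjust = "bonferroni") {
  if (is.data.frame(values)) values <- split(values$value, values$group)
  if (length(values) < 2) stop_config("need >= 2 groups")
  sizes <- lengths(values)
  if (any(sizes == 0)) {
    stop_config("group(s) with 0 values: %s",
                paste(names(values)[sizes == 0], collapse = ", "))
  }
  x <- unlist(values, use.names = FALSE)
  g <- factor(rep(names(values), sizes), levels = names(values))
  if (length(unique(x)) == 1) {
    # every observation identical: no evidence of any difference
    pairs <- t(utils::combn(names(values), 2))
    pairwise <- tibble(group1 = pairs[, 1], group2 = pairs[, 2],
                       z = 0, p = 1, p_adj = 1, annotation = "ns")
    return(structure(list(omnibus_p = 1, omnibus_stat = 0,
                          pairwise = pairwise, adjust_method = adjust),
                     class = "group_comparison"))
  }
  kw <- kruskal.test(x, g)
  r <- rank(x)
  N <- length(x)
  mean_ranks <- tapply(r, g, mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- t(utils::combn(names(values), 2))
  z <- p <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
                 (1 / sizes[[i]] + 1 / sizes[[j]]))
    z[k] <- (mean_ranks[[i]] - mean_ranks[[j]]) / se
    p[k] <- 2 * pnorm(-abs(z[k]))
  }
  p_adj <- pmin(1, p.adjust(p, method = adjust))
  pairwise <- tibble(group1 = pairs[, 1], group2 = pairs[, 2], z = z,
                     p = p, p_adj = p_adj,
                     annotation = annotate_p(p_adj))
  structure(list(omnibus_p = kw$p.value, omnibus_stat = unname(kw$statistic),
                 pairwise = pairwise, adjust_method = adjust),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-squared = %.4g, omnibus p = %.4g\n",
              x$omnibus_stat, x$omnibus_p))
  cat(sprintf("Dunn pairwise z-tests, %s-adjusted:\n", x$adjust_method))
  print(x$pairwise, ...)
  invisible(x)
}

#' Star annotation for p-values
#'
#' Figure-legend style significance bands: `ns` above the first threshold,
#' then `*`, `**`, `***`, and `****` strictly below the smallest. Defaults
#' are 0.05 / 0.01 / 0.001 with the four-star band at the printed
#' `< 0.00001`; all four are configurable.
#'
#' @param p numeric p-value(s).
#' @param thresholds decreasing vector `c(star, two, three, four)`: `*` for
#'   `p <= star`, `**` for `p <= two`, `***` for `p <= three`, `****` for
#'   `p < four`.
#' @return character vector in `{ns, *, **, ***, ****}`.
#' @export
annotate_p <- function(p, thresholds = c(0.05, 0.01, 0.001, 0.00001)) {
  stopifnot(all(diff(thresholds) < 0), length(thresholds) == 4)
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_character_)
    if (pp < thresholds[4]) "****"
    else if (pp <= thresholds[3]) "***"
    else if (pp <= thresholds[2]) "**"
    else if (pp <= thresholds[1]) "*"
    else "ns"
  }, "")
}

#' Summarize per-sample cell concentrations
#'
#' Headline enumeration statistics for a set of per-sample rare-cell
#' concentrations: arithmetic mean (also rounded to the nearest integer
#' for the headline figure), median and range.
#'
#' @param per_sample_counts numeric vector, cells/mL per sample.
#' @return tibble: `mean, mean_rounded, median, min, max, n`.
#' @export
summarize_enumeration <- function(per_sample_counts) {
  stopifnot(length(per_sample_counts) >= 1, all(is.finite(per_sample_counts)))
  tibble(
    mean = mean(per_sample_counts),
    mean_rounded = round(mean(per_sample_counts)),
    median = median(per_sample_counts),
    min = min(per_sample_counts),
    max = max(per_sample_counts),
    n = length(per_sample_counts)
  )
}

#' Spike-in recovery percentage
#'
#' @param detected number of spiked cells recovered by detection.
#' @param spiked number of cells spiked in.
#' @return `100 * detected / spiked` (percent).
#' @export
compute_recovery <- function(detected, spiked) {
  if (any(spiked <= 0)) stop_config("spiked count must be positive")
  100 * detected / spiked
}
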