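# Shared fixtures and independent oracles used across test files.

# small, fast simulation setup for frame-level tests
tiny_config <- function(seed = 11, n_rare = 0L, n_wbc = 500L,
                        composition = c(EPI.CTC = 1 / 3, pEMT.CTC = 1 / 3, CEC = 1 / 3),
                        ...) {
  sim_config(seed = seed, n_wbc_per_frame = n_wbc, n_rare = n_rare,
             composition = composition, n_bins = 200L,
             chrom_lengths = c(chrA = 2e6), ...)
}

# two-pass mean/SD oracle, independent of stats::sd internals
two_pass_zscore <- function(x, ref) {
  m <- sum(ref) / length(ref)
  v <- sum((ref - m)^2) / (length(ref) - 1)
  (x - m) / sqrt(v)
}

# exhaustive single-split search maximizing the same two-sample statistic
# CBS uses, over all boundary splits of x
brute_force_single_split <- function(x, min_width = 2L) {
  m <- length(x)
  s <- sd(x)
  best <- -Inf
  best_t <- NA_integer_
  for (t in seq(min_width, m - min_width)) {
    left <- x[1:t]; right <- x[(t + 1):m]
    stat <- abs(mean(left) - mean(right)) / (s * sqrt(1 / t + 1 / (m - t)))
    if (stat > best) { best <- stat; best_t <- t }
  }
  list(split = best_t, stat = best)
}

# brute-force clonality oracle: all-pairs shared-breakpoint comparison
# followed by transitive closure over an adjacency matrix
brute_force_clonality <- function(bp_list, altered, tol, min_shared = 2L) {
  n <- length(bp_list)
  shared <- function(a, b) {
    if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
    if (length(a) == 0) return(0L)
    sum(vapply(a, function(x) any(abs(x - b) <= tol), FALSE))
  }
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || !altered[i] || !altered[j]) next
    need <- min(min_shared, length(bp_list[[i]]), length(bp_list[[j]]))
    if (need > 0 && shared(bp_list[[i]], bp_list[[j]]) >= need) adj[i, j] <- TRUE
  }
  reach <- adj | diag(n)
  for (k in seq_len(n)) reach <- reach | (reach[, k] %o% reach[k, ] > 0)
  # connected components among linked altered cells
  linked <- vapply(seq_len(n), function(i) any(adj[i, ]), FALSE)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!linked[i] || !is.na(comp[i])) next
    cid <- cid + 1L
    members <- which(linked & (reach[i, ] | reach[, i]))
    comp[members] <- cid
  }
  comp
}

# binomial 95% CI half-width around a design fraction
binom_ci_halfwidth <- function(p, n) 1.96 * sqrt(p * (1 - p) / n)

# log-normal central-moment helper for constructing ellipse masks in tests
ellipse_moments <- function(a, b, theta = 0) {
  l1 <- a^2 / 4; l2 <- b^2 / 4
  c(mu20 = l1 * cos(theta)^2 + l2 * sin(theta)^2,
    mu02 = l1 * sin(theta)^2 + l2 * cos(theta)^2,
    mu11 = (l1 - l2) * sin(theta) * cos(theta))
}
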