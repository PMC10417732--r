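test_that("bin construction allocates proportionally with equal widths per chromosome", {
  b <- make_bins(c(chr1 = 5e6), n_bins = 5000)
  expect_equal(nrow(b), 5000L)
  expect_true(all(b$width == 1000))
  expect_true(all(b$gc >= 0 & b$gc <= 1))

  b2 <- make_bins(c(chr1 = 3e6, chr2 = 1e6), n_bins = 100)
  alloc <- table(b2$chrom)
  expect_equal(nrow(b2), 100L)
  expect_lte(abs(alloc[["chr1"]] - 75), 1)
  # bins are sorted, non-overlapping and cover each chromosome
  for (ch in unique(b2$chrom)) {
    sub <- b2[b2$chrom == ch, ]
    expect_equal(sub$start[1], 0)
    expect_true(all(diff(sub$start) > 0))
    expect_equal(sub$start[-1], sub$end[-nrow(sub)])
  }
})

test_that("bin coordinates round-trip through a BED-style writer/reader", {
  b <- make_bins(c(chrA = 1.7e6, chrB = 9e5), n_bins = 77)
  path <- withr::local_tempfile(fileext = ".bed")
  write.table(b[c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  back <- read.table(path, sep = "\t",
                     col.names = c("chrom", "start", "end"))
  expect_equal(back$chrom, b$chrom)
  expect_equal(back$start, b$start)
  expect_equal(back$end, b$end)
})

test_that("read counting uses half-open bins and multinomial-consistent totals", {
  bins <- make_bins(c(chrA = 1000), n_bins = 10) # width-100 bins
  reads <- data.frame(cell_id = "c1",
                      chrom = "chrA",
                      pos = c(0, 99, 100, 999, 1000)) # 1000 is outside
  cnt <- count_reads(reads, bins)
  expect_equal(unname(cnt["c1", 1]), 2L) # boundary start counted in its own bin
  expect_equal(unname(cnt["c1", 2]), 1L)
  expect_equal(unname(cnt["c1", 10]), 1L)
  expect_equal(sum(cnt), 4L)

  # a cell without reads keeps an all-zero row
  cnt0 <- count_reads(reads, bins, cells = c("c1", "empty"))
  expect_equal(sum(cnt0["empty", ]), 0L)

  set.seed(8)
  unif <- data.frame(cell_id = "u", chrom = "chrA",
                     pos = floor(runif(5000, 0, 1000)))
  cu <- count_reads(unif, bins)
  expect_equal(sum(cu), 5000L)
  # uniform reads: chi-square test against equal expectation not rejected
  expect_gt(chisq.test(as.vector(cu))$p.value, 0.001)
})

test_that("GC normalization removes injected bias and recenters the median", {
  cfg <- sim_config(seed = 19, n_bins = 5000L, reads_per_cell = 500000L,
                    gc_bias_strength = 8, chrom_lengths = c(chrA = 5e8))
  bins <- make_bins(cfg$chrom_lengths, cfg$n_bins)
  prof <- list(list(cell_id = "n1", cn = rep(2L, 5000),
                    breakpoints = integer(0), clone_id = "neutral"))
  cnt <- simulate_read_counts(prof, bins, cfg)
  raw_corr <- cor(log(cnt[1, ] + 0.5), bins$gc)
  ratio <- gc_normalize(cnt[1, ], bins$gc)
  expect_lt(abs(cor(log(ratio), bins$gc)), 0.05)
  expect_lt(abs(cor(log(ratio), bins$gc)), abs(raw_corr))
  expect_equal(median(ratio), 1, tolerance = 1e-9)
  expect_true(all(ratio >= 0))

  # no injected bias: normalization leaves profile essentially unchanged
  cfg0 <- sim_config(seed = 19, n_bins = 5000L, gc_bias_strength = 0,
                     noise_model = "poisson", chrom_lengths = c(chrA = 5e8))
  cnt0 <- simulate_read_counts(prof, bins, cfg0)
  r0 <- gc_normalize(cnt0[1, ], bins$gc)
  pre <- (cnt0[1, ] + 0.5) / median(cnt0[1, ] + 0.5)
  expect_lt(abs(cor(log(r0), bins$gc)), 0.05)
  expect_lt(max(abs(r0 - pre) / pre), 0.05)

  const <- rep(120L, 5000)
  expect_equal(gc_normalize(const, bins$gc), rep(1, 5000), tolerance = 1e-9)
  expect_error(gc_normalize(rep(0L, 5000), bins$gc), "informative")
})

test_that("CBS finds noiseless change-points exactly and leaves constants alone", {
  step <- c(rep(1, 100), rep(2, 100))
  seg <- segment_cbs(step, n_perm = 200, seed = 1)
  expect_equal(breakpoints(seg), 100L)
  expect_equal(seg$mean_ratio, c(1, 2))
  expect_equal(seg$start_bin, c(0L, 100L))
  expect_equal(seg$end_bin, c(100L, 200L))

  flat <- segment_cbs(rep(1.0, 60), n_perm = 200, seed = 1)
  expect_equal(nrow(flat), 1L)
  expect_equal(length(breakpoints(flat)), 0L)

  expect_error(segment_cbs(c(rep(1, 50), NA)), "finite")
  expect_warning(segment_cbs(step, n_perm = 50, seed = 1), "n_perm")
})

test_that("CBS matches exhaustive single-split search on small noisy signals", {
  set.seed(1234)
  hits <- 0L
  for (rep_i in 1:10) {
    m <- sample(30:50, 1)
    cp <- sample(10:(m - 10), 1)
    x <- exp(c(rnorm(cp, 0, 0.15), rnorm(m - cp, log(2), 0.15)))
    oracle <- brute_force_single_split(log2(x))
    seg <- segment_cbs(x, n_perm = 500)
    expect_true(oracle$split %in% breakpoints(seg))
    if (identical(breakpoints(seg), oracle$split)) hits <- hits + 1L
  }
  expect_gte(hits, 8L) # occasionally an extra split survives the merge pass
})

test_that("segments always partition the bin axis", {
  set.seed(77)
  for (k in 1:5) {
    x <- exp(rnorm(80, 0, 0.3)) + ifelse(seq_len(80) > 40, runif(1, 0, 1.5), 0)
    seg <- segment_cbs(x, n_perm = 200)
    expect_equal(seg$start_bin[1], 0L)
    expect_equal(seg$end_bin[nrow(seg)], 80L)
    if (nrow(seg) > 1) {
      expect_equal(seg$start_bin[-1], seg$end_bin[-nrow(seg)])
    }
  }
})

test_that("state calling follows the ratio-to-median thresholds and keeps breakpoints", {
  seg <- tibble::tibble(cell_id = "c", start_bin = c(0L, 50L, 120L, 200L),
                        end_bin = c(50L, 120L, 200L, 260L),
                        n_bins = c(50L, 70L, 80L, 60L),
                        mean_ratio = c(1.3, 1.0, 0.75, 0.6))
  called <- call_states(seg)
  expect_equal(called$state, c("gain", "neutral", "neutral", "loss"))
  expect_equal(called$mean_ratio[called$state == "gain"], 1.3)
  expect_equal(call_states(tibble::tibble(mean_ratio = 1.25))$state, "neutral")
  expect_equal(called$start_bin, seg$start_bin) # calling never moves breakpoints
})

test_that("clonality grouping matches the brute-force all-pairs oracle", {
  mk_seg <- function(id, bps, states, n_bins = 300L) {
    bounds <- c(0L, bps, n_bins)
    tibble::tibble(cell_id = id, start_bin = bounds[-length(bounds)],
                   end_bin = bounds[-1],
                   mean_ratio = ifelse(states == "gain", 1.5,
                                       ifelse(states == "loss", 0.5, 1.0)),
                   state = states)
  }
  a <- mk_seg("a", c(100L, 250L), c("gain", "neutral", "loss"))
  b <- mk_seg("b", c(100L, 250L), c("gain", "neutral", "loss"))
  cl <- detect_clonality(list(a = a, b = b))
  expect_true(all(cl$clonal_group == cl$clonal_group[1]))
  expect_true(all(cl$rationale == "shared_breakpoints"))

  neutral <- mk_seg("n", integer(0), "neutral")
  cl0 <- detect_clonality(list(n1 = neutral, n2 = neutral))
  expect_true(all(is.na(cl0$clonal_group)))
  expect_true(all(!cl0$is_altered))
  expect_error(detect_clonality(list(a = a), tol = -1), "tolerance")

  set.seed(99)
  for (rep_i in 1:20) {
    n_cells <- sample(4:8, 1)
    segs <- list()
    bp_list <- list()
    altered <- logical(n_cells)
    for (i in seq_len(n_cells)) {
      nb <- sample(0:4, 1)
      bps <- sort(sample(seq(10L, 290L, by = 5L), nb))
      nb_states <- if (nb == 0) "neutral" else
        sample(c("gain", "loss", "neutral"), nb + 1, TRUE)
      if (nb > 0 && all(nb_states == "neutral")) nb_states[1] <- "gain"
      segs[[sprintf("s%d", i)]] <- mk_seg(sprintf("s%d", i), bps, nb_states)
      bp_list[[i]] <- bps
      altered[i] <- any(nb_states != "neutral")
    }
    got <- detect_clonality(segs, tol = 2)
    comp <- brute_force_clonality(bp_list, altered, tol = 2)
    # same partition: pairwise co-membership must agree
    for (i in seq_len(n_cells)) for (j in seq_len(n_cells)) {
      same_got <- !is.na(got$clonal_group[i]) && !is.na(got$clonal_group[j]) &&
        got$clonal_group[i] == got$clonal_group[j]
      same_oracle <- !is.na(comp[i]) && !is.na(comp[j]) && comp[i] == comp[j]
      expect_equal(same_got, same_oracle)
    }
  }
})

test_that("clonality is invariant to cell order and applies the single-cell rule", {
  mk <- function(id, bps) {
    # the single middle segment (between the two breakpoints) is the gain
    states <- c("neutral", "gain", "neutral")
    bounds <- c(0L, bps, 300L)
    tibble::tibble(cell_id = id, start_bin = bounds[-length(bounds)],
                   end_bin = bounds[-1],
                   mean_ratio = ifelse(states == "gain", 1.5, 1.0),
                   state = states)
  }
  segs <- list(x = mk("x", c(50L, 120L)), y = mk("y", c(51L, 121L)),
               z = mk("z", c(200L, 250L)))
  fwd <- detect_clonality(segs)
  rev_ <- detect_clonality(rev(segs))
  expect_equal(fwd$clonal_group[fwd$cell_id == "x"] ==
                 fwd$clonal_group[fwd$cell_id == "y"], TRUE)
  expect_true(is.na(fwd$clonal_group[fwd$cell_id == "z"]))
  m <- match(fwd$cell_id, rev_$cell_id)
  expect_equal(is.na(fwd$clonal_group), is.na(rev_$clonal_group[m]))

  # lone altered cell: clonal only when overlapping a cancer-typical region
  solo <- list(z = mk("z", c(200L, 250L)))
  plain <- detect_clonality(solo)
  expect_true(is.na(plain$clonal_group))
  typical <- tibble::tibble(start_bin = 190L, end_bin = 220L)
  flagged <- detect_clonality(solo, cancer_typical_regions = typical)
  expect_equal(flagged$rationale, "cancer_typical_single")
  expect_false(is.na(flagged$clonal_group))
  far <- tibble::tibble(start_bin = 0L, end_bin = 40L)
  expect_equal(detect_clonality(solo, cancer_typical_regions = far)$rationale,
               "none")
})

test_that("simulated clone breakpoints are recovered at full scale (5000 bins, 500k reads)", {
  for (noise in c("poisson", "negative_binomial")) {
    cfg <- sim_config(seed = 11, n_bins = 5000L, reads_per_cell = 500000L,
                      noise_model = noise)
    bins <- make_bins(cfg$chrom_lengths, cfg$n_bins, seed = cfg$seed)
    prof <- simulate_profiles(setNames("EPI.CTC", "a"), cfg)
    cnt <- simulate_read_counts(prof, bins, cfg)
    rat <- gc_normalize(cnt, bins$gc)
    set.seed(1)
    seg <- segment_cbs(rat[1, ], n_perm = 100)
    bp <- breakpoints(seg)
    err <- vapply(prof[[1]]$breakpoints, function(b) min(abs(b - bp)), 0)
    if (noise == "poisson") {
      # shot noise only: every breakpoint localized within the clonality
      # matching tolerance of 2 bins
      expect_true(all(err <= 2))
    } else {
      # amplification overdispersion blurs occasional low-contrast edges;
      # the large majority must still land within tolerance
      expect_gte(mean(err <= 2), 0.8)
    }
  }
})

test_that("genomic regions convert to bin index ranges", {
  bins <- make_bins(c(chrA = 1000, chrB = 1000), n_bins = 20)
  reg <- data.frame(chrom = "chrB", start = 150, end = 350)
  rb <- regions_to_bins(reg, bins)
  expect_equal(nrow(rb), 1L)
  expect_true(rb$start_bin >= 10 && rb$end_bin <= 20) # lands in chrB's bins
})
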