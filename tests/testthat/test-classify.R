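bundle <- function(...) {
  defaults <- list(cell_id = "c1", cd45_status = FALSE, vim_call = NA,
                   clonal_status = "unknown", tissue_marker_positive = NA,
                   endothelial_positive = NA, eccentricity = NA_real_)
  args <- utils::modifyList(defaults, list(...))
  tibble::as_tibble(args)
}

test_that("the decision ladder reproduces the taxonomy definitions", {
  # clonal, Vim- -> epithelial CTC
  expect_equal(classify_cells(bundle(clonal_status = "clonal",
                                     vim_call = FALSE))$label, "EPI.CTC")
  # clonal, Vim+ -> partial-EMT CTC
  expect_equal(classify_cells(bundle(clonal_status = "clonal",
                                     vim_call = TRUE))$label, "pEMT.CTC")
  # non-altered, CD31+, Vim+, elongated -> circulating endothelial cell
  expect_equal(classify_cells(bundle(clonal_status = "non_altered",
                                     vim_call = TRUE,
                                     tissue_marker_positive = FALSE,
                                     endothelial_positive = TRUE,
                                     eccentricity = 0.9))$label, "CEC")
  # CD45+ always wins
  expect_equal(classify_cells(bundle(cd45_status = TRUE,
                                     clonal_status = "clonal"))$label, "WBC")
  # proteomics-only rung: tissue markers without CD31 split by Vim
  expect_equal(classify_cells(bundle(tissue_marker_positive = TRUE,
                                     endothelial_positive = FALSE,
                                     vim_call = TRUE))$label, "pEMT.CTC")
  expect_equal(classify_cells(bundle(tissue_marker_positive = TRUE,
                                     endothelial_positive = FALSE,
                                     vim_call = FALSE))$label, "EPI.CTC")
  # CD31 alone (round cell, Vim-) still reads endothelial
  expect_equal(classify_cells(bundle(endothelial_positive = TRUE,
                                     tissue_marker_positive = FALSE,
                                     vim_call = FALSE))$label, "CEC")
  # IF evidence alone cannot separate the types: no guess
  expect_equal(classify_cells(bundle(vim_call = TRUE))$label, "unclassified")
})

test_that("genomics outranks proteomics on conflict and the conflict is flagged", {
  res <- classify_cells(bundle(clonal_status = "clonal", vim_call = FALSE,
                               endothelial_positive = TRUE,
                               tissue_marker_positive = FALSE))
  expect_equal(res$label, "EPI.CTC")
  expect_true(res$conflict)
})

test_that("classification is a pure function with recorded confidence tiers", {
  b <- bundle(clonal_status = "clonal", vim_call = TRUE,
              tissue_marker_positive = TRUE, endothelial_positive = FALSE)
  expect_identical(classify_cells(b), classify_cells(b))
  expect_equal(classify_cells(b)$tier, "genomic+proteomic")
  expect_equal(classify_cells(bundle(clonal_status = "clonal"))$tier,
               "genomic_only")
  expect_equal(classify_cells(bundle(endothelial_positive = TRUE))$tier,
               "proteomic_only")
  expect_equal(classify_cells(bundle())$tier, "morphology_only")
})

test_that("pipeline label accuracy on fully simulated data is at least 95%", {
  cfg <- sim_config(seed = 20260925, n_wbc_per_frame = 2000L, n_rare = 200L,
                    composition = c(EPI.CTC = 0.4, pEMT.CTC = 0.3, CEC = 0.3),
                    n_bins = 500L, chrom_lengths = c(chrA = 2e8, chrB = 1.5e8))
  res <- deconvolve_draw(cfg, n_perm = 200)
  acc <- mean(res$classifications$label == res$truth$truth_label)
  expect_gte(acc, 0.95)
})

test_that("draw summaries count, fraction and order correctly", {
  cls <- tibble::tibble(
    cell_id = sprintf("c%03d", 1:100),
    label = rep(c("EPI.CTC", "pEMT.CTC", "CEC", "unclassified"),
                c(50, 20, 25, 5))
  )
  s <- summarize_draw(cls, "D1", timepoint_weeks = 4, disease_status = "AD")
  expect_equal(s$n_classified_rare, 95L)
  expect_equal(s$frac_epi_ctc, 50 / 95)
  expect_equal(s$frac_epi_ctc + s$frac_pemt_ctc + s$frac_cec, 1,
               tolerance = 1e-9)
  expect_equal(s$n_unclassified, 5L)

  empty <- summarize_draw(cls[0, ], "D0")
  expect_equal(empty$n_classified_rare, 0L)
  expect_true(is.na(empty$frac_cec)) # fractions undefined are NA, not 0

  chars <- rep(c(TRUE, FALSE), 50)
  s2 <- summarize_draw(cls, "D1", characterized = chars)
  expect_equal(s2$n_characterized, 50L)
  expect_equal(s2$frac_ch_epi_ctc + s2$frac_ch_pemt_ctc + s2$frac_ch_cec, 1,
               tolerance = 1e-9)

  rows <- list(
    summarize_draw(cls, "D3", timepoint_weeks = 16, disease_status = "SD"),
    summarize_draw(cls, "D1", timepoint_weeks = 0, disease_status = "AD"),
    summarize_draw(cls, "D2", timepoint_weeks = 8, disease_status = "AD")
  )
  lt <- longitudinal_table(rows)
  expect_equal(lt$draw_id, c("D1", "D2", "D3"))
  single <- longitudinal_table(rows[1])
  expect_equal(nrow(single), 1L)
})

test_that("a synthetic stable-disease draw is CEC-dominant and progression draws CTC-dominant", {
  base <- list(n_wbc_per_frame = 2000L, n_bins = 400L,
               chrom_lengths = c(chrA = 2e8, chrB = 1.5e8))
  cfg_sd <- do.call(sim_config, c(base, list(
    seed = 301, n_rare = 80L,
    composition = c(EPI.CTC = 0.15, pEMT.CTC = 0.10, CEC = 0.75))))
  cfg_ad <- do.call(sim_config, c(base, list(
    seed = 302, n_rare = 80L,
    composition = c(EPI.CTC = 0.54, pEMT.CTC = 0.36, CEC = 0.10))))
  sd_draw <- deconvolve_draw(cfg_sd, "D3", 16, "SD", n_perm = 150)
  ad_draw <- deconvolve_draw(cfg_ad, "D1", 0, "AD", n_perm = 150)
  expect_lt(abs(sd_draw$summary$frac_cec - 0.75),
            binom_ci_halfwidth(0.75, 80) + 0.05)
  ctc_frac <- ad_draw$summary$frac_epi_ctc + ad_draw$summary$frac_pemt_ctc
  expect_lt(abs(ctc_frac - 0.90), binom_ci_halfwidth(0.90, 80) + 0.05)
  lt <- longitudinal_table(list(ad_draw$summary, sd_draw$summary))
  expect_equal(lt$disease_status, c("AD", "SD"))
  expect_gt(lt$frac_cec[lt$disease_status == "SD"],
            lt$frac_cec[lt$disease_status == "AD"])
})
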