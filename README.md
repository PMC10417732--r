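# crcdeconv

Multi-omic deconvolution of circulating rare cells from enrichment-free
liquid-biopsy slides.

Cytokeratin-positive, CD45-negative rare cells in the blood of carcinoma
patients are a mixture of biologically distinct populations: epithelial
circulating tumor cells (**EPI.CTC**), tumor cells undergoing a partial
epithelial–mesenchymal transition (**pEMT.CTC**, vimentin-positive), and
circulating endothelial cells (**CEC**, copy-number-neutral, CD31-positive,
elongated). Immunofluorescence alone cannot separate them — vimentin marks
both pEMT tumor cells and endothelial cells — so this package fuses three
evidence layers, each implemented and tested as its own module:

- **IF detection**: CK positivity as *standard deviations over the mean*
  (SDOM) of the surrounding leukocytes, `(x − x̄_WBC)/s_WBC ≥ 6`, with
  DAPI/CD45 gates, vimentin RFI scoring, and moment-based eccentricity
  `e = sqrt(1 − λ₂/λ₁)`;
- **single-cell CNV**: genome binning (5000 bins at full scale), lowess GC
  normalization to ratio-to-median profiles, circular binary segmentation
  (arc mean-shift statistic with permutation p-values, compiled scan),
  gain (> 1.25) / loss (< 0.75) calls, and clonality defined as two or more
  cells sharing copy-number breakpoints (±2 bins), with a
  cancer-typical-region rule for a lone altered cell;
- **IMC proteomics**: negative-mask background subtraction, z-scores
  anchored to reference leukocytes, per-marker positivity with panel
  metadata (missing markers stay NA);
- **classification**: a first-match decision ladder (CD45 → clonality ×
  Vim → tissue markers → CD31/morphology), longitudinal per-draw
  summaries, Kruskal–Wallis + Dunn group comparisons with star
  annotations.

A synthetic-data generator produces every input with ground-truth labels —
slide frames of leukocytes plus rare cells, binned read counts from clonal
copy-number profiles at ~500,000 reads/cell with GC bias, ion counts with
additive background, and spike-in experiments — so the whole pipeline is
validated end to end at known truth.

## Worked example

```r
library(crcdeconv)

cfg <- sim_config(seed = 7, n_wbc_per_frame = 5000, n_rare = 60,
                  composition = c(EPI.CTC = 0.54, pEMT.CTC = 0.36, CEC = 0.10),
                  n_bins = 500)
res <- deconvolve_draw(cfg, draw_id = "D1", timepoint_weeks = 0,
                       disease_status = "AD", n_perm = 200)
table(truth = res$truth$truth_label, called = res$classifications$label)
#>           called
#> truth      CEC EPI.CTC pEMT.CTC
#>   CEC        6       0        0
#>   EPI.CTC    0      27        2
#>   pEMT.CTC   0       0       25
res$summary[c("draw_id", "n_classified_rare", "frac_epi_ctc",
              "frac_pemt_ctc", "frac_cec")]
#>   draw_id n_classified_rare frac_epi_ctc frac_pemt_ctc frac_cec
#> 1      D1                60         0.45          0.45      0.1
```

The confusion table is read against the generator's ground truth: all
endothelial cells are recovered as CEC (neutral genomes + CD31 + elongation),
clonal cells split into EPI/pEMT by the vimentin call, and the two
off-diagonal cells are vimentin false positives at the leukocyte
mean + 2 SD cutoff. `res$summary` carries the per-draw counts and the
fractions over classified rare cells that feed `longitudinal_table()`.

The scripted analysis under `analysis/` runs the full longitudinal
scenario (four draws at 4-week spacing, three at active disease, one at
stable disease, plus 430 and 100 cells/mL endothelial spike-ins):

```sh
Rscript analysis/01_simulate.R   # slide frames + spike-ins -> results/sim/
Rscript analysis/02_detect.R     # 6-SDOM detection, Vim, eccentricity
Rscript analysis/03_cnv.R        # counts -> ratios -> CBS -> clonality (+heatmap)
Rscript analysis/04_imc.R        # ion counts -> z-scores -> positivity
Rscript analysis/05_classify.R   # evidence fusion, longitudinal table + figure
Rscript analysis/06_report.R     # KW/Dunn comparisons, enumeration, recovery
```

On the shipped seeds this classifies 95.6–100% of rare cells correctly per
draw, yields a CEC-dominant stable-disease draw (85% CEC) against
CTC-dominant progression draws (87–93% CTC), and recovers 99.8% / 99.0%
of the 430 and 100 cells/mL spike-ins.

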