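---
title: "Multi-omic deconvolution of circulating rare cells: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omic deconvolution of circulating rare cells: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcdeconv)
```

## The problem

Enrichment-free liquid-biopsy platforms plate every nucleated cell of a
blood draw on slides and search the resulting monolayer (~3 million cells)
for rare events. The cytokeratin-positive, CD45-negative cells found this
way are heterogeneous: genuinely tumor-derived circulating tumor cells
(CTCs), CTCs that have undergone a partial epithelial–mesenchymal
transition (pEMT), and circulating endothelial cells (CECs) shed from the
vasculature or tumor microenvironment. These classes carry different
clinical meaning — CTC burden tracks progression while CECs can dominate at
stable disease — but immunofluorescence (IF) alone cannot separate them,
because vimentin positivity occurs both in pEMT tumor cells and in
endothelial cells.

`crcdeconv` implements the deconvolution as a reusable, tested pipeline
over three evidence layers plus morphometrics, exercised end to end on a
synthetic-data generator with ground-truth labels:

1. **IF detection** — the SDOM statistic, vimentin scoring, eccentricity;
2. **single-cell copy number** — binning, GC normalization, circular
   binary segmentation (CBS), gain/loss calls, clonality by shared
   breakpoints;
3. **imaging mass cytometry (IMC)** — background subtraction, z-score
   normalization against a leukocyte reference, marker positivity;
4. **classification** — a decision ladder fusing the three layers, with
   per-draw longitudinal summaries and rank-based group comparisons.

## Detection model

A cell is a rare-cell candidate when it is DAPI-positive, CD45-negative
and CK-positive. CK positivity is defined relative to the surrounding
leukocytes, which act as a built-in negative control: the cell's CK
intensity is expressed in *standard deviations over the mean* (SDOM) of
the leukocyte CK distribution,

$$\mathrm{SDOM} = \frac{x_{\mathrm{cell}} - \bar x_{\mathrm{WBC}}}{s_{\mathrm{WBC}}},$$

with the sample (n−1) SD, and the detection threshold is SDOM ≥ 6 (the
comparison is closed: a tie passes). "Surrounding leukocytes" is
implemented as *all* CD45-positive cells of the frame — the scan is a
monolayer region, no radius is defined by the assay, and a global frame
reference is deterministic. CD45 positivity for reference construction
uses the frame's 10th CD45 quantile; leukocytes outnumber rare cells by
orders of magnitude, so any quantile well above the rare fraction lands
inside the leukocyte distribution.

Two further gates use the same reference population: a DAPI floor at the
leukocyte mean − 2 SD, and a CD45 ceiling at the leukocytes' 10th CD45
percentile. Both are configurable; the marker logic is fixed by the assay
but the numeric gates are this package's choices.

Vimentin is reported as raw fluorescent intensity (RFI) and called
positive above the leukocyte mean + 2 SD — a reference-relative rule
deliberately parallel to the CK SDOM logic, since the assay scores Vim
within the cell mask without publishing a numeric cutoff.

Cell elongation is summarized as the eccentricity of the equivalent
ellipse: with $\lambda_1 \ge \lambda_2$ the eigenvalues of the central
second-moment matrix $[[\mu_{20}, \mu_{11}], [\mu_{11}, \mu_{02}]]$,
$e = \sqrt{1 - \lambda_2/\lambda_1}$, 0 for a circle and →1 for a
degenerate ellipse; it is invariant to rotation and uniform scaling, which
the tests verify directly.

## Copy-number model

Candidates are profiled at ~500,000 mapped reads per cell (the assay's
target depth; minimum 250,000), mapped to bins spanning the genome —
5000 bins at full scale. Bins are allocated to chromosomes proportionally
to length and equal-width within a chromosome. The hg19 variable-bin
mappability table is intentionally *not* reproduced: an abstract genome
with supplied chromosome lengths keeps the module self-contained and
testable, and the bin abstraction is what every downstream step consumes.

Counts are GC-corrected by locally weighted regression (lowess, span 0.3)
of log(count + 0.5) on per-bin GC fraction; the fitted trend is divided
out and the profile rescaled to median ratio exactly 1 — the
"ratio-to-median" scale on which all thresholds are defined. The 0.5
pseudocount stabilizes sparse single-cell bins and guarantees positive
ratios for the subsequent log transform.

Segmentation is circular binary segmentation on `log2(ratio)`. Whether the
original pipeline segments ratio or log-ratio space is not stated
publicly; log2 is used here because mean-shift statistics are
variance-stabilized on that scale, and the choice is recorded rather than
hidden. At each recursion the arc $(i, j]$ maximizing the two-sample
mean-shift statistic between arc and complement is located by exhaustive
$O(m^2)$ scan (compiled code; the scan sits inside the permutation loop).
The split is accepted when its permutation p-value — estimated
conservatively as $(1+k)/(1+B)$ — is below `alpha` (default 0.01,
`n_perm` default 1000). Accepted cuts recurse; afterwards adjacent
segments closer than `merge_tol` (0.1 in log2 units) are merged,
innermost-first. No further "undo" pruning is applied. Degenerate inputs
are explicit: constant windows yield a single segment, non-finite ratios
are an error, and `n_perm` below 100 warns.

Gains are segment mean ratios above 1.25 and losses below 0.75; the
neutral band [0.75, 1.25] is closed at both edges, so a mean of exactly
0.75 or 1.25 is neutral. State calling never moves breakpoints.

Clonality: two altered cells share a breakpoint when positions differ by
at most `tol` bins (default 2 — "shared" has no published numeric
definition, so the tolerance is exposed in the interface); cells sharing
at least 2 breakpoints (or all breakpoints of the sparser cell) are
linked, and clonal groups are the transitive closure of links. A lone
altered cell with no partner can still be flagged clonal when one of its
called segments overlaps a supplied cancer-typical region — the rule used
in practice when a draw yields a single altered cell. The region list is
an input (BED-style); the package ships no oncology knowledge base.

## IMC model

Ion counts are means over the cell mask (ions/pixel). Background, defined
as the negative mask space of the ROI, is subtracted per marker and
floored at zero (negative ion counts are unphysical), which also makes
the correction idempotent once background is zero. Columns are then
z-scored. The normalization population is the *reference leukocytes* by
default: z-scores read as "leukocyte SDs above leukocyte background",
mirroring the SDOM logic, and the positivity cutoff z ≥ 1.5 is reachable
for any marker regardless of how many cells of interest express it. The
pooled alternative (COIs and WBCs together) is available via
`population = "pooled"`, but has a structural drawback that drove the
default: if a fraction $q$ of the pooled population expresses a marker,
the expressing mode's z-score cannot exceed $\sqrt{(1-q)/q}$ — with ~200
COIs against ~150 reference WBCs that bound is ≈1.3, *below* the default
cutoff, so strongly expressed markers would paradoxically become
uncallable. Positivity is monotone in the cutoff, per-marker cutoffs are
configurable, and markers absent from a slide's panel are carried as NA,
never imputed. Whether z-scores are computed per slide or per cohort is
an open question in the assay description; the package computes them over
whatever table it is handed, so either scope is a matter of input
assembly.

## Classification ladder

First match wins, evaluated per cell:

1. CD45⁺ → WBC;
2. clonal ∧ Vim⁻ → EPI.CTC;
3. clonal ∧ Vim⁺ → pEMT.CTC;
4. tissue-marker⁺ ∧ ¬CD31⁺ → EPI.CTC / pEMT.CTC by Vim;
5. (non-altered ∨ CD31⁺) ∧ Vim⁺ ∧ eccentricity ≥ 0.8 → CEC;
6. CD31⁺ alone → CEC;
7. otherwise unclassified.

Genomics outranks proteomics on conflict (a clonal CD31⁺ cell is a CTC
with a logged conflict flag): clonal copy-number alteration is the
definition of tumor lineage here, and no clonal CD31⁺ cell has been
observed in practice — the rule exists so the case is handled
deterministically rather than silently. Cells with IF evidence only stay
unclassified: CK/Vim alone cannot separate the classes, and the package
does not guess. The elongation cutoff 0.8 operationalizes
"morphologically consistent with an endothelial cell"; CECs are shown
elongated but no numeric cutoff is published, so the value is a package
default, configurable, and the synthetic CEC eccentricity range
(0.85–0.97) sits clearly above the WBC/tumor ranges.

## Synthetic data: what it emulates, and what it does not

All inputs are generated with known ground truth. Intensities are
log-normal per channel per label (non-negative, right-skewed, like real
IF): WBC CK baseline mean 1.0, CV 0.15 (putting the 6-SDOM cutoff near
1.9 in readable units); rare-cell CK means 2.8–3.2 so true rare cells
clear detection with probability ≈ 0.995; pEMT vimentin is drawn
uniformly from the observed clonal Vim⁺ RFI range 0.0032–0.0522, with
the WBC vimentin baseline placed so the mean + 2 SD cutoff (~0.0022)
falls below that range. Rare-cell DAPI runs higher than leukocyte DAPI
(larger, often aneuploid nuclei), keeping the DAPI floor harmless to true
positives. Read counts follow expected count ∝ copy number × bin width ×
a unimodal GC factor $\exp(-s (g - 0.45)^2)$, with negative-binomial
noise (dispersion 0.1 — mild overdispersion typical of
whole-genome-amplified single cells; Poisson available). All tumor cells
of a draw share one clone: identical breakpoints with copy numbers in
{1, 3, 4} on a diploid baseline, so every alteration clears the ratio
thresholds. Ion counts add Poisson background at a configurable rate on
top of per-label expression levels, with a configurable EpCAM
co-expression fraction (default 0.5) among tumor cells.

One master seed fans out to named child streams (`child_seed`), so adding
a generator never perturbs another's draws, and equal seeds give
byte-identical outputs.

What passing tests on this generator show is that the *pipeline* — gates,
normalizations, segmentation, grouping, ladder — recovers known structure
at realistic signal-to-noise. What they cannot show: real slides have
segmentation artifacts, autofluorescence, doublets and clusters, optical
PSF effects, variable WGA quality, isotope spillover, and patient-level
marker heterogeneity; none of these are modeled, and per-patient findings
from archived slides are not reproducible from synthetic data.

## Numerical choices and problem sizes

- Ties at thresholds: detection and positivity comparisons are closed
  (≥); the copy-number neutral band is closed; `annotate_p` assigns
  `****` strictly below its smallest threshold, matching the printed
  "< 0.00001" convention (the more common `< 0.0001` is a configuration
  away).
- The star bands default to 0.05 / 0.01 / 0.001 / 0.00001; the example
  p-values often printed alongside figure legends (0.1234, 0.0332,
  0.0021, 0.0002) land in ns / * / ** / *** under these bands.
- Dunn's post hoc test uses pooled-ranking z-tests with the tie-corrected
  variance and Bonferroni adjustment over all pairs by default; the
  adjustment method is recorded in the result object because "Dunn's
  correction" alone underdetermines it.
- End-to-end runs in the tests and the acceptance script use a
  desk-scale genome of 500 bins at the standard 500,000-read depth
  (~1000 reads/bin) with `n_perm = 200`; the full 5000-bin setting is
  exercised where it matters most — GC-bias removal and breakpoint
  recovery — on single cells. These sizes are the package's validation
  profile choices.
- Under Poisson read noise, simulated clone breakpoints are recovered
  exactly at full scale; under the default negative-binomial dispersion,
  occasional low-contrast edges localize a few bins off, which the
  clonality tolerance (±2 bins, ≥2 shared breakpoints) and the IMC layer
  absorb — a cell whose clonality call degrades is still classified
  correctly through its protein evidence.

## Known limitations

- The CBS permutation test is exchangeability-based and conservative;
  extremely short segments (< `min_width` = 2 bins) are undetectable by
  construction.
- Clonality's transitive closure can chain groups through intermediate
  cells; with the default "≥ 2 shared breakpoints" rule and complex
  clones this is the intended behavior, but single-breakpoint cells are
  linked on their only breakpoint and are therefore the most
  error-prone members.
- The greedy nearest-neighbour COI relocation is optimal only when the
  IF→IMC jitter is small relative to cell spacing (the regime the
  re-staining workflow operates in); it does not solve a global
  assignment problem.
- Marker positivity at z ≥ 1.5 has a non-trivial family-wise
  false-positive rate across a 6-channel tissue panel (~30% under pure
  reference noise); the classification ladder tolerates this because
  tissue calls are only consulted when genomic evidence is absent and
  endothelial evidence is negative, but users reading the positivity
  matrix directly should raise per-marker cutoffs.
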