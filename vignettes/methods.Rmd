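---
title: "Models and methods behind teaAroma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind teaAroma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teaAroma)
```

`teaAroma` turns integrated GC-MS peak tables from a seasonal tea study
into aroma statistics, and pairs them with the expression statistics of
a small two-condition transcriptome and a qPCR validation panel. This
vignette documents the models, the tunable parameters and their
defaults, the synthetic-data generator's assumptions, and the design
choices made where the methodology was genuinely open.

## The GC-MS chain

**Retention-index calibration.** A ladder of n-alkanes (C9–C21 by
default) run under the identical temperature programme maps carbon
number to retention time. A peak at retention time $RT(x)$ bracketed by
alkanes $n$ and $n+1$ receives the Kovats index

$$ RI = 100\,n + 100\,\frac{RT(x) - RT(n)}{RT(n+1) - RT(n)}, $$

piecewise-linear and exactly $100n$ on the rungs. We deliberately
refuse to extrapolate: because ladder and samples share the programme,
a peak outside the ladder span signals a calibration fault, and
`retention_index()` raises an error rather than guessing.

**Library annotation.** Peaks are matched to the compound library by
nearest reference RI within a tolerance (default 5 index units, a
conservative capillary-column convention; configurable via
`ri_tolerance`). Exact distance ties break toward the lexicographically
smaller compound id and are flagged ambiguous, so the choice is
deterministic and visible. Mass-spectral matching — the other half of
routine identification — is intentionally out of scope; identity here
comes from RI alone.

**Internal-standard quantification.** Each run is spiked with a known
mass $m_s$ (ng) of internal standard (ethyl decanoate in the default
fixture). With $S_i$ and $S_s$ the compound and standard areas and $m$
the sample mass (g),

$$ C_i = \frac{S_i}{S_s}\cdot\frac{m_s}{m} \quad [\mathrm{ng/g}], $$

linear in $S_i$ and invariant to a joint rescaling of all areas. The
two masses are carried exactly in these units and entered once, as a
`quant_spec(sample_mass_g, is_mass_ng)`; the package never hard-codes a
gram-to-nanogram conversion for the spiked standard, since spike
protocols vary.

## Aroma statistics

**OAV.** The odor activity value of compound $i$ is $C_i / T_i$ with
$T_i$ its odor threshold in water (ng/g). OAV ≥ 1 is classed a
significant contributor, 0 ≤ OAV < 1 minor. Two choices matter:

* OAVs are computed *per replicate* and then summarised as mean ± SD,
  matching how replicate tables are reported, rather than as the OAV of
  the mean concentration (the two differ under noise).
* A compound without a threshold has an *undefined* OAV — it is skipped
  and listed, never scored zero. Treating it as zero would silently
  deflate dimension totals.

**Radar coordinates.** Per odor dimension (floral, fruity, green,
woody, roasted, chemical) the scored OAVs are summed and
log-transformed: coordinate $= \log_{10}(\text{total} + 1)$. The +1
offset (configurable) keeps empty dimensions — roasted aromas are often
absent — at exactly 0 instead of $-\infty$; base 10 is the
flavour-literature convention. We transform the log of the sum, not the
sum of logs: the dimension total is the quantity of interest and the
transform is only display compression.

**Terpene index.** $TI = S_l/(S_l+S_g)$ from linalool and geraniol
*peak areas* (the internal-standard factors would cancel anyway).
Bounded in [0, 1], scale-invariant, 0 iff linalool is absent, 1 iff
geraniol is. Both areas zero is an error, not a number.

**Group comparisons.** `compare_groups()` reports, side by side, the
two-sided equal-variance Student's t (the convention in seasonal
comparison figures) and the two-sided Mann–Whitney U, exact for group
sizes ≤ 8, plus per-group CV%. Reporting both rather than gating one on
the other is a deliberate reading of the ambiguous convention
"t-tests followed by a Mann–Whitney test"; no gate is defensible
without more detail, so none is implemented. No multiple-testing
correction is applied across compounds by default (matching common
practice in this literature); the DEG arm, where thousands of tests are
run, always corrects.

**PCA.** `pca_volatiles()` centres always and scales to unit variance
by default, because volatile concentrations span four orders of
magnitude and an unscaled PCA would be a one-compound plot. Constant
columns are dropped with a warning. Variance fractions are
nonincreasing and sum to 1; loadings are orthonormal.

## Expression arm

The module starts at the count matrix; read QC and alignment are
upstream tools, not statistics, and are out of scope.

**FPKM.** $\mathrm{FPKM}_{gj} = 10^9\, c_{gj} / (L_g\, N_j)$ with gene
length $L_g$ in bases and library size $N_j$ defaulting to the column
sum.

**DEG calling.** Per-gene two-sided Welch t on $\log_2(\mathrm{FPKM}+1)$,
Benjamini–Hochberg adjustment across genes, direction by the sign of
the mean log2 fold change subject to both thresholds (defaults
FDR ≤ 0.05 and |log2FC| ≥ 1, both configurable). Fold changes are
oriented winter over spring, so "up" means higher in winter. Genes
with zero variance in both groups and equal means are `ns` by
convention. The row-wise Welch implementation is vectorised for
simulation studies and is asserted equal to `stats::t.test` gene by
gene in the test suite.

**Enrichment.** For each gene set, the upper-tail hypergeometric
probability $P(X \ge k)$ of the observed DEG overlap, with the universe
fixed to all genes in the matrix (the least presumptuous universe when
none is declared), BH-adjusted across sets. The implementation calls
`stats::phyper`; the tests compare it against direct combinatorial
enumeration for every instance with a universe of up to 30 genes.

**qPCR.** Livak 2^−ΔΔCT: per replicate,
$\Delta Ct = Ct_\text{gene} - Ct_\text{reference}$; then
$\Delta\Delta Ct$ subtracts the *calibrator condition's mean* ΔCt, and
relative expression is $2^{-\Delta\Delta Ct}$. Spring is the calibrator
in the default fixture so winter fold changes read directly. The
calibrator's mean ΔΔCt is zero by construction, so its relative
expression is exactly 1 at zero noise and centred on 1 (geometric mean
1) under noise. Replicates missing a reference Ct are excluded with a
warning. Concordance with RNA-seq compares fold-change *signs* only —
the magnitudes are on different pipelines — and excludes zero fold
changes.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions
under which the analysis is validated.

* **Design.** Four groups (SDT, WDT, SFL, WFL) with six GC-MS
  replicates each; summary statistics use the first three (`stat_replicates`,
  default 3), reflecting the common report-three-of-six convention.
  The expression arm is 2000 genes, 3 vs 3, eight 30-gene pathways; the
  qPCR panel is six genes (three planted up, three down) plus an actin
  reference.
* **Anchoring.** The six key volatiles are planted at threshold ×
  published mean OAV for the two dry teas; linalool/geraniol are
  planted so the four group terpene indices are exactly 0.72, 0.87,
  0.31 and 0.00; the remaining ~34 library compounds share the rest of
  each group's total (16 080, 22 930, 1622.20 and 1120.32 ng/g) with
  class-level seasonal multipliers (ketones/esters richer in spring dry
  tea, alcohols/olefins and sesquiterpenes richer in winter, aldehydes
  and ketones richer in winter leaves). Between-replicate CVs for the
  key compounds come from their published mean/SD ratios (0.07–0.17);
  all other compounds default to CV 0.10.
* **Noise models.** Lognormal multiplicative noise on peak areas (mean
  1 at the stated CV — multiplicative detector/extraction noise);
  negative-binomial counts with dispersion 0.01 (a biological
  coefficient of variation of 0.1, the standard figure for genetically
  identical organisms — tea cultivars are clonal — and the regime in
  which a 3 vs 3 Welch/BH caller has high power at |log2FC| = 3);
  gaussian noise on the Ct scale (default SD 0.2 cycles). These are the
  minimal field-standard choices; none is fit to data.
* **Exactness.** Peak areas are generated by inverting the
  quantification formula and retention times by inverting the RI
  interpolation, so at zero noise every analysis stage composed with
  its generator is the identity on the ground truth (to floating-point
  rounding; tests assert 1e-9 relative). `simulate_counts(exact = TRUE)`
  emits rounded expected counts for the analogous deterministic check.
* **What it does not emulate.** Chromatographic peak shapes,
  co-elution, missing peaks near the detection limit, batch effects,
  GC drift, sequencing lane effects, primer-efficiency deviations.
  Passing tests therefore certify the *computational* chain — formulas,
  calling rules, orderings, determinism — not robustness to
  instrument-level artefacts in real data.

## Numerical and degenerate-input conventions

* Retention times outside the ladder, nonpositive masses, a zero
  internal-standard area, a zero universe, both terpene areas zero: all
  hard errors, never silently patched values.
* Two constant identical groups compare with p = 1 and a degenerate
  flag; constant different groups give p = 0 with infinite t.
* Validation errors from TSV readers cite the offending file line.
* All tables are UTF-8 tab-separated text with `#` comments; written
  doubles carry R's full default precision, so a write–read round trip
  preserves values to 15 significant digits and repeated runs at one
  seed are byte-identical.

## Problem sizes used in the checks

The packaged checks run at the study's own scale: 1000 random ladders
for the RI oracle, the full four-group fixture for closure checks, 200
seeded simulations each for the null-FDR and power studies of the DEG
caller (2000 genes, 3 vs 3), exhaustive enumeration up to a 30-gene
universe for the hypergeometric oracle, and full permutation
enumeration for Mann–Whitney groups of up to six replicates.

## Known limitations

* RI matching ignores mass spectra; isomers closer than the tolerance
  can only be disambiguated by the tie rule.
* The DEG caller is a plain per-gene Welch t; it does not share
  variance across genes and is conservative at n = 3 with genuinely
  dispersed counts (at dispersion 0.05 its power at |log2FC| = 3 drops
  well below the level it reaches at 0.01).
* Published seasonal headline totals are used only to anchor the
  generator's defaults; nothing in the package estimates them from real
  chromatograms.
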