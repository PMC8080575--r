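---
title: "Methods: expression-based dissection of the malignant ascites ecosystem"
author: "asceco"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression-based dissection of the malignant ascites ecosystem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asceco)
```

# Overview

Malignant ascites in advanced gastric cancer carries a mixed ecosystem of
disseminated tumor cells, tumor-associated macrophages (TAMs) and
peritoneum-derived mesothelial cells. `asceco` implements an expression-only
analysis chain for such data: normalization and quality control of
single-cell matrices, an expression-based copy-number proxy (the
chromosomal expression pattern, CEP), ligand–receptor interaction
enumeration between cell populations, extraction and scoring of M1/M2
macrophage polarization signatures, and survival stratification of bulk
cohorts by signature score. A synthetic-data module generates all of these
inputs with known ground truth, so the full chain is testable without any
sequencing data.

This vignette records the models, the tunable parameters and their
defaults, the numerical conventions, and the design decisions taken where
the procedure admitted more than one reasonable reading.

# Normalization and quality control

Full-length (SMART-seq style) data arrive as TPM. The expression value is
$E_{ij} = \log_2(\mathrm{TPM}_{ij}/10 + 1)$; the divisor 10 damps the
inflation of per-gene TPM in single cells with shallow complexity.
Droplet data arrive as UMI counts and are rescaled per cell to a total of
10,000 ("pseudo-TPM") before $E_{ij} = \log_2(\mathrm{pseudoTPM}_{ij}+1)$.
Both transforms are monotone and map 0 to 0; the pseudo-TPM transform is
invariant to per-cell sequencing depth.

A gene is *expressed* in a cell when $E_{ij} > 1$, strictly. The cell/gene
filter removes cells expressing fewer than `min_genes` (default 1000)
genes, then removes genes expressed in fewer than `min_cells` (default 10;
2 is appropriate for very small cohorts) of the *retained* cells. The
order — cells first, then genes, in a single pass — is a design decision:
it is deterministic, idempotent, and auditable from the `QCReport`, which
records thresholds, the order, and the removed identifiers. Droplet cells
are screened on three inclusive criteria: total counts in
[1000, 150000], detected genes in [200, 10000], and mitochondrial
percentage at most 20.

Cell typing by marker thresholds conjoins per-gene clauses
(e.g. macrophages: CD86 > 2, MUC16 < 1.1, EPCAM = 0, CD3D = 0 in E
units). Equality against zero is evaluated as $|E| < 10^{-12}$ to absorb
floating-point noise; cells matching no rule or more than one rule are
reported as unassigned, the latter flagged as ambiguous. Whether
"marker = 0" should mean a raw zero count or undetectable expression is
not decidable from the data model alone; treating it as $E \approx 0$ is
the stricter and simpler convention.

# Chromosomal expression patterns (CEP)

Aneuploid tumor cells shift the average expression of large contiguous
gene blocks. CEP turns this into a copy-number proxy:

1. restrict to autosomal genes (chromosomes 1–22) using a gene annotation
   (id, chromosome, start);
2. Z-normalize each gene across cells and clip to $[-3, 3]$ (the `clip`
   parameter), so single outlier cells cannot mimic a CNV. The population
   standard deviation (denominator $n$) is used and recorded in `params`;
   zero-variance genes map to zero;
3. within each chromosome, sort genes by start (ties broken by gene id for
   determinism) and average over every fully contained sliding window of
   150 consecutive genes (step 1). Chromosomes with fewer genes than the
   window contribute no windows. Shrinking edge windows were rejected
   because they would inflate variance at chromosome ends;
4. center each cell by subtracting its genome-wide mean window value.
   Centering is per cell (not per window) because its purpose is removing
   cell-level baseline shifts left by the Z-scores.

The per-cell instability score is the mean of squared CEP values
(MS); cells with planted copy-number events score higher, monotonically in
the event amplitude. Group comparisons of MS use a Welch two-sample
t-test restricted to the two groups named (tiny populations such as a
handful of mesothelial cells are excluded from testing rather than
pooled). Cell–cell similarity uses Pearson correlation over windows —
mirroring the idea that the *patterns*, not raw genes, characterize a
clone — followed by average-linkage agglomerative clustering on
$1 - r$; the linkage is a parameter because the original choice is not
recoverable from the procedure's description.

# Ligand–receptor interaction enumeration

Interactions are counted from binary expression calls at the strict
threshold $E > 1$. For a pair (L, R) and ordered direction
$g_1 \to g_2$, the intercellular count is the number of ordered pairs of
distinct cells with the sender expressing L and the receiver expressing
R; a single cell expressing both L and R is one *self-sufficient* event
and still participates in intercellular counts with other cells (the two
categories are tallied independently). Counting is directional, matching
the "ligand-expressing cell (L) > receptor-expressing cell (R)" reading
of directions. Top pairs per direction are ranked by count with
lexicographic (ligand, receptor) tie-breaks. Pair databases are TSVs with
`ligand`, `receptor`, `source` columns; merging databases tallies the
union with duplicates counted once, and pairs whose genes are absent from
the matrix are skipped and listed, never fatal.

Salient genes of a group (used to label interaction figures) are those
whose mean E across the group's cells strictly exceeds the q-quantile
(type-7 linear interpolation) of the candidate subset's means *and* whose
expressing-cell fraction strictly exceeds a floor — (0.95, 0.75) for the
broad view, (0.5, 0.1) for sparser cytokine panels.

# M1/M2 signature extraction

Reference macrophages differentiated to the M1 (LPS/IFN-γ) and M2
(IL-4/IL-10) poles provide the contrast. Differential expression uses a
negative-binomial GLM likelihood-ratio test written for this package:

* expected counts (RSEM-style, fractional) are rounded half-to-even, since
  the NB likelihood requires integers; all-zero genes are excluded and
  recorded;
* two normalization schemes are pluggable as size factors: TMM (trimmed
  mean of M-values against the cell with median-closest total count, 30%
  two-sided trim on M, 5% on A, precision-weighted) and median-of-ratios
  (per-cell median ratio to the per-gene geometric mean over all-positive
  genes). Both absorb depth and are rescaled to geometric mean 1;
* per-gene dispersions are moment estimates from the pooled within-group
  variance of normalized counts, shrunk toward an $a + b/\mu$ trend with
  configurable weight (default 0.35). This deliberately does not
  replicate any specific package's empirical-Bayes machinery; the
  simulation suite shows the resulting test holds its nominal type-I
  error (fraction of null p-values below 0.05 within [0.03, 0.07] at
  2000 genes);
* the LRT statistic $2(\ell_1 - \ell_0)$ for the group coefficient is
  referred to $\chi^2_1$; BH adjustment is applied per (donor, scheme)
  analysis; the log2 fold change is computed from normalized group means
  with pseudocount 0.5 (sign convention stated in the result metadata).

A gene enters the M1 (resp. M2) signature only if it passes
logFC > 2 and FDR < 0.05 *in both normalization schemes* and *in both
donors*; this double intersection is what suppresses method- and
donor-specific false positives, and under a null simulation it returns
empty signatures in ≥ 95% of seeds. An optional exclusion list (e.g.
dissociation-induced immediate-early genes such as EGR1, FOS, FOSB, JUN)
can be applied to final signatures; it is off by default.

Signature scoring is the mean E over the signature genes detected in the
matrix, with the number of genes actually used reported. Scores can be
affinely rescaled to $[-1, 1]$ for display. Polarization of a cell
population is summarized by OLS of the M2 score on the M1 score (slope
with 95% CI) together with the mean score difference; neither alone is
treated as a decision criterion.

# Survival stratification

Bulk cohort expression is on the same $\log_2(\mathrm{TPM}/10+1)$ scale.
Samples are stratified at the 25th/75th percentiles of the signature
score (type-7 interpolation): *high* strictly above the 75th, *low*
strictly below the 25th, everything else excluded. Strictness makes the
two groups symmetric and deterministic under ties; the convention is
recorded in the output. Kaplan–Meier curves and the two-group log-rank
test (hypergeometric variance, simultaneous risk sets at ties; fitted via
the `survival` package) compare high vs low. Single-gene stratification
and leave-one-out re-scoring reuse the same path. Cox modeling and stage
adjustment are out of scope by design; stage is carried as metadata only.

# The synthetic-data module

Every generator is a pure function of its configuration (including the
seed) and leaves the caller's RNG state untouched.

**Ascites populations** (`simulate_ascites`): negative-binomial counts
with log-normal gene means (meanlog 0, sdlog 1) and log-normal per-gene
dispersions (median 0.15). Genes are laid out on autosomes 1–22 in blocks
proportional to approximate per-chromosome protein-coding gene counts, so
at the default 5000 genes every large chromosome comfortably exceeds the
150-gene CEP window. The default population emulates the profiled ascites
samples: four patient-specific tumor clones (18+18+17+17 cells), 75
macrophages and 5 mesothelial cells. All tumor cells share a 300-gene
×1.5 trunk gain on chromosome 1; each clone additionally carries its own
gain or loss (×1.8 or ×0.5 over 200–250 genes), reproducing
patient-specific chromosomal expression patterns and the elevated
copy-number fluctuation of tumor cells relative to stroma. Ligand–
receptor planting raises CCL3/CCR1 in macrophages and IL1B (macrophage)
with IL1R2 (tumor) to a mean count of 25, high enough that essentially
every cell of the expressing population is called positive at $E > 1$.
What the generator does *not* emulate: transcriptome-wide gene–gene
correlation, doublets, ambient RNA, zero inflation beyond the NB, or
batch effects — so passing tests demonstrate correctness of the
computations under the stated model, not robustness to those artifacts.

**Reference macrophages** (`simulate_reference_macrophages`): two donors
with 49/23 and 48/22 M1/M2 cells (97 and 45 in total), NB dispersion 0.2,
baseline means log-normal (meanlog 1.5, sdlog 1.5) — deliberately deep,
as full-length expected counts are, so that a sizable set of genes is
detected in every cell and the median-of-ratios estimator is applicable.
Donor variability is a per-donor log-normal multiplicative factor on
every gene (sdlog 0.3), which shifts donors apart without confounding the
within-donor M1/M2 contrast. Planted truth: 60 shared M1-high and 20
shared M2-high genes at log2 fold change 3, plus 30 donor-specific decoy
DE genes per donor that the cross-donor intersection must reject.

**Bulk cohort** (`simulate_bulk_cohort`): signature genes load on a
latent per-sample activity (loading 0.5 E units per activity SD, residual
SD 0.3, baseline uniform in [2, 4]); background genes are noise. Survival
is exponential with log-hazard proportional to the standardized realized
signature score. The hazard coefficient is parameterized as the log
hazard ratio *between the top and bottom score quartiles*: the
standardized score is divided by the expected quartile-mean gap of a
standard normal, $2\varphi(\Phi^{-1}(0.75))/0.25 \approx 2.54$, so
`coef = log(2.5)` yields an empirical high-vs-low quartile hazard ratio
near 2.5. (Parameterizing on the raw standardized score would make the
quartile hazard ratio $\exp(2.54\,\beta)$, which is not the quantity the
stratified analysis estimates.) Censoring marks the configured fraction
of samples (default 20%) and replaces their time by a uniform fraction of
the event time. Baseline hazard defaults to $\log 2 / 730$ per day, a
two-year median.

# Problem sizes and numerical conventions

The simulation-based checks run at the following sizes, chosen as the
package's own test conditions: CEP recovery at 5000 genes × 150 cells;
interaction oracle equivalence on 200 random 12-cell fixtures; signature
recovery at the full two-donor reference (2000 genes, 142 cells) and the
null-intersection property over 100 seeds at 1000 genes; DE type-I error
on one 2000-gene, 40 + 40-cell null; survival calibration over 500 null
cohorts and power over 100 cohorts of 300 samples each. Quantiles use
type-7 linear interpolation throughout; all "over threshold" rules are
strict; gene sort ties are broken lexicographically; rounding of expected
counts is half-to-even; and every stochastic check runs under a fixed
recorded seed.

# Known limitations

* CEP is a relative, expression-based proxy: it cannot call absolute copy
  number, breakpoints, or events on chromosomes with fewer genes than the
  window, and strong transcriptional programs confined to a genomic
  neighborhood can mimic a CNV.
* The interaction tally is descriptive enumeration; it attaches no null
  model or permutation p-value to a pair.
* The DE engine is intentionally simpler than the mature count-model
  packages (no Cox–Reid adjusted profile likelihood, no empirical-Bayes
  trend fitting, no zero-inflation component); the dual-scheme,
  dual-donor intersection is the robustness mechanism instead, and the
  full-data signature sizes of the original analyses should be treated as
  approximate reproduction targets.
* Survival analysis is limited to two-group log-rank on overall survival;
  no proportional-hazards modeling or covariate adjustment is provided.
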