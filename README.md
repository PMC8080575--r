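# asceco

Expression-based analysis of the malignant ascites ecosystem.

Advanced gastric cancer disseminates into the peritoneal cavity, and the
resulting malignant ascites holds a mixed ecosystem: patient-specific
aneuploid tumor cells, tumor-associated macrophages (TAMs), and a handful
of mesothelial cells. `asceco` is an R package for dissecting such
ecosystems from expression data alone — single-cell matrices (full-length
TPM or droplet UMI) and bulk cohorts — aimed at computational biologists
who want each step of the analysis to be an explicit, testable function.

The package covers five connected analyses:

* **Normalization & QC** — E = log2(TPM/10 + 1) for full-length data and
  E = log2(pseudoTPM + 1) with per-cell rescaling to 10,000 for droplet
  data; strict E > 1 expression calls; cells-then-genes quality filters;
  droplet count/feature/mitochondrial screening; marker-threshold cell
  typing (e.g. macrophages: CD86 > 2, MUC16 < 1.1, EPCAM = 0, CD3D = 0).
* **Chromosomal expression patterns (CEP)** — a copy-number proxy: per-gene
  Z-scores clipped to [−3, 3], genome-ordered 150-gene sliding-window
  means per chromosome, per-cell centering; per-cell instability as the
  mean of squared CEP values (MS); Pearson-correlation clustering of CEP
  profiles; Welch t-test of MS between cell groups.
* **Ligand–receptor interactions** — directional counting of expression
  pairs between cell groups from binary E > 1 calls ("intercellular"),
  and single cells expressing both partners ("self-sufficient");
  top-pair rankings and salient-gene labeling by quantile/fraction rules.
* **M1/M2 macrophage signatures** — a negative-binomial GLM
  likelihood-ratio test with two pluggable normalizations (TMM,
  median-of-ratios); genes pass at logFC > 2 and FDR < 0.05; the final
  signature is the intersection across both normalization schemes and
  both reference donors. Signature scores E_s(S) are mean E over detected
  set genes, with [−1, 1] rescaling and an M1-vs-M2 polarization fit.
* **Survival stratification** — bulk samples split at the 25th/75th score
  percentiles into low/high groups, compared by Kaplan–Meier curves and
  the log-rank test; single-gene and leave-one-out variants.

A first-class synthetic-data module (`simulate_ascites`,
`simulate_reference_macrophages`, `simulate_bulk_cohort`) generates all
inputs with known ground truth — patient-specific CNV clones, planted
ligand–receptor co-expression, two-donor M1/M2 references with
donor-specific decoys, and cohorts whose hazard depends on an M2 score —
so the whole pipeline is exercised offline.

## Worked example

```r
library(asceco)

# simulated ascites: 4 tumor clones (70 cells), 75 macrophages,
# 5 mesothelial cells over 5000 genes, with planted CNV segments
sim <- simulate_ascites(ascites_config(seed = 1))
em  <- pseudo_tpm_normalize(sim$counts)
z   <- zscore_clip(em, sim$annotation, clip = 3)
cep <- compute_cep(z, sim$annotation, window = 150)
cep
#> CEPResult: 1986 windows (size 150) x 150 cells

ms  <- cnv_instability_ms(cep)
cmp <- compare_ms_groups(ms, sim$cell_groups, c("tumor", "macrophage"))
sprintf("MS tumor = %.4f, MS macrophage = %.4f, Welch t = %.1f, p = %.2g",
        cmp$means[1], cmp$means[2], cmp$t, cmp$p)
#> "MS tumor = 0.0267, MS macrophage = 0.0106, Welch t = 16.4, p = 2.5e-28"
```

Tumor cells carry the planted copy-number segments, so their CEP
fluctuation (MS) is about 2.5× the macrophage baseline and the group
difference is decisive. Signature extraction and survival follow the same
pattern:

```r
ref <- simulate_reference_macrophages(reference_config(seed = 1))
sig <- extract_m1_m2_signatures(ref$counts, ref$donor, ref$state)
sig$M1; sig$M2
#> SignatureSet 'M1': 60 genes
#> SignatureSet 'M2': 20 genes
sum(ref$truth$m1_shared %in% sig$M1$genes)   # all 60 planted genes found
#> [1] 60

coh <- simulate_bulk_cohort(cohort_config(seed = 1), sig$M2)
signature_survival(coh, sig$M2)
#> KMResult: high n=75, low n=75 (excluded 150); log-rank chisq=12.119, p=0.000499
```

The cohort generator links hazard to the M2 score at a quartile hazard
ratio of 2.5, and the high/low stratification recovers the association.

A thin command-line wrapper over the same functions ships in
`inst/cli/asceco.R` (subcommands `qc`, `cep`, `interact`, `score`,
`survival`, `simulate`); the vignette in `vignettes/` documents the
models, parameters and design decisions.

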