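---
title: "Methods: cell type-interaction mQTL mapping with imqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell type-interaction mQTL mapping with imqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Bulk-tissue DNA methylation is a mixture: the beta value observed at CpG
$j$ in individual $i$ is approximately $\sum_k \pi_{ik}\, m_{jk}$, the
cell-type proportions $\pi_{ik}$ weighting per-cell-type methylomes
$m_{jk}$. A genetic effect confined to cell type $k$ therefore appears in
bulk with its magnitude scaled by $\pi_{ik}$ — and so varies across
individuals with their composition. `imqtl` turns this into a test: for a
CpG, a cis variant and a cell type, it fits

$$\mathrm{DNAm}_i = \beta_0 + \beta_1 G_i + \beta_2 C_i +
\beta_3\, G_i \times C_i + \beta_4\,\mathrm{Age}_i + \beta_5\,\mathrm{Sex}_i
+ \sum_{k=1}^{5}\gamma_k \mathrm{PC}_{\mathrm{gen},ik}
+ \sum_{l=1}^{L}\delta_l \mathrm{PC}_{\mathrm{DNAm},il} + \varepsilon_i$$

by ordinary least squares, where the response is the rank-inverse-normal
(INT) transformed M-value and $C_i$ the INT-transformed estimated
proportion of the modeled cell type. $\beta_3$ is the interaction term of
interest; $\beta_1$ within this model is the "main effect", and the
genotype coefficient of the model *without* $C$ and $G \times C$ is the
"marginal effect". P-values come from the $t$ distribution with $n - p$
residual degrees of freedom, which matters at the sample sizes (tens to a
few hundred) typical of tissue methylation studies.

Key assumptions: effects are approximately linear in dosage and in
composition on the transformed scale; one cell type is modeled at a time
(a marginal interaction model — correlated compositions mean an
interaction mapped to one cell type can reflect a correlated one); the
estimated, not true, proportions enter the model.

### Multiple testing

Within a CpG the minimum interaction p-value over cis variants is
multiplied by the effective number of tests $M_\mathrm{eff}$ — the
smallest number of leading eigenvalues of the variant correlation matrix
capturing 99.5% of their sum — and across CpGs by the number of CpGs
tested; both products are capped at 1. A plain per-CpG Bonferroni is
available by setting `emt = FALSE`. The monotonicity
$p_\mathrm{bonf} \ge p_\mathrm{EMT} \ge p_\mathrm{min}$ is tested as an
invariant, and the family-wise error rate of the whole scheme is measured
on null simulations (below). The exact internals of published
effective-number-of-tests estimators vary; the eigenvalue rule used here
collapses perfectly correlated variants to one test and counts independent
variants nearly fully, the two limits that are unambiguous.

### Filters

Variant QC drops variants with missingness, exact Hardy-Weinberg
$p < 10^{-6}$ (conditional-on-allele-counts exact test, no mid-p), or
MAF $\le 0.1$. Interaction scans additionally require MAF $> 0.1$ in both
the upper and lower halves of the modeled cell type's proportion
(samples exactly at the median go to the lower half — a fixed, testable
rule), so that an apparent interaction cannot be driven by an allele
present in only one end of the composition distribution. Lead pairs are
chosen by smallest p, then smallest variant-CpG distance, then
lexicographic variant id — fully deterministic.

## Deconvolution

The reference panel is built from sorted-cell beta values: per cell type a
one-vs-rest moderated t-test (limma's empirical-Bayes variance
shrinkage), keeping CpGs with BH-FDR < 0.001 that are *hypomethylated* in
the target type and whose absolute mean beta difference against the pooled
mean of the other types exceeds a per-type threshold (0.9 immune, 0.8
epithelial, 0.81 fibroblast, 0.715 endothelial, all above a 0.7 floor that
keeps differences biological rather than technical). "Compared to the
others" is interpreted as the pooled rest mean — one comparison per type,
matching the single threshold each type carries; a CpG passing for two
types is assigned to the type with the larger difference. The centroid is
the per-type mean beta over the selected DMCs.

Proportions are estimated per bulk sample by robust regression of the
sample's beta values at panel CpGs on the centroid columns: Huber loss
with tuning constant 1.345, IRLS with at most 500 iterations, no intercept
(the centroid columns already span the constant under simplex mixing).
Negative coefficients are truncated to zero and the rest renormalized to
sum to one; renormalization keeps downstream rank-INT transforms stable.
Cell types with more than 50% exactly-zero estimates are excluded from
mapping (strict threshold: exactly 50% is retained). Panel validation
mixes one held-out sorted profile per type with flat-Dirichlet weights —
the maximum-entropy choice for "random weights summing to one" — and
reports per-type Pearson r and RMSE over 500 mixtures.

## Colocalization

Per variant, the Wakefield log approximate Bayes factor is
$\tfrac12\log\frac{V}{V+W} + \tfrac12 z^2 \frac{W}{V+W}$ with $V$ the
squared standard error and $\sqrt{W}$ = 0.15 (quantitative) or 0.2
(case-control). Under at most one causal variant per trait, the five
hypothesis sums are accumulated in log space with log-sum-exp (ABFs
overflow past $|z| \approx 40$), and $H_3$ uses the identity
$\sum_{i \ne j} = \sum_i \sum_j - \sum_{i=j}$. The implementation is
tested against brute-force enumeration over all causal-configuration pairs
for loci of up to 6 variants. Priors may be derived from genome-wide
counts: $p_1 = (n_1 - n_{12})/N$, $p_2 = (n_2 - n_{12})/N$,
$p_{12} = n_{12}/N$. Summary statistics lacking standard errors are
reconstructed from p, MAF and N with the quantitative-trait approximation
$\mathrm{SE} = 1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})N}$; interaction
statistics can equally be supplied as beta/SE directly.

## Numerical choices

- **INT offset**: ranks are mapped through $(r - 0.5)/n$ — the simple
  offset standard in QTL pipelines — with average ranks for ties;
  configurable in principle but fixed here for reproducibility.
- **Beta clipping**: bulk beta values are clipped to
  $[10^{-3}, 1 - 10^{-3}]$ so M-values stay finite.
- **Scan engine**: for a given variant the design matrix is identical for
  every CpG in its window, so one Cholesky factorization of $X^\top X$
  serves all of them; coefficients, SEs and p-values then cost one
  cross-product per pair. The engine is required (and tested) to match a
  plain `lm()` per-pair fit to $10^{-8}$ relative error; rank-deficient
  designs are skipped with a logged reason.
- **PCA**: genetic PCs use greedy LD pruning ($r^2 > 0.2$ within 500 kb,
  position order) then SVD of centred, scaled dosages; methylation PCs
  use SVD of the CpG-centred matrix. Component signs are fixed by making
  each component's largest-magnitude entry positive, so results are
  invariant to sample order.
- **Scree elbow**: the number of methylation PCs is chosen on the scree
  rescaled to the unit square, as the point with maximum perpendicular
  distance to the line joining the first and last scree points; the
  retained count is one less than the elbow index (the elbow sits on the
  first noise component). When the maximum distance is below 0.2 the
  scree has no pronounced elbow — the isotropic-noise regime, where
  measured distances cluster near 0.1 against 0.65+ for planted factors —
  and a single component is retained. An all-equal scree warns and
  returns 1.
- **kNN imputation** operates on CpG rows (neighbouring probes), the
  common orientation in methylation practice; distance is the root mean
  squared difference over shared observed columns, restricted to
  candidate rows observing the missing column.
- **Interaction regressor**: the product $G \times \mathrm{INT}(C)$ of the
  raw dosage with the transformed proportion, not a re-transformed
  product; the transform is a property of the proportion, and the product
  must remain linear in dosage for $\beta_3$ to retain its
  per-dosage-unit interpretation. The marginal model drops both the
  proportion and the product term (the classic bulk cis-mQTL
  specification); a switch retains the proportion as a covariate if
  desired.

## The synthetic-data generators

The generators produce exactly the structure the analysis assumes:
Hardy-Weinberg genotypes at chosen MAFs; Dirichlet compositions whose
concentration sum controls between-individual variance; bulk beta values
as proportion-weighted mixtures of per-cell-type baselines carrying
planted per-cell-type genetic effects plus Gaussian beta-scale noise,
clipped; sorted-cell references with planted hypomethylation; paired
summary-statistic tracks from variant-by-variant regressions of simulated
traits on a shared panel. A single master seed fans out to per-operation
child seeds, so stages can be re-run in isolation bit-identically.

Defaults describe a generic solid tissue: four cell types with Dirichlet
concentrations (5, 2, 1, 2) (a dominant epithelial compartment), per-CpG
grand means uniform on (0.2, 0.8) with per-type deviations of SD 0.1
(creating realistic cell-type DMS structure), residual SD 0.05 on the
beta scale — post-normalization array noise is not published anywhere we
know of, so this is a free parameter chosen once — and age/sex covariates
that by default do not affect methylation, exercising covariate plumbing
without biasing recovery.

What the generators deliberately do **not** emulate: realistic LD beyond
simple uniform correlation to a causal variant, probe chemistry and
normalization artefacts, non-MCAR missingness, batch structure, or
correlated environmental effects on methylation. Passing the recovery and
calibration studies therefore shows the estimators are correct under the
model's own assumptions — not that those assumptions hold in any
particular tissue.

## Simulation studies and their operating points

Problem sizes were chosen so each study carries real statistical content
at desk scale:

- **Planted-effect recovery** (`run_recovery_study`): 200 replicates of
  n = 2000 with one beta-scale effect of 0.2 planted in a minor, highly
  variable cell type, modeled as a *two-component* composition with
  proportions Beta(0.15, 0.85). The two-component design is deliberate: a
  power analysis of the two-part specificity criterion shows that with
  three or more Dirichlet components, the expected proportion of the
  target cell type within another type's upper-half stratum is bounded
  below by roughly a third of its overall mean, so at n = 2000 the
  stratified association in other strata is essentially always nominally
  significant in the same direction and no composition can satisfy the
  criterion reliably. A minor cell type facing the aggregate of the rest —
  the regime where cell-type-specific imQTLs are actually discovered, a
  variable minority population against a dominant background — isolates
  the criterion's logic cleanly.
- **Family-wise error** (`run_fwer_study`): 200 null studies of 50 CpGs by
  20 cis variants at n = 200, full scan with EMT and Bonferroni; the
  rejection rate is compared with 0.05 plus twice its Monte-Carlo SE.
- **Power versus composition variance** (`run_power_curve`): fixed mean
  proportion 0.25 and effect 0.15 at n = 200, Dirichlet concentrations
  40 / 8 / 2 (proportion variances 0.0046 / 0.021 / 0.063), 200
  replicates each; detection power must be non-decreasing in variance.
- **Panel study** (`run_panel_study`): 62/65/60/66 planted DMCs for
  immune/epithelial/fibroblast/endothelial cells (planted depths 0.93 /
  0.83 / 0.84 / 0.75, each a few noise-SDs above its selection threshold)
  among 800 background CpGs, 12 sorted training samples per type;
  validation on independently simulated held-out profiles via 500 noisy
  (SD 0.05) mixtures.
- **Colocalization calibration** (`run_coloc_calibration`): loci of 30–50
  variants, shared causal z of 8; posterior mass should concentrate on
  the shared-variant hypothesis.

## Known limitations

- One cell type is modeled at a time; with strongly correlated
  compositions the mapped cell type is an attribution, not an
  identification.
- The specificity criteria inherit the stratified design's resolution:
  with more than a handful of mutually correlated cell types, upper-half
  strata overlap and the criteria become conservative.
- The effective-number-of-tests estimator is an eigenvalue heuristic; its
  FWER behaviour is verified by simulation under the generator's LD
  structure, not under arbitrary real LD.
- RPC assumes the panel's cell types span the tissue; a missing cell type
  biases all proportions, and the zero-inflation filter only removes the
  clearest failures.
- The colocalization engine assumes at most one causal variant per trait
  per locus; allelic series require conditioning first (the secondary
  scan helps but is not a fine-mapper).
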