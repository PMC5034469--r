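---
title: "Methods: regional age-EWAS within GWAS LD blocks"
author: "admrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional age-EWAS within GWAS LD blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admrscan)
```

This vignette is the package's account of its statistical methods: the
models, the tunable parameters and their defaults, what the synthetic
study generator does and does not emulate, the numerical choices, and the
known limitations. Every number quoted here is computed by the package's
own tests or scripts; nothing is asserted that the code does not produce.

## The analysis model

The response for one genomic window is a vector of per-sample methylation
scores: depth-normalised read counts (RPM) in a 500-bp window, slid every
250 bp, restricted to windows lying fully inside GWAS LD blocks. The full
model, fit by maximum likelihood with `lme4`,

$$ m_{ij} = \beta_0 + \beta_{age}\,\mathrm{age}_{ij} + \beta_g g_i +
\boldsymbol\beta_c^\top \mathbf{c}_{ij} + u_{f(i)} + v_{p(i)} +
\varepsilon_{ij}, $$

has fixed effects for age at blood draw, the allelic count $g_i \in
\{0,1,2\}$ of the block's haplotype-tagging SNP, smoking status, batch and
four leukocyte fractions (lymphocyte, monocyte, neutrophil, eosinophil),
and two nested random intercepts: family $u_{f}$ and twin pair $v_{p}$.
The age term is tested by a likelihood-ratio test against the identical
model without it, referred to $\chi^2_1$; genotype-by-age interaction adds
`age:g` and is tested the same way. ML (not REML) fitting is used
throughout because the compared models differ in fixed effects.

Design choices that were genuinely open:

* **"Zygosity as a random effect"** is encoded as a per-pair intercept
  nested in family rather than a two-level zygosity factor: a variance
  component with two levels is inestimable, while a pair intercept is what
  actually carries twin resemblance (MZ and DZ pairs each get one;
  singletons get a private level). Longitudinal repeats reuse their
  individual's pair and family intercepts; no additional individual-level
  intercept is added, keeping exactly the two listed random effects.
* **Normalisation.** The per-window response is z-scored across samples by
  default (`inverse_normal` and `none` are available). The LRT is
  invariant to affine rescaling of the response, so the choice moves the
  coefficient scale, not the p-values; the z-score default mirrors
  standard per-probe standardisation in array practice. Zero-variance
  windows are flagged and excluded from modelling but retained in the
  Bonferroni denominator, as are windows whose optimiser fails.
* **Boundary variance estimates** (components fit at zero) keep the naive
  $\chi^2_1$ reference. This is the convention of ANOVA-style LRTs on
  mixed models; it can be mildly conservative for tests on variance
  components but is exact in the limit for fixed-effect tests.
* **Windows within blocks** means containment, not overlap: a window
  protruding from its block is excluded, so the tested set and the
  enrichment background are the same universe. Blacklist removal uses
  any-overlap (≥1 bp) — stricter than the enrichment rule — because a
  poor-mappability window is removed as a whole.

## LD blocks and the overlap engine

A genetic map (cM/Mb per interval) is segmented at a 10 cM/Mb threshold:
maximal runs of sub-threshold intervals become blocks; hotspot intervals
are boundary regions belonging to no block (the map interval's own span is
excluded rather than assigned to a neighbour — the conservative reading).
Blocks longer than 10 Mb are dropped, and only blocks holding a GWAS SNP
with $p < 10^{-7}$ are retained. Construction is idempotent and invariant
to subdividing map intervals at equal rate, which the tests check.

All enrichment statistics share one overlap primitive: a query interval
hits a feature track when its overlap with the *union* of the features is
at least a fraction $f$ of the query length (default $f = 0.1$, the
"moderate overlap" convention; boundary equality counts; coordinates are
0-based half-open). The implementation reduces and intersects intervals
with `IRanges` and is property-tested against a base-by-base counting
oracle. Raising $f$ is monotone: it can only turn hits into misses.

## a-DMR calling and replication tiers

Bonferroni-significant windows merge when they overlap **or are
book-ended** (gap exactly 0 bp) *and* share the sign of $\beta_{age}$.
With a 250-bp slide this means a single failing intervening window breaks
a region unless the flanking windows touch. Adjacent windows of opposite
sign split into separate regions, so every a-DMR is reported as hyper- or
hypomethylated, never mixed — the alternative (sign-free merging) would
occasionally fuse antagonistic neighbours into uninterpretable regions.
Region coordinates are the union of the contributing window spans.

Replication refits every window in an independent cohort with the reduced
model (batch fixed; family and pair random) and reports nested tiers:
same direction of effect; additionally $p < 0.05$; additionally below the
*discovery* Bonferroni level — at window level and at region level (a
region qualifies when any of its windows does). Array-style per-CpG
results can be scored against regions the same way (`probe_validation`),
including the no-coverage case.

## Cell-composition controls

Leukocyte fractions are covariates in the main model, but composition is
also interrogated directly, with a monozygotic-discordant design over six
blood-cell traits (CD4⁺ T, CD8⁺ T, T cell, NK, CD34⁺, B): windows must
have ≥90% of samples non-zero (the boundary counts); raw scores are
residualised on smoking, the four leukocyte fractions, age and batch;
residuals are rank inverse-normalised (Blom offset 3/8, ties averaged);
and the high-minus-low co-twin differences are tested by a one-sided
one-sample t-test. Pairs with zero trait discordance are dropped for that
trait — their ordering is undefined. "Signal for any of the six traits"
takes the minimum p without multiplicity adjustment, deliberately, since
the comparison of interest is a fraction against its own background, not
a calibrated test. With full covariate adjustment the p-value is only
approximately invariant to monotone transforms of the raw scores (the
residual ranks can change); with intercept-only adjustment
(`adjust = FALSE`) the invariance is exact, and that is the form the
property test pins down.

## Disease enrichment

a-DMR-hosting blocks are mapped through their SNPs to traits and 15 broad
disease classes (blocks deduplicated, SNPs deduplicated by rsid, trait
associations kept with multiplicity). The age-related enrichment uses a
2×2 Fisher exact test (a-DMR block × age-related block); the sample
(cross-product) odds ratio is reported alongside the conditional-MLE
estimate, with a Haldane 0.5 correction flagged when a cell is empty. The
permutation analogue draws the age-related count of blocks uniformly
without replacement and scores overlap with the a-DMR blocks; the
empirical p uses add-one smoothing, $(1 + \#\{T^* \ge T\})/(B+1)$, so it
is never zero at finite $B$ and converges to the exact hypergeometric
upper tail, which the tests verify. Pearson χ² without continuity
correction is the default for the (large-count) fold-enrichment tables;
the MZ blood-trait comparison uses R's continuity-corrected test.

## The synthetic study generator

The generator emulates the *statistical structure* of a blood MeDIP-seq
twin age-EWAS so that every downstream stage can be validated against
known truth. Defaults (all configurable through `sim_config()`):

* Two 100-kb chromosomes; genetic-map tiles of 5 kb with baseline rates
  0.1–2 cM/Mb and Poisson hotspots (10 per Mb) at 12–60 cM/Mb; a 60-SNP
  GWAS catalogue with p-values straddling $10^{-7}$; CpG islands with
  10× CpG density; blacklist, chromatin-state and 12-tissue DHS tracks
  (4 blood-related).
* 80 families — twin pairs (half MZ) with 15% singletons; co-twins share
  age at draw; ages uniform on 19–82 years; 20% of individuals get a
  second draw ~2.18 years later. MZ co-twins share genotypes; DZ co-twins
  draw alleles from simulated parents (allelic correlation 1/2, which the
  tests verify). Leukocyte fractions are Dirichlet; the six blood-cell
  traits are standardised scores loading on the lymphocyte fraction
  (CD34⁺ independent), so they correlate with — but are not captured by —
  the adjusted fractions.
* Window values: a CpG-density baseline (offset 2 + 0.25 per CpG) plus
  planted effects, per-window family and pair intercepts (SD 0.3 each),
  Gaussian noise (SD 1), small per-window smoking and batch shifts
  (SD 0.1), a mean-one lognormal depth factor (log-SD 0.05), flooring at
  zero, 0.5% random dropout, and 2% of windows heavily zero-inflated
  (30% zeros) to exercise the non-zero filter. Ages enter centred at the
  range midpoint so hypomethylated trajectories do not collide with the
  zero floor; the depth factor is mean-corrected so raw-scale slopes stay
  unbiased.
* Planted truth: 30 age windows (|slope| 0.05–0.09 units/year, random
  sign, laid in runs of 1–3 adjacent windows so merged regions arise), 20
  genotype windows (0.5–1.0 per allele), 10 genotype-by-age windows
  (interaction slope 0.02–0.04 opposing the main slope), 20 blood-trait
  windows (0.8–1.5 per trait SD). Effect magnitudes were chosen so
  planted age effects sit well clear of the Bonferroni boundary at the
  default cohort size — the recall-of-truth test expects every planted
  region recovered — while genotype, interaction and cell effects are
  subtle enough that the corresponding negative controls are informative.

What the generator does **not** emulate: read-level sampling (values are
Gaussian around the baseline rather than counts), spatial correlation of
noise between overlapping windows (window noise is independent, so merged
regions arise only from planted runs), realistic chromosome sizes or
LD-block length distributions (at 100 kb nothing approaches the 10-Mb
pruning bound — pruning is tested on constructed maps), linkage between
the tagging SNP and unmodelled variants, and ACE-style decomposition of
twin resemblance (two nested intercepts stand in for it). Consequently,
passing tests demonstrate the pipeline's correctness and calibration
under the stated generative model, not robustness to every artefact of
real MeDIP-seq data.

## Calibration and problem sizes

The acceptance suite runs one simulation at the default conditions with
the age-window count raised to 200 on a 150-kb-per-chromosome genome
(~1100 windows, ~750 null), and checks: empirical type-I error of the age
LRT within the 99% binomial band around 0.05 with uniform null p-values
(Kolmogorov–Smirnov); slope recovery unbiased within 2 Monte-Carlo SEs
with 95%-CI coverage in [90%, 98%]; exact agreement of the mixed model
with OLS when variance components vanish (tolerance 1e-6, on a fixture
whose ML variance estimate lies on the zero boundary) and with
closed-form GLS on balanced pairs (1e-5); uniform age p-values on
genotype-driven windows; no cell-driven window among called a-DMRs and a
non-significant MZ-discordance χ²; hand-enumerated merge fixtures
reproduced exactly; and byte-identical summaries for repeated runs at one
seed. The end-to-end demonstration uses the default ~700-window study —
sizes chosen to keep the full validation comfortably interactive on a
single core.

Numerical conventions: optimiser budget 200 iterations per fit (windows
within one LD block share a design, so the model is fit once per block
and refitted per response, which is exact); negative LRT statistics are
clipped at zero and tolerated to $-10^{-6}$; empirical p-values are
add-one smoothed; all coordinate arithmetic is 0-based half-open; every
output file carries a provenance header with package version, seed and a
config hash.

## Limitations

* The $\chi^2_1$ reference for the LRT is asymptotic; at a few hundred
  effective units (pairs) mild miscalibration by seed is visible and is
  why the type-I band is the 99% binomial interval, not a point.
* ML standard errors carry no small-sample degrees-of-freedom correction,
  so CI coverage sits at the lower half of its nominal band.
* The blood-trait control inherits the power of the MZ-discordant design:
  with few discordant pairs, absence of enrichment is weak evidence.
* At toy genome scale, block-level disease fractions are coarse (a
  handful of blocks), so the Fisher/permutation machinery is exercised on
  the reconstructed published-scale instance in the acceptance suite
  rather than on the simulated genome.
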