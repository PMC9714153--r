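---
title: "mQTL-aware EWAS: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mQTL-aware EWAS: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

DNA methylation at a CpG site is measured as a beta value — the
fraction of methylated molecules, in [0, 1] — and at roughly a fifth of
array CpGs that fraction is partly controlled by nearby common genetic
variants (cis methylation quantitative trait loci, mQTLs). An
epigenome-wide association study (EWAS) that regresses methylation on a
phenotype while ignoring this genetic component mis-attributes variance:
estimates can be biased when genotype and phenotype are correlated, and
are noisier even when they are not. `mqtlewas` implements the full
procedure for doing EWAS with the genetic component modeled explicitly:
discover each CpG's cis-mQTL, pool discoveries across datasets into a
per-CpG mQTL database, and refit the EWAS with the matched mQTL dosage
as a covariate, quantifying what changed. Because real neonatal
genotype/methylation cohorts are access-restricted, the package also
ships a synthetic cohort generator with planted effects; every claim
the package makes about itself is tested against that generator's truth
tables.

## The cis-mQTL scan

For CpG $j$ with methylation vector $y_j$ and the dosages $g_v$ of the
$K_j$ variants within 1 Mb on either side (a 2 Mb total window), the
scan fits the marginal model

$$y_{ij} = \alpha + \beta_v g_{iv} + \gamma^\top z_i + \varepsilon_{ij}$$

for each cis variant $v$, where $z_i$ holds the scan covariates: sex,
methylation batch, and the first five genetic principal components.
(The EWAS stage later uses a different, richer covariate set; the two
stages are deliberately kept distinct.) Computationally the scan
residualizes $y_j$ and all cis dosages on $z$ once and regresses
residuals on residuals; by the Frisch–Waugh theorem this equals the
full-design fit, and the test suite holds the two paths together to
1e-8. The top SNP is the one with the smallest nominal P; ties are
broken by distance to the CpG, then lexicographic variant id.

The minimum of $K_j$ correlated tests is not uniform under the null, so
nominal P values are calibrated by permutation: the covariate-residualized
methylation vector is permuted $n_{perm} = 1000$ times (genotypes and
covariates held fixed, which preserves the cis LD structure of the
window and the covariate geometry), and the window-minimum P is
recorded for each permutation. A $\mathrm{Beta}(a, b)$ distribution is
fitted to the 1000 minima by maximum likelihood — method-of-moments
start, Newton iterations on the score equations to 1e-8, falling back
to method of moments with a flagged record after 100 iterations — and

$$p_{adj} = F_{\mathrm{Beta}(a,b)}(p_{nom}^{top}).$$

The empirical permutation P, $(1 + \#\{p_{min} \le p_{nom}^{top}\}) /
(n_{perm} + 1)$, is reported alongside; the beta form interpolates
below the $1/(n_{perm}+1)$ floor of the empirical estimate. For $K$
independent null variants the minimum of $K$ uniforms is
$\mathrm{Beta}(1, K)$, which the tests use as an oracle: fitted $b$
tracks $K$, and a single null variant gives $a \approx b \approx 1$.
Degenerate perfect fits (numerically zero residual) report $p = 0$ by
convention and are excluded from the beta fit.

Permutation streams are seeded per CpG by a stable hash of the global
seed and the CpG id, so results are identical no matter how the CpG
loop is ordered or partitioned.

CpGs on sex chromosomes, and CpGs sitting on a variant with MAF > 0.05
(at the CpG position or the next base), are excluded before scanning,
mirroring standard probe hygiene for polymorphism-confounded probes.

## From scans to a database

Each dataset (a cohort stratum scanned separately) contributes its
CpG–SNP pairs with adjusted P < 0.05. A pair seen in two or more
datasets is pooled by fixed-effects inverse-variance meta-analysis
after allele harmonization:

$$w_i = 1/se_i^2, \qquad
\hat\beta = \frac{\sum w_i \beta_i}{\sum w_i}, \qquad
se(\hat\beta) = \Big(\sum w_i\Big)^{-1/2},$$

with $p = 2\Phi(-|z|)$ computed on the log scale so that P values far
below the double-precision underflow limit still carry a usable
$\log_{10} p$. Pairs seen in a single dataset keep that dataset's
statistics — inclusion requires significance in *any one* dataset, not
all, since the union of per-dataset discoveries is what the database
records. Harmonization aligns effect alleles within each pair, negating
flipped effects, and drops strand-ambiguous variants (A/T, C/G) with
MAF in [0.4, 0.5], whose orientation frequency cannot resolve. Within
each CpG, records are ranked by meta P (ties by distance, then id); the
rank-1 SNP is the CpG's *assigned* mQTL, and only that SNP enters the
EWAS design — lower ranks stay in the database but are not used as
covariates.

Cross-dataset agreement of assigned mQTLs is summarized as: same SNP;
different SNP but in LD (dosage $r^2 > 0.5$); either. LD is the squared
Pearson correlation of dosage vectors, which is invariant to allele
flips.

## The paired EWAS

Per CpG, two nested linear models on the beta values:

* **plain**: `beta ~ birthweight + sex + gestational_age + batch +
  case_status + CD8T + CD4T + NK + Bcell + Mono + nRBC + PC1..PC10`
* **mQTL**: the same plus the assigned mQTL dosage (when the CpG has
  one).

Granulocytes — the dominant neonatal class — are deliberately excluded
from the cell-fraction block: the seven fractions sum to one, so the
seventh column is collinear and the design builder refuses it. Samples
with gestational age below 30 weeks are excluded up front (with a
logged count), since extreme prematurity distorts the
birthweight–methylation relationship. A sensitivity variant adds
maternal weight gain, dropping (and counting) rows where it is missing.

The contribution of the mQTL term is tested by the partial F-test

$$F = \frac{(RSS_{red} - RSS_{full})/q}{RSS_{full}/df_{full}},$$

which for $q = 1$ equals the squared t of the mQTL coefficient — an
identity the tests enforce to 1e-8. Per-dataset results are pooled per
platform with the same inverse-variance machinery and Bonferroni
corrected at $\alpha / m$ over the $m$ CpGs pooled. Model comparison
reports, per CpG, the relative coefficient change
$(\beta_{mqtl} - \beta_{plain}) / |\beta_{plain}|$ (flagged above 20%
in either direction, undefined and marked when $\beta_{plain} = 0$),
whether the P value strictly improved, and counts of gained/lost
Bonferroni significance. Bonferroni is the headline correction; a
Benjamini–Hochberg column is available behind a flag for the
changed-coefficient follow-up analyses.

## Enrichment

Whether mQTL-matched CpGs concentrate in genomic features is tested two
ways, labeled distinctly because they answer slightly different
questions. The 2×2 Fisher exact test splits CpGs into mQTL-matched vs
not and in-feature vs not; its two-sided P sums hypergeometric
probabilities of tables no more likely than the observed one (exact up
to a minimum margin of 10^4^, chi-squared without continuity correction
beyond — at that size the approximation error is far below any
decision threshold). Fold enrichment is
$(a/(a+b)) / ((a+c)/n)$ and the odds ratio is $ad/bc$. The
island-relation view instead compares the proportion of mQTL-matched
CpGs in each category (Island, N_Shore, S_Shore, N_Shelf, S_Shelf,
OpenSea) against the *array-wide* proportion — a superset, not the
complement — with a two-sample proportion chi-squared test without
continuity correction and star coding. The superset comparison is
conservative (the two groups overlap), increasingly so as the
mQTL-matched fraction grows; the disjoint Fisher P is reported
alongside. A combined shore-vs-rest test is attached because shores are
where mQTL-matched CpGs are expected to concentrate.

## Cell-type deconvolution

The EWAS needs cell-composition covariates. Given a reference matrix
$R$ (marker CpGs × 7 cell classes: CD8T, CD4T, NK, Bcell, Mono, Gran,
nRBC), a sample's proportions solve

$$\min_p \|y - Rp\|^2 \quad \text{s.t. } p \ge 0,$$

by Lawson–Hanson active-set nonnegative least squares, then renormalize
onto the simplex $\sum p = 1$. The solver is deterministic and the
simplex constraint holds to 1e-8 always. Reference library *selection*
(an IDOL-style optimization over external flow-sorted data) is out of
scope: the function accepts a fixed reference CpG set, and the
generator emits a matching synthetic reference whose markers are
hypermethylated in their own class (~0.85) and hypomethylated elsewhere
(~0.15). At least 90% of reference CpGs must be present in a sample's
profile.

## What the generator emulates — and what it does not

`sim_config()` describes a two-stratum newborn cohort: a smaller NLW
and a larger LAT stratum (the larger admixed stratum mirrors the usual
composition of multi-ethnic US birth cohorts and makes the
power-vs-sample-size asymmetry reproducible). Genotypes are sums of two
haplotypes drawn by thresholding a latent Gaussian AR(1) process within
LD blocks; the latent correlation is calibrated per adjacent pair (via
the bivariate-normal orthant probability) so that the realized
*allele-level* correlation equals `ld_rho`, and allele frequencies are
drawn per block with small jitter, because adjacent variants with very
different frequencies cannot be in strong LD.
 Methylation is additive
on the raw beta scale with clipping to [0, 1] — not on M-values —
because the downstream models regress beta values directly:

$$\beta_{ij} = \mathrm{clip}\big(\mu_j + b^{mqtl}_j g_{ij}
  + b^{bw}_j (BW_i - 3400) + \text{batch} + \text{sex}
  + \text{cell effects} + N(0, \sigma)\big),$$

with baselines $\mu_j$ from a trimodal mixture near 0.1/0.5/0.9, as on
real arrays. Birthweight follows
$3400 + 150\,(GA - 39) + 120\,I(\text{male}) + N(0, 400)$ grams with
gestational age $N(39, 1.5)$ weeks; a small fraction (default 2%) of
samples is drawn preterm below 30 weeks precisely so the exclusion
rule has something to exclude. Default effect scales: mQTL effects
$N(0, 0.05)$ beta-units per allele (or a fixed magnitude when
`mqtl_effect_fixed` is set), birthweight effects 0.02 beta-units per
1000 g — the scale at which neonatal birthweight EWAS effects are
reported. Cell proportions are Dirichlet with a granulocyte-dominated
mean, as in cord blood.

Passing tests on this generator demonstrate calibration, recovery and
internal consistency of the statistical machinery. They do not
demonstrate robustness to things the generator omits: probe-chemistry
(type I/II) artifacts, admixture LD between blocks, trans effects,
batch-by-probe interactions, or non-additive (dominance) genetic
effects. Clipping at the beta boundaries attenuates planted effects for
CpGs near 0 or 1; this is a real phenomenon on arrays too, but it means
effect-recovery checks are run at moderate baselines.

## Numerical and design choices

* All regressions go through one QR path; perfect fits (RSS numerically
  zero relative to the response scale) report se = 0 and p = 0 by
  convention; rank-deficient designs error naming the aliased columns
  rather than silently dropping them.
* Missing dosages are mean-imputed per variant before regression
  (missingness is capped at 5% by QC upstream, so the gaps are small).
* Genotype QC order: missingness → exact Hardy–Weinberg (P < 1e-4) →
  MAF (< 0.01) → imputation R² (≤ 0.6). HWE uses the exact conditional
  test on rounded hard calls; dosages with fractional part above 0.1
  are treated as too uncertain to hard-call and are left out of that
  variant's HWE counts. The filters are idempotent.
* Coordinates are 1-based for CpGs and SNPs (as in array manifests);
  BED stays native 0-based half-open and is converted exactly once, in
  `read_features()`. Genome builds are treated as opaque: all inputs
  must share one.
* What is permuted: the covariate-residualized phenotype. Permuting
  genotypes instead would break the LD of the window; permuting raw
  phenotype would break the covariate structure. Full permutation
  (1000 per CpG) is used rather than an adaptive/downsampled scheme —
  at these problem sizes the single matrix product per permutation
  batch makes full permutation cheap.
* Meta-analysis is fixed-effects only, with no heterogeneity statistic;
  the direction string uses METAL-style "+/−/?" with "?" for
  non-contributing datasets.
* The "proportion tests" for island categories are chi-squared without
  continuity correction; with the category counts involved the
  correction is negligible and omitting it matches the large-sample
  convention.
* P values below ~1e-308 are preserved as `log10_p`.

## Problem sizes used by the test suite

The calibration and recovery properties are exercised at the sizes the
procedure is designed around: a 500-CpG null scan with 1000
permutations and n = 300 (about 50 cis variants per 2 Mb window) for
null calibration and beta-approximation fidelity; 150 planted CpGs at
0.06 beta-units/allele, MAF 0.3 for recovery; 120-CpG two-stratum
cohorts for the EWAS recovery, variance-reduction and de-biasing
checks; exhaustive enumeration of 2×2 tables up to total 40 for Fisher
exactness; and a 40-CpG end-to-end pipeline run executed twice for
determinism. Per-CpG ±2 SE recovery of planted birthweight effects is
asserted as at least 85% of planted CpGs covered, the nominal per-CpG
coverage being ~95%.

## Known limitations

Trans-mQTLs are out of scope (the cis window is the model); conditional
multi-SNP models are not fitted, so an assigned mQTL may tag rather
than be the causal variant; the EWAS adjusts for exactly one (top)
mQTL per CpG; and the enrichment machinery tests marginal overlap, not
conditional enrichment given CpG density. The synthetic reference for
deconvolution is idealized — real flow-sorted references have
correlated markers and class-imbalanced information content.
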