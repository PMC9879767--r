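---
title: "Maternal amino acids and offspring birthweight: methods behind matmr"
author: "matmr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maternal amino acids and offspring birthweight: methods behind matmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matmr)
```

## The scientific question and the study design

Amino acids cross the placenta and are the substrate of fetal protein
synthesis, yet whether differences in *maternal* circulating levels cause
differences in fetal growth is unresolved; small supplementation trials and
confounded observational studies disagree. Two-sample Mendelian
randomisation (MR) addresses this with maternal genetic variants as
instrumental variables: sample 1 provides SNP–amino-acid associations from
a large metabolite GWAS (tens of thousands of adults), sample 2 provides
SNP–birthweight associations from a maternal GWAS of offspring birthweight.
Under the instrumental-variable assumptions — relevance, independence of
confounders, and exclusion (the variant affects birthweight only through
the amino acid) — the ratio of the two association scales estimates the
causal effect of a 1 SD higher maternal level on offspring birthweight.

`matmr` implements that pipeline end to end, together with the sensitivity
and validation analyses that probe each assumption, and a generative
simulator of mother–child duos so that every stage can be exercised and
calibrated without external data.

## Reconstructing exposure effects from z-score meta-analyses

Metabolite GWAS are typically meta-analysed on the z-score scale across
heterogeneous measurement platforms. For a standardised trait the
per-allele effect and its standard error are recovered from the z-score
$z$, effect-allele frequency $p$ and sample size $n$ as

$$\mathrm{se} = \frac{1}{\sqrt{2p(1-p)(n + z^2)}}, \qquad
  \hat\beta = z \cdot \mathrm{se}.$$

The formula involves the frequency only through $p(1-p)$, so whether the
effect-allele frequency or the folded minor-allele frequency is supplied is
immaterial. `metaAnalyseZ()` implements the sample-size-weighted
combination $z_{\mathrm{meta}} = \sum_i \sqrt{n_i}\, z_i \big/
\sqrt{\sum_i n_i}$ after aligning every study to a common effect allele;
`qcFilter()` applies the post-meta-analysis exclusions (minor allele
frequency below 0.5%, capture by fewer than half the studies *or* half the
maximal sample size — either coverage criterion suffices, matching the
disjunctive phrasing of the rule). The pooled effect-allele frequency is
the $n$-weighted mean, a documented choice (the source pipelines do not
specify one); it is configurable by supplying pre-pooled tables instead.

## Instrument construction

**Selection.** Instruments must pass the metabolome-wide adjusted
threshold $5\times10^{-8}/102 = 4.9\times10^{-10}$ (the genome-wide level
divided by the number of principal components explaining 95% of metabolite
variation), applied strictly (`<`).

**Clumping.** `clumpInstruments()` is greedy: the lowest-p unclaimed SNP
becomes an index variant and claims every unclaimed SNP with $r^2 \ge$
threshold within the window. Two parameterisations matter in practice: the
sentinel stage ($r^2 < 0.05$, ±1 Mb) and the stringent stage
($r^2 < 0.01$, ±10,000 kb). LD is consumed as a precomputed pairwise
table — desk-scale testability was preferred over bundling a reference
panel — and absent pairs are treated as $r^2 = 0$. Ties are broken by
p-value, then position, then SNP id, so output is invariant to input row
order. Positions are 1-based and the window is symmetric.

**Proxies.** Instruments absent from the outcome GWAS are substituted by
their highest-$r^2$ proxy at $r^2 \ge 0.8$ when one exists in the outcome
table; the optional `EA_MAP` column (`"tEA=pEA,tOA=pOA"`) translates proxy
alleles into the target's allele space. Unproxiable SNPs are dropped with
a logged reason.

**Harmonisation.** `harmonise()` aligns outcome effects to the exposure's
effect allele: identical orientation is kept, swapped alleles flip the
sign and frequency, strand complements are resolved for non-palindromic
variants. Palindromic (A/T, C/G) variants carry no strand information in
their alleles; they are retained only when the minor-allele frequency is
below 0.30 on both sides *and* the frequencies agree under one orientation
(|Δeaf| ≤ 0.08), in which case the frequency decides the orientation.
Both thresholds are configurable; 0.30 is a conventional safe margin well
below the 0.42–0.48 frequencies at which ambiguity actually bit in the
motivating data, and 0.08 is a documented default rather than an inferred
convention. Multi-allelic (duplicated) sites are excluded at load.

## The estimator suite

With aligned per-instrument effects $(\hat\beta_{Xj}, \hat\beta_{Yj})$ and
outcome standard errors $\sigma_{Yj}$, weights are $w_j = 1/\sigma_{Yj}^2$.

- **Wald ratio** (single instrument):
  $\hat\theta = \hat\beta_Y/\hat\beta_X$, with first-order delta-method
  standard error $\sigma_Y/|\hat\beta_X|$. The first-order form is the
  standard default in two-sample MR; the second-order correction is
  negligible at the instrument strengths enforced here (F ≫ 10).
- **IVW, multiplicative random effects**: weighted regression through the
  origin, $\hat\theta = \sum w_j \hat\beta_{Xj}\hat\beta_{Yj} / \sum w_j
  \hat\beta_{Xj}^2$, fixed-effect $\mathrm{se}_0 = (\sum w_j
  \hat\beta_{Xj}^2)^{-1/2}$, inflated by the residual scale
  $\sqrt{Q/(k-1)}$ floored at 1. The floor (convention, configurable via
  `reFloor = FALSE`) prevents under-homogeneous sets from reporting less
  than the fixed-effect uncertainty.
- **Cochran's Q / I²** on the per-SNP ratios with weights
  $(\hat\beta_{Xj}/\sigma_{Yj})^2$; $I^2 = \max\{0, 100\,(Q - df)/Q\}$.
- **MR-Egger**: the same weighted regression with a free intercept, after
  re-orienting instruments so all exposure effects are positive. The
  intercept estimates average directional pleiotropy; the slope is the
  causal effect under the InSIDE assumption. Standard errors use the same
  floored multiplicative residual scaling. The companion statistic
  $I^2_{GX} = \max\{0, (Q_{GX} - (k-1))/Q_{GX}\}$ (with $Q_{GX}$ the
  precision-weighted spread of the exposure effects) quantifies regression
  dilution from exposure measurement error; values below 0.9 raise a
  caution flag on the Egger estimates.
- **Weighted median**: per-SNP ratios ordered with normalised
  inverse-variance weights (first-order ratio variance
  $\sigma_{Yj}^2/\hat\beta_{Xj}^2 + \hat\beta_{Yj}^2\sigma_{Xj}^2/
  \hat\beta_{Xj}^4$); the estimate interpolates the standardised
  cumulative weight at 50% and is consistent while more than half the
  weight comes from valid instruments. Its standard error is a parametric
  bootstrap (per-SNP effects redrawn from their sampling distributions;
  default 1000 replicates; an explicit seed is required).
- **Influence**: leave-one-out IVW for $k \ge 2$ and Cook's distances for
  $k \ge 5$ on the weight-transformed through-origin regression, flagging
  $D_j > 4/k$.

`runMR()` applies the policy used in the motivating analysis: one
instrument → Wald ratio; two or more → IVW + Q + leave-one-out; five or
more → additionally weighted median, MR-Egger and Cook's distances.
Exposures with no surviving instruments (the cysteine case) are skipped
with a reason. Results are reported in outcome SD units and in grams via
the 484 g-per-SD conversion (the median birthweight SD of the contributing
cohorts).

Confidence intervals and p-values use normal quantiles throughout,
including the Egger intercept — a deliberate, documented convention. Its
cost is mild anti-conservatism at small $k$ (at $k = 15$ the intercept
test's size is ≈ 7% rather than 5%); the calibration scenario below
therefore works in the large-$k$ regime where the convention is accurate,
and small-$k$ Egger p-values should be read with that in mind.

## Multivariable MR

To probe pleiotropy routed through body-mass index or smoking, the
instruments of all exposures are unioned and re-clumped at the stricter
$r^2 < 0.001$ (±10,000 kb) threshold with priority by the smallest p
across exposures (`jointClump()`); union SNPs missing from one exposure's
summary statistics are 0-imputed with a flag (strict mode drops them), and
their standard error is set to infinity so they carry no weight in
instrument-strength calculations. `mvmrIVW()` fits the weighted
multi-exposure regression without intercept, with cross-exposure
association covariance fixed at zero, and the same floored multiplicative
residual scaling. An exposure whose effect column is identically zero is
dropped from the fit with an `NA` estimate, so a null second exposure
reproduces the univariable IVW exactly; genuinely collinear exposures are
an error.

`conditionalFStat()` regresses the target exposure's instrument effects on
the other exposures' effects *through the origin* (weights from the
target's precisions), and divides the weighted residual sum of squares by
$k - d$, $d$ = number of other exposures + 1. Through-origin conditioning
is what makes the two boundary cases come out right: uninformative other
exposures give approximately the mean univariable F, and a target fully
explained by the others gives F ≈ 0. Values below 10 flag conditional
weakness.

## Partitioning maternal and fetal effects

Mothers transmit half their genotype, so with maternal effect $\beta_m$
and fetal direct effect $\beta_f$ the two available GWAS have expectations
$E[\hat b_{\mathrm{own}}] = \beta_f + \beta_m/2$ (own birthweight on own
genotype) and $E[\hat b_{\mathrm{off}}] = \beta_m + \beta_f/2$ (offspring
birthweight on maternal genotype). Inverting this system gives the
weighted-linear-model (WLM) adjusted effects

$$\hat\beta_m = \tfrac{1}{3}(4\hat b_{\mathrm{off}} - 2\hat
b_{\mathrm{own}}), \qquad
  \hat\beta_f = \tfrac{1}{3}(4\hat b_{\mathrm{own}} - 2\hat
b_{\mathrm{off}}),$$

with standard errors propagated under a zero covariance between the two
GWAS. The constants are derived here from the transmission expectations
(and pinned by the pure-fetal test case $b_{\mathrm{own}} = 0.1,
b_{\mathrm{off}} = 0.05 \Rightarrow \hat\beta_m = 0$) rather than copied
from any published supplement. The zero-covariance assumption is exact for
the simulator's disjoint samples and a simplification for real GWAS with
overlapping participants, where it is mildly conservative for the
difference contrast. MR against the *unadjusted* maternal-genotype GWAS is
biased by $\beta_f/2$ per instrument; MR against the WLM-adjusted effects
is not — the simulator's `fetal-effect` scenario demonstrates exactly
this, which is the design rationale for using adjusted maternal effects as
the outcome sample.

## Instrument-relevance validation

Instruments come from a general-population GWAS; their relevance to
*pregnant* women is checked by re-estimating the SNP–exposure associations
in a pregnancy cohort and a women-only cohort. `preprocessBiomarker()`
reproduces the biomarker pipeline (natural log, winsorise at mean ± 5 SD,
Z-transform, residualise on age and 10 genetic principal components);
`snpAssoc()` regresses residuals on dosages; `crossSourceHeterogeneity()`
tests each association across sources with a fixed-effect Cochran Q
(consistent when p > 0.05, the criterion used for the published 67-of-89
count); `metaPerExposure()` first pools instruments within source.
Low-imputation-quality flags are consumed as input annotation, not
recomputed. `pairwiseEffectCorrelation()` correlates SNP-effect vectors
across exposures over pairwise-complete SNPs (at least 3 shared; a
documented choice over listwise deletion), reproducing the clustered
genetic architecture of, for example, the branched-chain amino acids.

## The synthetic-data generator

`simulateDuos()` draws maternal genotypes $G_m \sim \mathrm{Bin}(2, p)$
under Hardy–Weinberg, transmits one uniformly chosen maternal allele and
adds one $\mathrm{Bern}(p)$ paternal allele (random mating, no
assortment), giving the expected mother–child dosage correlation of 0.5.
The exposure is $X = G_m\gamma + \varepsilon_X$ and birthweight
$Y = \theta X + G_m\phi + G_c\delta + \varepsilon_Y$, then both are
standardised; $\phi$ is maternal horizontal pleiotropy and $\delta$ the
fetal direct effect. `gwasScan()` produces per-SNP summary statistics,
`makeLDTable()` the LD dialect for clumping, and
`simulateSumstatsDirect()` is the fast path that draws summary estimates
from their analytic sampling distributions
($\mathrm{se} = 1/\sqrt{2p(1-p)n}$ on the standardised scale) — exact
enough for replicate-heavy calibration and orders of magnitude cheaper.
All randomness flows from one integer seed; stages and replicates draw
sub-seeds through the generator's own scrambling (`deriveSeed()`,
`replicateSeeds()`), because arithmetic seed chains were measured to leave
Mersenne–Twister streams at fixed offsets detectably correlated.

**Scenario definitions** (`mrScenario()`), fixed once as the package's
study conditions:

- *causal*: $\theta = 0.12$ SD (≈ 58 g after conversion — the magnitude
  scale of the strongest published amino-acid effects), 15 unlinked
  instruments with frequencies 0.1–0.5 and effects 0.06–0.12 SD, exposure
  GWAS $n = 80{,}000$ and $100{,}000$ duos, mirroring the source GWAS
  scale; mean instrument F ≈ 280.
- *null*: $\theta = 0$, otherwise identical.
- *balanced-pleiotropy*: $\phi_j \sim N(0, 0.01)$ redrawn per replicate
  study (balanced pleiotropy is a statement about the pleiotropy
  *distribution*; conditioning on one fixed draw tests an arbitrary
  realisation instead), 100 equal-precision instruments (constant
  frequency 0.3, hence constant outcome SE). Equal precision makes the
  multiplicative heterogeneity model behind the Egger standard errors
  correctly specified, and $k = 100$ puts the normal-quantile convention
  in its accurate regime: the measured intercept rejection rate is 5.3%
  (10,000 replicates) against the $t_{k-2}$ theoretical 5.28%. Under
  heteroscedastic precisions the same test is conservative — a model
  limitation documented here rather than hidden in the scenario.
- *directional-pleiotropy*: 20 instruments, $\phi = +0.03$ on the subset
  carrying ≈ 30% of the analytic IVW weight
  ($w_j \propto \gamma_j^2\, 2p_j(1-p_j)$); chosen by weight, not count,
  because the robustness guarantee of the weighted median is stated in
  weight terms.
- *fetal-effect*: $\delta = 0.1$ on every SNP, $\phi = 0$ — the
  exclusion-restriction threat that the WLM partition removes.

**What the generator does not emulate** — and what passing tests therefore
do not establish about real data: realistic LD from reference panels
(LD enters only through explicit block construction or supplied tables),
assortative mating and parental-genotype correlation, sample overlap
between exposure and outcome GWAS, imputation uncertainty, non-normal
trait distributions, population stratification, and between-platform
measurement heterogeneity beyond what the z-score machinery models.

## Numerical conventions and degenerate inputs

Ties in clumping break by (p, position, SNP id); the weighted-median
interpolation clamps to the extreme ratios when 50% falls outside the
cumulative grid; Cook's distances are 0 for a perfect fit and infinite for
leverage-1 points; $I^2$ and $I^2_{GX}$ floor at 0 ($I^2_{GX} = 0$ when
$Q_{GX} = 0$); zero spread in exposure effects makes the Egger fit
collinear and is an error; monomorphic SNPs are dropped from GWAS scans
and LD tables with a reason; empty instrument sets are allowed everywhere
and skipped with a logged reason at the `runMR()` level.

The test suite runs the full calibration at reduced but adequate problem
sizes — 500 replicates for coverage, 1000 for intercept calibration, 200
for the directional contrast, 300 for the WLM bias comparison, with the
duo simulator at 4,000–60,000 families — sizes at which the Monte-Carlo
error is small against every asserted margin.

## Known limitations

- Normal-quantile inference makes small-$k$ Egger intercept tests mildly
  anti-conservative; no $t$ correction is applied by design.
- Weak-instrument bias is only diagnosed (F, $I^2_{GX}$, conditional F),
  not corrected.
- The WLM zero-covariance SE propagation ignores own/offspring sample
  overlap.
- LD-aware operations trust the supplied pairwise table; absent pairs are
  silently independent.
- The conservative-instrument workflow consumes externally curated SNP
  sets (gene/pathway annotation is configuration, not computation).
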