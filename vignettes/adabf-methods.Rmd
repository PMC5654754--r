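---
title: "Adaptive combination of Bayes factors: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive combination of Bayes factors: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adabf)
library(dplyr)
```

## The problem

Gene- or region-based association tests aggregate the evidence of many
variants, which helps when single-variant tests are underpowered — the usual
situation for rare variants — but hurts when the region is mostly neutral:
every neutral variant adds noise. Adaptive tests therefore truncate the
variant set, keeping only the most promising variants, and pay for the
selection by assessing the optimised statistic against a resampled null.

When the region mixes rare and common variants, the question is *how to rank
variants for truncation*. A p-value threshold treats a common variant with
p = 0.2 and a rare variant with p = 0.2 identically, yet they are not
equivalent: the common variant's p-value comes from a precise effect estimate
(it is probably genuinely null), while the rare variant's comes from a noisy
one (it may simply be underpowered). This package ranks variants by the
Wakefield approximate Bayes factor instead, which accounts for exactly this
asymmetry, and combines the top-`k` log Bayes factors with `k` chosen
adaptively.

## Per-variant summaries

Every design reduces to a per-variant effect estimate
$\hat\beta \sim N(\beta, \hat V)$:

* **Case-parent trios.** For each variant, `count_transmissions()` counts
  transmissions of the minor allele ($b$) and the major allele ($c$) from
  heterozygous parents to the affected child. `tdt_effect()` then sets
  $\hat\beta = \log(b/c)$, $\hat V = (b+c)/(bc)$, and the transmission
  disequilibrium chi-square $(b-c)^2/(b+c)$. The double-heterozygote family
  with a heterozygous child contributes one transmission to each count.
* **Unrelated subjects.** `regression_effect()` fits, per variant, a logistic
  (binary trait) or linear (quantitative trait) model of the outcome on the
  genotype score 0/1/2 plus any covariates, and reports the maximum-likelihood
  coefficient, its variance, and the 1-df Wald test.

Assumptions worth keeping in mind: variants are biallelic and autosomal;
genotype scores count minor-allele copies after deterministic orientation
(frequencies from founders in trio data, from all subjects otherwise, ties at
0.5 broken by allele name); and the normal approximation for $\hat\beta$ is
doing real work for very rare variants, where counts are small.

## The Wakefield Bayes factor

With a zero-mean normal prior $\beta \sim N(0, W)$ on the true effect, the
marginal-likelihood ratio of alternative to null has the closed form

$$BF = \sqrt{\frac{\hat V}{\hat V + W}}
  \exp\!\left(\frac{\hat\beta^2 W}{2 \hat V (\hat V + W)}\right),$$

which is exact under the normal model (`wakefield_bf()` is tested against
numerical quadrature of the defining integral). Two properties drive the
method:

* at fixed $\hat V$, the BF is increasing in the Wald statistic
  $\hat\beta^2/\hat V$ — strong signals win;
* at a fixed p-value, the BF vanishes as $\hat V \to 0$ **or**
  $\hat V \to \infty$ — a "significant" result built on a negligible effect,
  and a noisy estimate that could not have detected anything, are both
  discounted.

The default prior standard deviation is 0.2 ($W = 0.04$), the prior used in
large GWAS of binary traits (95% of true log odds ratios within ±0.4); the
`adabf1` preset uses 0.1 ($W = 0.01$) as a sensitivity check, and results are
typically stable across the two. For quantitative traits the same prior is
sensible only on a standardized scale, so `regression_effect()` warns when
the outcome's standard deviation strays more than 10% from 1 rather than
silently rescaling — the caller decides how to standardize. A per-variant
(e.g. frequency-dependent) prior variance would slot into the same formula,
but no such rule ships because none is established.

## Adaptive combination and the resampled null

For a region with $L$ usable variants, scores are $\log BF_l$ (or $-\log
p_l$ for the `ada` competitor, which shares all machinery). The summary score
$S_k$ is the sum of the $k$ largest scores, $k = 1, \dots, L$ (ties broken by
ascending variant index). Because $\log BF$ can be negative, $S_k$ is not
monotone in $k$ — the adaptive choice of $k$ is what removes the neutral
tail.

Significance is assessed by parametric resampling of the per-variant
estimates under the global null: $B$ draws from $N(\mathbf 0, V)$ with
$V_{ij} = R_{ij}\sqrt{\hat V_i \hat V_j}$, where $R$ is the genotype
correlation matrix (founders only, for trios), a standard approximation to
the correlation of the association statistics. Each draw is scored and
summarised exactly like the observed data. The per-$k$ p-value is the
fraction of resamples with $S_k^{(b)} \ge S_k$; the region statistic is
`MinP`, the minimum over $k$; and the adjusted p-value compares the observed
`MinP` with each resample's own `MinP`, computed by ranking every resample
against the full ensemble with itself included. Self-inclusion bounds per-
resample p-values below by $1/B$ and makes the adjusted p-value slightly
conservative rather than anti-conservative.

The resample count escalates sequentially: start at $B = 100$; while the
adjusted p-value is at most $10/B$, draw a fresh ensemble ten times larger,
up to $B = 10^7$. Null regions stop immediately; only promising regions pay
for precision. A fresh (rather than extended) ensemble per stage keeps every
stage an unbiased estimate at its own $B$; stage seeds derive
deterministically from the master seed, so results are exactly reproducible.
Memory is about $8BL$ bytes at the final stage, which is what practically
bounds $B$ for very long regions.

Numerical corner cases, all deterministic:

* zero observed exceedances report $1/B$ with a `floor` flag, never 0;
* a zero transmission cell gets the Haldane–Anscombe 0.5 correction (flagged
  `corrected`; configurable to drop instead), keeping rare variants — the
  method's focus — in the analysis with finite $\hat\beta, \hat V$;
* separated logistic fits (common for rare variants) fall back to a Firth
  penalized fit, flagged, so Wald summaries stay finite;
* pairwise-complete correlation matrices are repaired to positive
  semidefiniteness by clipping eigenvalues at $10^{-10}$ and rescaling to
  unit diagonal;
* Mendelian-inconsistent trios are skipped at the offending variant only
  (and counted), preserving the rest of the trio's information.

The burden baseline (`burden_test_trio()`, `burden_test_unrelated()`) is the
plain unweighted linear combination: pooled transmission deviations
$Z = \sum_l (b_l - c_l) / \sqrt{\sum_l (b_l + c_l)}$ for trios, a regression
on the per-subject genotype sum for unrelated subjects. No frequency weights
are applied anywhere, keeping the comparison between methods fair. Its known
weakness — cancellation under mixed effect directions — is the scenario where
the adaptive test shines, and kernel-type alternatives are deliberately out
of scope.

## What the simulator emulates (and what it does not)

`make_pool()` builds a synthetic pool of $H = 10{,}000$ haplotypes over
$L = 150$ sites standing in for a ~20 kb resequenced region. Target site
frequencies follow a density $\propto 1/f$ on $[1/H, 0.5]$ — the L-shaped
spectrum of sequence data, matching the $1/i$ neutral site-frequency
spectrum — and haplotypes come from a latent Gaussian AR(1) process
(parameter `ld`, default 0.5) thresholded per site, giving local allele-
sharing. Monomorphic columns are redrawn so every site segregates.

Disease status follows a logistic model with intercept
$\alpha = \log(0.05/0.95) = -2.94$ (5% prevalence, and
$\mathrm{logit}^{-1}(-2.94) = 0.0503$ exactly) plus per-causal-variant log
odds ratios of magnitude $\log 1.5$ or $\log 1.25$, all-deleterious or half
protective. Trios draw four parental haplotypes, transmit one per parent at
random, and keep families with an affected child (rejection on haplotype
indices, so the 5% acceptance rate costs little); case-control sampling
fills quotas of cases and controls the same way. Random mating makes
founders Hardy–Weinberg by construction, and null transmissions are unbiased
— both are tested.

What the generator does **not** reproduce: coalescent linkage
disequilibrium. The latent AR(1) correlation is attenuated on the binary
scale — strongly so between rare sites, where binary margins bound the
attainable correlation — so realized LD is weaker and shorter-ranged than in
real sequence data, and there are no recombination hotspots or demographic
structure. Consequently, passing calibration and power tests here supports
the method's validity and its ordering against the burden baseline, but
printed power curves or ranking means from coalescent-based experiments are
not reproduced numerically: quantities that depend on the exact LD fabric
are checked as *properties* (calibration within binomial error, orderings,
stratified advantages), not as numbers.

## Study sizes used by the shipped experiments

Chosen once as realistic desk-scale versions of the full designs, and stated
here because they are the package's defaults:

* calibration: 2,000 null replicates per design at the full study sizes —
  2,000 trios or 1,000 + 1,000 unrelated subjects — over 150-variant regions
  from 20 pools; the 5%-level rejection rate is required to sit inside the
  99% binomial interval around 0.05. Sample size matters here: at a quarter
  of these sizes the test turns visibly conservative (rejection near 0.03),
  because the discrete, bounded statistics of variants with a handful of
  minor-allele copies cannot match the Gaussian tails the null ensemble
  assumes; the effect shrinks as counts grow, and a residual conservative
  tilt remains in the unrelated design even at full size;
* ranking: 5,000 replicates of the one-causal-variant experiment
  (OR 1.5, 1,000 cases + 1,000 controls), stratified by the causal pool
  frequency at 0.1%, 1% and 5%. Replicates whose causal variant is
  monomorphic in the drawn sample are redrawn, since neither ordering is
  defined for an untestable variant;
* power: 250 replicates, 400 trios, four causal variants of |OR| = 1.5 with
  half protective — the cancellation scenario — comparing the adaptive test
  with the burden baseline on identical data at $\alpha$ = 0.01, with the
  resampling cap at $10^4$ (ample to resolve rejection at 0.01).

In the ranking experiment the Bayes-factor ordering is dramatically better
in the rare strata (mean causal rank roughly halved below 0.1% MAF) and at
parity above 5%. In the 1–5% stratum, under these exact conditions, the
orderings are close and the small margin can favour either side: a region
carries a few dozen near-zero-information ultra-rare variants whose Bayes
factors sit just below 1, and in replicates where the mid-frequency causal
variant draws a weak statistic (log BF < 0) those variants separate the two
orderings. The margin's sign in that stratum is therefore
condition-dependent (LD fabric, sample size), while the rare-stratum
advantage — the method's point — is large and stable.

## Known limitations

* The multivariate-normal null for $\hat\beta_0$ leans on asymptotics that
  are thin for variants with a handful of informative transmissions; the
  continuity and Firth corrections keep such variants usable, and the
  calibration experiments check the net effect, but extremely sparse regions
  in small samples deserve caution.
* Covariates are supported only for unrelated designs; the
  transmission-based trio test conditions on parental genotypes and has no
  natural covariate slot.
* X-chromosome variants, general pedigrees, dosage data and kernel-type
  tests are out of scope.
* Regions with thousands of variants at $B = 10^7$ exceed desktop memory
  (about $8BL$ bytes); the escalation cap is configurable per region.
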