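---
title: "Differential abundance with group-wise structured zeros: models and design"
author: "zidaseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential abundance with group-wise structured zeros}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Microbiome count tables are sparse (often 50--95% zeros), overdispersed,
compositional, and shallow in replication. Two distinct failure modes of
count-model differential abundance testing follow from the zeros:

1. **Group-wise structured zeros.** A taxon observed only in one of the
   two comparison groups perfectly separates the group indicator. The
   unpenalized negative binomial (NB) maximum likelihood estimate of the
   group coefficient is infinite, its Wald standard error explodes, and
   the taxon — often the biologically most interesting one — is reported
   as non-significant.
2. **Zero inflation.** Zeros in excess of what an NB predicts inflate
   the estimated dispersion, destroying power for every taxon.

`zidaseq` addresses the two failure modes with two different devices and
combines them in one pipeline: structured-zero taxa are tested with a
**ridge-stabilized NB likelihood-ratio test** (the penalty keeps the
separated coefficient finite; the LRT, unlike the Wald test, remains
informative), and the remaining taxa are tested with the same engine
after **down-weighting excess zeros** with per-taxon zero-inflated NB
(ZINB) observation weights.

# Models

## The testing engine

For taxon $j$ with counts $y_{ij}$ in samples $i$, size factors $s_i$
and design row $x_i$:

$$y_{ij} \sim \mathrm{NB}(\mu_{ij}, \phi_j), \qquad
\log \mu_{ij} = x_i^\top \beta_j + \log s_i ,$$

with variance $\mu + \phi\mu^2$. Estimation maximizes the weighted,
ridge-penalized log-likelihood
$\sum_i w_{ij}\,\ell(y_{ij};\mu_{ij},\phi_j) -
\tfrac{\lambda}{2}\lVert\beta_{j,-0}\rVert^2$
by Fisher-scoring IRLS with step-halving (the intercept is never
penalized). The default $\lambda = 10^{-6}$ is a numerical stabilizer:
it leaves well-identified fits unchanged to ~8 decimal places but caps
the separated coefficients at finite values. Dispersions are estimated
per taxon by maximizing the Cox–Reid adjusted profile likelihood
($\beta$ profiled out at each candidate $\phi$, bounded to
$[10^{-8}, 10]$), under the full model, and held fixed for both LRT
fits. The test statistic is $2(\ell_{\text{full}} -
\ell_{\text{reduced}})$ (clipped at 0) against $\chi^2$ with
df = rank difference; weights do not reduce the df, matching the
convention of weighted NB analyses. Benjamini–Hochberg adjustment is
applied per analysis part by default (the two parts are separate
analyses that are merged afterwards; a joint scope is available).

## Observation weights

The ZINB mixture for a taxon is
$P(y=0) = \pi + (1-\pi) f_{\mathrm{NB}}(0;\mu,\phi)$ with
$f_{\mathrm{NB}}(0;\mu,\phi) = (1+\phi\mu)^{-1/\phi}$, positives from
the NB. The weight of an observed zero is the posterior probability
that it came from the count component; positive counts get weight 1.
Weights are floored at $10^{-6}$ so IRLS never sees an exact zero
weight.

The EM fit is per taxon: the E-step computes posterior structural-zero
probabilities; the M-step runs a weighted ridge NB regression with the
dispersion re-profiled, and a ridge logistic regression of the
posterior memberships. Taxa without zeros short-circuit ($\pi$ at its
lower boundary, all weights 1).

**Weight-model regularization (a deliberate design choice).** The
package's default weight generator (`zinbWeights(model = "pooled")`)
fits the weight model in a strongly regularized configuration: pass 1
estimates per-taxon dispersions from intercept-only ZINB fits and pools
them into one common dispersion (geometric median); pass 2 re-runs each
taxon's EM conditional on that dispersion with intercept-only mean and
zero models, leaving two free parameters per taxon. This is the
strong-shrinkage limit of joint zero-inflation weight generators, whose
default penalties crush non-intercept coefficients and dispersion
heterogeneity. The reason is empirical and reproducible with the
package's own benchmark: when the weight model is given per-taxon
maximum-likelihood freedom (4--6 parameters per taxon on 10--50
samples), the estimated weights adapt to noise in the very observations
being tested, and the weighted LRT's null rejection rate roughly
doubles; with generative-truth weights the same engine is nearly
nominal. Pooling removes most, not all, of the gap; the residual
small-sample inflation of the weighted path is a known property of
weighted $\chi^2$ tests at small effective sample sizes and decays with
$n$. The full per-taxon variant remains available
(`model = "per_taxon"`) for sensitivity analyses. The test fits always
keep the full design and per-taxon Cox–Reid dispersions.

## The combined two-path pipeline

`runCombined()` in `two_group` mode: validate/align, filter (keep a
taxon iff some group has $\ge$ `minSamples` samples with count $\ge$
`minCount`; defaults 2 and 2, evaluated within at least one group),
classify structured zeros on observed counts, compute size factors once
on the whole filtered table (both parts share one scale), then part A
(structured taxa, unweighted ridge NB LRT) and part B (the rest, ZINB
weighted), BH within part, merge. In `multi_covariate` mode (factors
with more than two levels, where "structured" is contrast-specific) the
classification step is skipped for testing: all filtered taxa are
analyzed both unweighted and weighted, each analysis is BH-adjusted
separately, and the union of significant taxa is the result;
`significantTaxa()` implements the union rule. The full/reduced designs
are treatment-coded against a reference level, e.g. full
$\{1, \mathrm{N}, \mathrm{P}\}$ vs reduced $\{1, \mathrm{P}\}$ to test
N against the control.

Structured-zero taxa can optionally be declared significant without
testing (`declareStructuredSignificant`), for settings where the
structured zeros are believed biological; the default is to test them.

## Normalization

Three size-factor schemes, all rescaled to geometric mean 1 so they act
as centred offsets (only ratios matter to the GLM; an intercept absorbs
the rescaling — the tests verify the LRT is invariant to it):

* **poscounts** — median-of-ratios with a pseudo-reference built from
  positive counts only, divisor $n$ (zeros add nothing to the geometric
  sum but count in the divisor). Medians of even sets are the
  arithmetic mean of the central ratios.
* **TMM** — trimmed mean of M-values with the conventional defaults
  (30% M-trim, 5% A-trim, upper-quartile reference rule,
  inverse-delta-variance weighting), matching the canonical
  implementation to $10^{-10}$.
* **GMPR** — geometric mean of pairwise median count ratios, designed
  for sparse tables. Note an algebraic property asserted by the tests:
  on columns that are exact scalar multiples $d_i$ of each other, GMPR
  yields $s_i \propto d_i^{\,n/(n-1)}$ (for two samples, the squared
  ratio) — exact depth recovery only as $n$ grows. The geometric mean
  is taken over the pairs with shared support rather than failing when
  some pairs share none.

# The synthetic-data generator

`simulateDataset()` draws, per sample: presence indicators
$\mathrm{Bernoulli}(p_j)$; for present taxa a log abundance
$\mathcal{N}(m_j + \delta_j \cdot 1[\text{treated}], \sigma_j)$
truncated at $\pm 4\sigma$ around its mean; exponentiation and
renormalization to proportions; a library size
$\mathrm{round}\{\exp(\mathcal{N}(\log D, \sigma_D))\}$; and a multinomial count
vector (compositional coupling, not independent per-taxon draws).
Spike-ins add $\delta$ to the log abundance of treated samples only
(abundance effect; prevalence untouched), with half the spiked taxa up
and half down. Spike eligibility is the top prevalence decile, and
about 10% of taxa are spiked by default.

The two presets encode contrasting study conditions by their summary
statistics: `forest_like` (303 taxa, median depth 1883, ~84–86% zeros —
shallow and highly sparse, very low counts) and `np_like` (928 taxa,
median depth 215,356, ~54–55% zeros — deep, moderately sparse). The
parameter choices behind them, each made for realism and fixed:

* **Prevalence** follows U-shaped Beta distributions
  (np Beta(0.66, 0.54), forest Beta(0.30, 0.70)) — the core-plus-rare
  bimodality of real 16S prevalence profiles; the means were set once
  so the simulated overall zero fractions match the targets.
* **Log-abundance means** are normal with large spread (sd 3.0 / 2.5
  natural-log units) and location pinned by the compositional
  constraint $J \bar{p}\, E[e^m] \approx 1$; this yields a
  few-dominant-taxa, many-low-count profile, with median expected
  counts per present taxon of a few (forest) to tens (np).
* **Within-taxon log sds** are uniform on $[0.3, 1.0]$, i.e. NB
  dispersions $e^{\sigma^2}-1 \approx 0.1$–$1.7$, the range real BCV
  plots span. Larger sds would imply BCVs near 3 and make even a
  correctly specified NB test asymptotically anti-conservative against
  the lognormal tail.

What the generator does **not** emulate: taxon–taxon correlations
beyond the compositional constraint, phylogenetic structure,
batch/covariate effects on prevalence, and prevalence effects of
treatments (spikes act on abundance only). Passing tests therefore
demonstrate calibration and power under compositional zero-inflated
sampling, not robustness to, e.g., correlated blooms.

Two observation-side facts about the generator matter when reading
recovery checks. First, spiking mass up in treated samples shifts *all*
treated proportions down (compositional closure), so the injected
$\delta$ is recovered as a spiked-vs-unspiked difference, not an
absolute one. Second, conditioning on $y > 0$ censors the lower tail
wherever detection is uncertain, biasing nonzero means; recovery is
therefore measured on the deep template over taxa detected in >90% of
samples, where both corrections together return the injected effect to
within Monte Carlo error.

# The benchmark harness

`runBenchmark()` reproduces the evaluation protocol: per replicate,
simulate, filter, classify and **exclude** structured-zero taxa (the
protocol that puts weighted and unweighted methods on comparable
footing; a flag includes them), normalize, test, BH-adjust, and score.
Power = TP/(TP+FN); FDR = FP/(TP+FP) with the 0/0 case defined as 0 so
replicates without discoveries can be averaged; the observed type I
error is the fraction of raw null p-values below $\alpha$. Replicate
seeds are `baseSeed + replicate`, shared across grid cells so
comparisons are paired.

For the null-calibration check, "within 3 binomial standard errors of
$\alpha$" uses $\mathrm{SE} = \sqrt{\alpha(1-\alpha)/\bar m}$ with
$\bar m$ the average number of tested taxa per replicate — not divided
by the number of replicates, because p-values within a compositional
replicate are positively dependent and the replicate-mean SE would be
anti-conservative.

Problem sizes used by the shipped tests and the acceptance script —
chosen as a reduced grid that keeps the Monte Carlo error well below
the effects being measured: 12--20 null replicates of the np-like
template at 25 samples per group for calibration; 6 replicates per cell
of the forest-like template at 5 and 25 per group and effects
$\{0.5, 1, 2\}$ for the power surface; $n = 500$ for parameter
recovery.

# Numerical choices

* IRLS: step-halving on the penalized objective; linear predictor
  clipped at $\pm 50$; convergence at relative objective change
  $<10^{-10}$ (fits) within 100 iterations.
* EM: observed-data log-likelihood tolerance $10^{-6}$, max 100
  iterations; the dispersion is profiled over the full range on the
  first iteration and locally thereafter; non-convergence is flagged
  per taxon and the last iterate returned.
* Dispersion bounds $[10^{-8}, 10]$, with an exact snap to the bound
  when the profile optimum hugs it (degenerate taxa report exactly
  $10^{-8}$). An optional empirical-Bayes trend-shrinkage step exists
  and is off by default: on the package's own null benchmark it
  degrades calibration, because dispersion heterogeneity across taxa is
  real rather than sampling noise.
* Ties and even medians follow the standard "mean of the two central
  values" convention, which is why the poscounts cross-check against
  the log-scale-median reference implementation needs a ratio-scale
  location function.
* All-zero taxa are rejected by the fitters (the filter removes them
  upstream); a simulated sample drawing no present taxon is redrawn
  once and then left all-zero with a warning.

# Known limitations

* The weighted path's type I error at small $n$ sits a little above
  nominal even with pooled weights (and with oracle weights); the
  package reports it honestly rather than masking it. At
  moderate-to-large $n$, or for the unweighted path at any tested $n$,
  calibration is nominal.
* Per-taxon EM (no joint factorization across taxa beyond the pooled
  dispersion) trades the efficiency of a joint low-rank model for
  simplicity and transparency.
* Classification of structured zeros uses observed zeros only; at
  small $n$, sampling zeros can masquerade as structured. The pipeline
  treats the classification as a routing device, not a biological
  claim.
* The multi-covariate path reports the union of two analyses; it does
  not adjust across the two paths (each is BH-adjusted separately, as
  in the two-part design).
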