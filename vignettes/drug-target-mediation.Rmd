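---
title: "Drug-target MR with two-step mediation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target MR with two-step mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetmr)
```

## The question the pipeline answers

Lipid-lowering drugs act on well-characterised protein targets (APOB,
HMGCR, PCSK9, APOC3, LPL, ...). Genetic variants in or near the gene
encoding a target shift lifelong exposure to the target's activity and can
therefore proxy pharmacological modulation: this is drug-target Mendelian
randomization (MR). `targetmr` implements a complete drug-target MR study
with a mediation layer: does inhibiting a lipid target change disease risk,
and how much of that change flows through an intermediate trait (here, a
sphingolipid metabolite such as neutral ceramidase)?

The design is two-step MR. Step 1 estimates the target's effect on the
outcome ($\beta_3$) and on the mediator ($\beta_1$) using the target's cis
instruments. Step 2 estimates the mediator's effect on the outcome
($\beta_2$) using the mediator's own instruments. The indirect effect is
$\beta_1\beta_2$, the total effect $\beta_3 + \beta_1\beta_2$, and the
proportion mediated

$$ E\% = \frac{\beta_1\beta_2}{\beta_3 + \beta_1\beta_2}. $$

A terminological caveat the package documents rather than resolves: the
formula treats $\beta_3$ as a *direct* effect, yet $\beta_3$ is taken from
ordinary (unadjusted) step-1 MR, whose estimand is conventionally the
*total* effect; the published odds ratios equal $\exp(\beta_3)$. The
package implements exactly the formula above and exposes all three betas,
so users can see what was combined. The synthetic-data module makes the
issue concrete: with no pleiotropy, IVW on the target's instruments
recovers the generative *total* effect $\;\text{direct} +
\beta_1\beta_2$, and this is asserted in the test suite.

## Instrument construction

For a target gene, instruments are drawn from the exposure GWAS within a
cis window (default ±100 kb around the gene body, 1-based inclusive
coordinates), kept at genome-wide significance ($p < 5\times10^{-8}$,
strict), thinned by greedy LD clumping, and strength-filtered.

* **Clumping** (`clump()`): variants are ordered by p-value (ties broken by
  variant id so the result is order-independent), the best remaining
  variant is retained, and every remaining variant with $r^2$ at or above
  the threshold *and* within the clumping window (default 10,000 kb) of it
  is discarded. Drug-target sets use a permissive $r^2 < 0.30$ — cis
  regions rarely contain many independent signals, and correlated
  instruments are accepted in exchange for strength. Mediator
  (metabolite/protein) instruments use the stringent conventional
  $r^2 < 0.001$.
* **Strength** (`f_statistic()`): the per-variant approximation
  $F = (\hat\beta/\widehat{se})^2$, with variants kept only when $F > 10$.
  The cutoff is applied per variant (the conservative reading; a set-level
  mean is also reported by `print.instrument_set`). The filter runs after
  clumping, matching the usual prune-then-check practice; running it
  before would only change results when a weak variant shields a strong
  one inside the same clump.

## Harmonization

Outcome effects are aligned to the exposure's effect allele
(`harmonize_pair()`): matching alleles are kept, swapped alleles negate
the outcome beta and reflect its allele frequency, and strand complements
(A↔T, C↔G) are resolved before a pair is declared irreconcilable.
Palindromic variants (A/T, C/G) carry no strand information in their
labels, so they are kept only when both allele frequencies fall on the
same side of 0.5 and both minor-allele frequencies are below 0.42 — the
conventional inference limit; frequencies nearer 0.5 (or missing) make the
strand undecidable and the variant is dropped. Dropped pairs carry `NA`
betas so they cannot leak into an estimator.

## Estimators

All estimators work on the per-variant Wald ratios
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with first-order
delta-method standard errors $se_{Yj}/|\hat\beta_{Xj}|$ and
inverse-variance weights $w_j = \hat\beta_{Xj}^2/se_{Yj}^2$ (exposure-side
noise is ignored in the weights, the standard first-order convention).

* **Wald ratio**: single-instrument estimate; used automatically whenever
  only one instrument survives.
* **IVW** (`mr_ivw()`): weighted regression through the origin,
  $\hat\beta = \sum w_j \hat\theta_j / \sum w_j$. Multiplicative
  random-effects standard error: the fixed-effect se is scaled by
  $\max(1, \sqrt{Q/(n-1)})$, so heterogeneity widens but never narrows the
  CI; p-values are two-sided normal.
* **MR-Egger** (`mr_egger()`): weighted regression *with* an intercept
  after orienting all exposure betas non-negative. The intercept estimates
  average directional pleiotropy. Standard errors are scaled by
  $\max(1, \hat\sigma)$ (weighted residual sd on $n-2$ df) and p-values use
  the t distribution on $n-2$ df — with very few instruments the heavy t
  tail correctly limits how small an Egger p-value can get.
* **Weighted median** (`mr_weighted_median()`): the interpolated weighted
  median of the ratios (cumulative weight midpoints
  $s_j = \sum_{i\le j} w'_i - w'_j/2$, linear interpolation to
  $s = 0.5$), consistent when ≥ 50% of weight is valid.
* **Modes** (`mr_mode()`): argmax of a Gaussian-kernel density over the
  ratios, with equal weights (simple mode) or $w_j$ (weighted mode).
  Bandwidth is the modified Silverman rule
  $h = \phi\, 0.9\,\min(sd, IQR/1.349)\,n^{-1/5}$ with $\phi = 1$; the
  density is evaluated on a fixed 512-point grid spanning
  $[\min - 3h, \max + 3h]$, so the estimate is deterministic. When all
  ratios coincide the common ratio is returned directly.

Median and mode standard errors come from a parametric bootstrap (default
1000 resamples): both betas are redrawn from
$N(\hat\beta, \widehat{se}^2)$ and the estimator recomputed, weights
included. The bootstrap needs exposure standard errors; the simulator
always provides them. The bootstrap seed is mandatory (package default
20231116), is consumed in a local RNG scope, and never disturbs the
caller's random stream — two pipeline runs with the same config are
byte-identical.

## Diagnostics, reliability, gating and FDR

`cochran_q()` computes $Q = \sum_j w_j(\hat\theta_j - \hat\beta_{IVW})^2$
(chi-squared, $n-1$ df, under homogeneity); `egger_intercept_test()` tests
the Egger intercept against zero. Both are flagged at $p < 0.05$
(configurable).

An estimate is **reliable** when the primary method (IVW, or Wald ratio
for singleton sets) is significant at 0.05 *and* agrees in sign with the
MR-Egger estimate; singleton sets cannot be direction-checked and are
flagged accordingly. The **positive-control gate** removes any target
whose instruments fail to show a reliable, FDR-significant effect on an
outcome where the causal relationship is established (coronary heart
disease for lipid targets): a target that cannot reproduce a known effect
is not trusted on the novel one. The gate uses FDR-adjusted p-values, for
consistency with the study-wide 0.05-after-FDR significance convention.

FDR is Benjamini–Hochberg, adjusted within each analysis stage and
outcome across targets (the family key is configurable and recorded in
the run manifest; the family was a genuinely open choice, and
per-stage-and-outcome is the narrowest family that still corrects the
across-target multiplicity actually incurred). Mediation is computed only
when $\beta_1, \beta_2, \beta_3$ are all significant; by default this
gate uses raw p-values (the weaker reading of "statistical significance"),
switchable to FDR-adjusted.

## The synthetic-data generator

`simulate_region()` generates summary statistics analytically rather than
from individual-level genotypes: MAFs are uniform; SNP correlations follow
AR(1), $r_{ij} = \rho^{|i-j|}$ (a single parameter that still exercises
clumping nontrivially); a random subset of SNPs gets standardized causal
effects $\gamma \sim N(0, \gamma_{sd}^2)$; marginal effects are the
LD convolution $R\gamma$; and observed betas add noise with the analytic
GWAS standard error $1/\sqrt{2\,maf(1-maf)\,n}$ (quantitative) or
$1/\sqrt{2\,maf(1-maf)\,n\,cf(1-cf)}$ (binary, case fraction $cf$). The
mediator's SNP effects are $\beta_1 R\gamma$, the outcome's
$(\text{direct} + \beta_1\beta_2) R\gamma$ plus optional per-SNP
pleiotropy.

`simulate_study()` assembles a full study: the target's cis region drives
the exposure (and, downstream, the mediator, the positive-control outcome
and the disease outcome), and a *second* region gives the mediator its own
instruments, whose only path to the outcome is $\beta_2$. The second
region is essential: step-2 MR through the target's own SNPs would
estimate $(\text{direct}+\beta_1\beta_2)/\beta_1$, not $\beta_2$.

Default study conditions: 100 SNPs, $\rho = 0.8$, 20 causal SNPs with
$\gamma_{sd} = 0.05$ (lipid-scale cis effects), exposure and outcome
GWAS n = 200,000 (30% cases), positive-control GWAS n = 87,000,
$\beta_1 = 0.24$, $\beta_2 = -0.08$, direct effect $-0.20$ — generative
mediated proportion $\approx 8.8\%$. The mediator GWAS uses n = 20,000
with large mediator-region effects ($\gamma_{sd} = 0.4$): metabolite and
protein GWASs are one to two orders of magnitude smaller than lipid
GWASs, and their usable instruments are few, strong cis signals — the
simulated mediator ends up with 2–4 instruments after $r^2 < 0.001$
clumping, mirroring the data situation the design targets.

What the generator does *not* emulate: realistic human LD panels,
winner's-curse from discovery selection, sample overlap between GWASs, or
multi-allelic sites. Passing tests therefore demonstrate correctness of
the statistical machinery under the stated generative model, not
robustness to every artefact of real consortium data.

## Validation problem sizes

The test suite validates estimator implementations against independent
brute-force oracles (weighted least squares via `lm`, a literal step-up
FDR, an interpolation oracle for the weighted median, an exhaustive greedy
oracle for clumping) on ~1,000 random instances each; calibration uses 500
replicates of a 30-instrument, n = 100,000 design for IVW coverage and
diagnostic type-I error, and 200 full pipeline replicates for recovery of
the generative mediated proportion. These sizes give Monte-Carlo standard
errors comfortably inside the asserted bands while keeping the whole suite
around a minute.

## Degenerate inputs and numerical conventions

* Exposure beta exactly 0 → degenerate-instrument error (no ratio).
* Fewer instruments than a method's minimum (2 for IVW, 3 for
  Egger/median/modes) → explicit error; `mr_all_methods()` degrades to the
  Wald ratio for singletons and skips 3+-instrument methods at $k = 2$.
* All ratios identical → mode/median return the common ratio; $Q = 0$,
  $p = 1$.
* Identical exposure betas after Egger orientation → collinearity error.
* Mediation with $|\beta_3 + \beta_1\beta_2| < 10^{-12}$ →
  undefined-proportion error.
* OR confidence intervals use the normal 97.5th percentile 1.959964.
* Rounding (ORs to 2 decimals, proportions to 1 decimal) happens only in
  the rendering layer; all upstream tables keep full precision, and the
  results writer serializes floats at 6 significant digits.

## Known limitations

Instrument correlation within the permissive $r^2 < 0.30$ sets is ignored
by the estimators (as in the standard first-order toolchain), which
understates standard errors when several retained variants are correlated.
No Steiger filtering, multivariable MR, or MR-PRESSO-style outlier removal
is provided. The mediation proportion is reported without a standard
error by default, matching the convention of reporting the point
proportion; the delta-method variance would additionally require the
covariance of $\beta_1$ and $\beta_3$, which share instruments.

## A minimal run

```{r example, eval = TRUE}
st <- simulate_study(seed = 42)
cfg <- study_config(st$targets, methods = c("ivw", "mr_egger"), seed = 42)
res <- run_two_step(cfg, st$datasets, st$ld)
res$primary_results[, c("stage", "exposure", "outcome", "beta", "pvalue",
                        "fdr_pvalue", "reliable")]
res$mediation
st$truth$proportion_true
```
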