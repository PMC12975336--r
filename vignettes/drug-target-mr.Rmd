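---
title: "Drug-target Mendelian randomization: models, estimators and the synthetic test bed"
author: "statinmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomization: models, estimators and the synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statinmr)
```

## The scientific problem

Statins lower LDL cholesterol by inhibiting HMG-CoA reductase (HMGCR),
and randomized trials and observational cohorts both suggest they
modestly raise type 2 diabetes (T2D) risk. Drug-target Mendelian
randomization probes this mechanistically: common variants within
±1000 kb of the *HMGCR* transcription start site that lower LDL-C act
as lifelong, confounding-free proxies of pharmacological HMGCR
inhibition. Comparing their LDL-C effects (from a lipid GWAS) with
their T2D effects (from an independent disease GWAS) yields a causal
effect per standard deviation of LDL-C lowering; the same machinery
applied to gut microbial, metabolite and protein GWAS identifies
molecular signatures of statin exposure, and mediation, colocalization
and summary-data MR distinguish which of those signatures plausibly
carry the diabetogenic effect.

`statinmr` implements this entire analysis graph as reusable,
seed-deterministic components, together with a synthetic two-sample
GWAS generator with known ground truth against which every estimator is
calibrated. The numbered scripts under `analysis/` narrate one complete
run; the package functions in `R/` do all computation.

## Data model and harmonization

Summary statistics are per-variant marginal associations (`beta`, `se`,
`p`, `N`, alleles, effect-allele frequency), read and written in the
COJO `.ma` dialect or a column-mapped TSV. Variant identity is
chromosome:position plus the unordered allele pair; rsids are carried
but advisory, since positional matching is what the source files
support. Harmonization aligns the outcome's effect allele to the
exposure's, flipping signs and complementing frequencies for swapped or
strand-flipped codings. Palindromic variants (A/T, C/G) carry no strand
information, so by default their orientation is inferred from allele
frequency, and any variant with minor-allele frequency above 0.42 on
either side (or a missing frequency) is dropped as ambiguous — the
conventional two-sample MR practice. Multi-allelic positions are
dropped and logged; load reports conserve row counts exactly.

## Estimators

All correlated-instrument estimators weight by
$\Omega = D\rho D$, with $D = \mathrm{diag}(\sigma_Y)$ the outcome
standard errors and $\rho$ the reference-panel LD correlation —
outcome-side uncertainty only (the NOME assumption; exposure-side noise
is ignored in the weights, a documented first-order limitation).

* **IVW (correlated):**
  $\hat\theta = (\beta_X^\top \Omega^{-1} \beta_Y) /
  (\beta_X^\top \Omega^{-1} \beta_X)$, fixed-effect SE
  $(\beta_X^\top\Omega^{-1}\beta_X)^{-1/2}$. The multiplicative
  random-effects model inflates the SE by
  $\max(1, \sqrt{Q/(n-1)})$; by default the fixed model is used for
  up to three instruments and the multiplicative model beyond that,
  with both selectable.
* **MR-Egger:** GLS of $\beta_Y$ on $(1, \beta_X)$ after orienting
  every variant to $\beta_X \ge 0$ (outcome betas and LD signs
  co-flipped); the intercept tests directional pleiotropy.
* **Generalized Cochran's Q:**
  $(\beta_Y-\theta\beta_X)^\top\Omega^{-1}(\beta_Y-\theta\beta_X)$
  against $\chi^2_{n-1}$.
* **Multivariable MR:** the joint GLS solve over several exposure
  columns, used to estimate a mediator's outcome effect adjusted for
  the drug-target region. Effect columns stay on the per-allele scale,
  which is row-consistent with the outcome side.
* **Mediation:** product of coefficients
  $\alpha\beta$ with SE
  $\sqrt{\alpha^2\sigma_\beta^2+\beta^2\sigma_\alpha^2-\sigma_\alpha^2\sigma_\beta^2}$.
  This unbiased-variance form can go negative near
  $\alpha=\beta=0$; the package then falls back to the first-order
  delta SE $\sqrt{\alpha^2\sigma_\beta^2+\beta^2\sigma_\alpha^2}$ and
  sets a provenance flag. The proportion mediated divides the indirect
  effect by the **total** univariable drug-target effect (not
  direct + indirect), matching the convention in which the proportion
  is quoted against the effect a clinician would observe.
* **Colocalization:** Wakefield log-ABFs per SNP,
  $\tfrac12\log\frac{V}{V+W}+\tfrac12\frac{W}{V+W}Z^2$, with effect
  priors $W^{1/2}=0.15$ for quantitative and $0.2$ for binary traits
  (the cited method's conventional defaults; the priors
  $p_1=p_2=10^{-4}$, $p_{12}=10^{-5}$ are stated directly). Hypothesis
  sums use log-sum-exp stabilization, the two-distinct-variants sum
  being the full product minus the shared-SNP diagonal. The decision
  rule is strict: PP4 > 0.7.
* **SMR/HEIDI:** $T_{SMR}=z_X^2 z_Y^2/(z_X^2+z_Y^2)$ on 1 df; the
  multi-SNP variant sums $T_{SMR}$ over near-independent top QTLs with
  a weighted-$\chi^2$ null (eigenvalues of the selected variants' LD),
  and HEIDI tests deviations of per-variant Wald ratios from the top
  QTL's ratio with delta-method variances and LD-derived covariances.
  All weighted-$\chi^2$ tails use two-moment (Satterthwaite) matching;
  an exact Davies-style tail is out of scope. HEIDI eligibility
  (QTL $p<1.57\times10^{-3}$, $r^2$ with the top QTL in $[0.05,0.9]$,
  the 20 strongest kept) follows the reference software's conventions —
  these are package defaults, not values fixed by any publication.
* **GSMR-style reverse MR:** iterative heterogeneity-outlier removal
  (worst deviation from the fixed-effect pooled estimate at
  $p<0.01$ per iteration, variance floored at half the Wald-ratio
  variance so a contaminated interim fit cannot flag everything),
  then correlated IVW on the survivors.
* **Power:** two-sided normal approximation with
  $NCP = n\,r^2 K(1-K)\,\theta^2$; the minimum detectable effect
  inverts this by bisection to $10^{-6}$. A logistic-regression
  simulation oracle in the test suite bounds the approximation error.

Numerical choices: every GLS solve runs on an eigenvalue-floored
($10^{-10}$), re-symmetrized, unit-diagonal copy of the LD matrix,
because sample LD from a few hundred reference donors is routinely
indefinite after subsetting. Clumping ties on p-value break by
chromosome:position so results are independent of row order.
Confidence intervals use the normal quantile 1.959964 throughout; odds
ratios are exponentiated only at the reporting layer. The published
threshold "LD < 0.3" (and reverse-MR "LD < 0.05") is interpreted as
$r^2$, the clumping convention; both are configuration-exposed.

## The synthetic test bed

The generator emulates the statistical structure of the study — not its
biology: one LD block (default 60 variants, AR(1) dosage correlation
0.8, 5 kb spacing) around a designated drug-target gene; an LDL-C-like
unit-SD exposure driven by 10 causal variants spread across the block
(regional $h^2 \approx 0.2$); optional mediators receiving
$\alpha\times$ the exposure's genetic path plus their own causal
variants, standardized to unit variance; and a binary T2D-like outcome
whose liability $\theta X + \sum\beta_m M_m + \varepsilon$ uses a
*logistic* residual, so thresholding at the prevalence quantile (10%)
coincides with a logistic model and $\theta$ is a log-odds-per-SD
effect on every path. Cohorts (50,000 per GWAS arm by default, LD
reference panel of 494 — the size of a 1000 Genomes ancestry panel) are
disjoint by construction, giving the two-/three-sample design.

Two sampling modes share one ground truth. `"individual"` draws
Hardy–Weinberg 0/1/2 dosages from a latent-Gaussian haplotype model in
which **every** pairwise latent correlation is calibrated (tetrachoric
Hermite-series inversion) so realized dosage LD matches the target at
all distances, then runs genuine per-variant marginal regressions
(linear, or logistic for the outcome, with a linear-probability
shortcut rescaled by $1/(K(1-K))$ for calibration suites).
`"summary"` draws the marginal estimates directly from their asymptotic
distribution, $\hat\beta \sim \mathcal N(R\,b,\; R/n_{\mathrm{eff}})$
with $n_{\mathrm{eff}} = nK(1-K)$ on the outcome side — the standard
summary-statistic sampling model — which makes ten-thousand-replicate
calibrations run in seconds. One caveat is physical: dosage
correlations between variants with very different allele frequencies
are bounded (Fréchet) below high targets, so heterogeneous-MAF
configurations realize capped adjacent LD; LD-calibration checks use
near-constant MAF configurations where the target is attainable.

What passing tests show — and what they do not: calibration and
recovery hold under this generator's homogeneous-effect,
single-block, additive, panmictic world. Real data add polygenic
leakage into flanking regions, allele-frequency and LD differences
between the GWAS cohort and the reference panel, sample overlap,
population stratification and selection effects, none of which the
generator emulates; the test bed validates the estimators' arithmetic
and their advertised operating characteristics, not robustness to
those failure modes.

## Study conditions used by the shipped analyses

Replicate experiments (test suite and acceptance script) use: null and
$\theta=0.35$ studies at 50,000 per arm with ~10–19 selected
instruments; a mediation study with $\alpha=0.35$, $\beta=0.25$,
$\theta_{direct}=0.2625$ (planted proportion 25%), the mediator owning
three causal variants at the far end of the block so its instruments
are nearly independent of the target region's; colocalization at 1%
explained variance and $n=20{,}000$ per trait; HEIDI null calibration
at 2% explained variance. The IVW type-I calibration uses the
fixed-effect variance model — the correct model under the generator's
homogeneous null — while default analyses keep the count-based model
switch. The full screen demo runs at 20,000/20,000/5,000 cohort sizes
with a deliberately modest mediator ($\alpha = 0.12$) so that no
instrument trips the outcome-association removal filter, plus eight
null features; these sizes keep a complete run in seconds while leaving
every filter active.

Known limitations, stated once: exposure-side uncertainty is excluded
from IVW weights (NOME); coloc assumes a single causal variant per
trait, so the polygenic drug-target region itself colocalizes poorly
with the outcome even under a genuinely causal simulation (the
dedicated single-causal scenarios are the meaningful coloc test);
Satterthwaite tails are approximate in the far tail; and the built-in
gene TSS table (GRCh37) is a convenience, overridable per region.

## Design choices that were genuinely open

The spec-level decision points resolved here, with reasons: palindromic
ambiguity bound 0.42 (common practice; the alternative "drop all"
policy is exposed); multi-allelic sites dropped rather than matched by
allele pair (no reliable cross-file ordering); proportion-mediated
denominator = total univariable effect (matches how mediation
percentages are quoted; the direct+indirect alternative is a config
change away); fixed-vs-random IVW switch at 3 instruments (mirrors the
reference implementation's behavior when LD is supplied); HEIDI
covariance construction as documented above, validated by
null-calibration simulation rather than by a published formula; and
binary-outcome summary statistics on the log-odds scale end to end,
with the liability threshold realized through a logistic residual so
the two sampling modes agree.
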