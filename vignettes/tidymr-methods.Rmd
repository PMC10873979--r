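---
title: "Methods: two-sample and multivariable Mendelian randomization in tidymr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample and multivariable Mendelian randomization in tidymr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidymr)
library(dplyr)
```

## The model and its assumptions

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure on an outcome from GWAS summary statistics alone. For SNP $j$, let
$\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) be its per-allele association with the
exposure and $\hat\beta_{Yj}$ (SE $\sigma_{Yj}$) its association with the
outcome (log-odds for a binary outcome). If SNP $j$ is a valid instrument —
relevant, independent of confounders, and affecting the outcome only through
the exposure — then $\beta_{Yj} = \theta\,\beta_{Xj}$ and each Wald ratio
$\hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the causal effect $\theta$.

The estimators implemented here are the standard battery:

* **IVW** (`mr_ivw()`): the inverse-variance-weighted mean of the Wald
  ratios, computed as the weighted regression of $\hat\beta_Y$ on
  $\hat\beta_X$ through the origin with weights $1/\sigma_{Yj}^2$ (the two
  formulations are algebraically identical). The default effects model is
  multiplicative random effects: the fixed-effect SE is scaled by
  $\max(1, \hat\sigma)$ where $\hat\sigma^2$ is the weighted residual mean
  square. Underdispersion is never rewarded (the floor at 1); a
  fixed-effect model is available by flag. P-values use the normal test.
* **MR-Egger** (`mr_egger()`): the same regression with an intercept,
  after orienting every SNP so $\hat\beta_{Xj} \ge 0$. The slope is a
  pleiotropy-robust causal estimate under the InSIDE assumption; a nonzero
  intercept measures directional pleiotropy. Slope and intercept are tested
  against $t_{n-2}$.
* **Weighted median** (`mr_weighted_median()`): ratios are ordered,
  inverse-variance weights ($1/\mathrm{se}^2_{\text{ratio},j}$, first-order
  delta method) are normalized, each ratio is placed at its cumulative
  weight minus half its own weight, and the estimate is the linear
  interpolation at weight 0.5. It is consistent when valid instruments
  carry more than half the weight. Its SE is a parametric bootstrap
  (default 1000 replicates, seedable; `n_boot = 0` skips the SE for fast
  point estimation in simulations).
* **Multivariable MR** (`mvmr_ivw()`, `mvmr_egger()`, `mvmr_median()`):
  weighted multiple regression of $\hat\beta_Y$ on $K$ exposure-effect
  columns through the origin; each coefficient is that exposure's *direct*
  effect conditional on the others. The Egger variant adds an intercept
  (orientation by the first exposure; intercept tested on $t_{n-K-1}$).
  The median variant minimizes the weighted absolute residuals
  (0.5-quantile regression through the origin) by iteratively reweighted
  least squares, bootstrap SEs. At $K=1$ the IVW and Egger variants reduce
  exactly to their univariable forms.

All intervals use the conventional 1.96 multiplier on the normal scale
(t-quantiles for Egger intercepts), and `to_odds_ratio()` exponentiates
estimate and interval for binary outcomes.

## Instrument selection and harmonization

`select_instruments()` applies, in order: the genome-wide significance
filter ($p < 5\times10^{-8}$, strict), greedy LD clumping (lowest p-value
first, removing neighbours within 10,000 kb at $r^2 > 0.001$), exclusion of
SNPs annotated to listed confounder traits (local annotation table standing
in for a PhenoScanner query, screened at $5\times10^{-8}$), exclusion of
SNPs genome-wide associated with the outcome, and proxy substitution for
instruments missing from the outcome panel ($r^2 > 0.8$, strict; best
$r^2$, ties by distance then rsid). Every stage logs counts into an
attrition table. The ordering follows the narrative sequence of standard MR
pipelines; it is a documented choice, since filter order is not an
invariant. Proxy substitution replaces the missing SNP by the proxy's *own*
exposure and outcome records rather than splicing records of two different
SNPs: our LD reference stores $r^2$ only, so the allele phase needed for
splicing is not identifiable.

Instrument strength uses the standardized-trait approximation
$r^2_j = 2\,\mathrm{MAF}_j(1-\mathrm{MAF}_j)\beta_j^2$ and
$F_j = r^2_j (n-2)/(1-r^2_j)$, flagging $F \le 10$; when the allele
frequency is missing, an optional fallback uses
$F_j = (\beta_j/\mathrm{se}_j)^2$.

`harmonize()` aligns all betas to the (first) exposure's effect allele:
identical alleles are kept, swapped alleles negate the outcome beta and
complement its EAF, complementary alleles are strand-corrected first, and
palindromic SNPs (A/T, G/C) — whose strand cannot be resolved from allele
labels — are oriented by allele-frequency agreement when both EAFs lie
outside $0.5 \pm 0.08$ (configurable band), else dropped as ambiguous. A
stricter drop-all-palindromic policy is available. Irreconcilable allele
sets are dropped as incompatible. Dropped SNPs never appear in the returned
frame; the full audit is attached as an attribute and serialized with the
frame.

## Sensitivity battery

* **Cochran's Q** (`mr_cochran_q()`):
  $Q = \sum_j w_j(\hat\theta_j - \hat\theta)^2$ over the Wald ratios with
  $w_j = 1/\mathrm{se}^2_{\text{ratio},j}$, $\chi^2_{n-1}$ p-value, and
  $I^2 = \max(0, (Q - df)/Q)\cdot 100$.
* **MR-PRESSO** (`mr_presso()`): the observed residual sum of squares uses
  leave-one-out IVW slopes, $RSS = \sum_j w_j(\hat\beta_{Yj} -
  \hat\theta_{(-j)}\hat\beta_{Xj})^2$; `n_sim` datasets are simulated from
  the fitted no-pleiotropy model (normal draws centred on
  $\hat\beta_{Xj}$ and $\hat\theta_{(-j)}\hat\beta_{Xj}$ with the observed
  SEs) and Monte-Carlo p-values use the add-one estimator
  $(1 + \#\{RSS^* \ge RSS\})/(n_{sim}+1)$, which avoids zero p-values and
  makes the test's size $\approx \alpha$ by construction. When the global
  test fires, per-SNP squared residuals are compared to their simulated
  distributions with Bonferroni correction across SNPs; the corrected
  estimate is IVW on the outlier-free frame (exactly — this identity is
  tested). The distortion test compares the observed relative displacement
  of the IVW estimate against displacements obtained by removing random
  inlier subsets of the same size; this operationalization of the
  distortion reference distribution is our variant of the procedure. The
  p-value resolution is $1/(n_{sim}+1)$, so Bonferroni-corrected per-SNP
  calls need $n_{sim}$ of roughly $20\times$ the SNP count or more;
  `n_sim = 1000` (the customary default) is adequate for panels up to ~50
  SNPs.
* **Leave-one-out** (`mr_leave_one_out()`): IVW with each SNP excluded;
  a SNP is flagged influential when its exclusion changes the estimate's
  sign or moves it outside the full-frame 95% CI. This flag is an explicit
  heuristic operationalization of "strongly deviating".
* **Funnel data** (`mr_funnel_data()`): per-SNP ratio against precision
  $1/\mathrm{se}_{\text{ratio}}$, plus a weighted regression of ratio on
  precision whose slope is $\approx 0$ for a symmetric funnel — symmetry,
  not asymmetry, is the no-pleiotropy signature, so the package reports the
  regression rather than asserting a verbal reading.

## The study driver

`mr_study()` (or `run_study()` from a YAML config) runs the full design:
per-exposure instrument selection, harmonization, the three univariable
estimators, the sensitivity battery, automatic outlier-corrected re-analysis
when MR-PRESSO flags SNPs (both passes reported), then multivariable MR on
the jointly re-clumped union of the per-exposure instrument sets, aligned
complete-case to the first exposure's effect alleles. Significance of the
final-pass IVW p-values uses the Bonferroni threshold
$\alpha/K$ (0.05/4 = 0.0125 for a four-exposure family, conventionally
printed as 0.013) with a suggestive band up to 0.05 (strict upper bound).
Indirect effects are reported descriptively as total (univariable) minus
direct (multivariable), without a mediation SE. Everything is deterministic
given the config seed; per-exposure seeds are derived from it.

The multivariable instrument set is built union-then-joint-reclump (each
SNP ranked by its best p-value across exposures); per-exposure selection
before joint clumping is the documented default among the defensible
alternatives.

## The synthetic-data generator

`simulate_study()` exists so that every stage above can be exercised and
validated end-to-end with known ground truth. Its defaults emulate the
structure of a thyroid-function study: a large continuous exposure GWAS
($N = 119{,}715$), a biobank case-control outcome ($N = 211{,}023$, case
fraction $5668/211023 \approx 0.027$), block-constant LD, ~15% palindromic
variants, and outcome records with swapped allele labels and strand flips
that harmonization must undo. Summary statistics are simulated directly on
the summary level: $\hat\beta_X \sim N(\gamma_j, \sigma_{Xj}^2)$ with
$\sigma_{Xj} = 1/\sqrt{2N_X \mathrm{MAF}_j(1-\mathrm{MAF}_j)}$, binary
outcome effects on the log-odds scale with
$\sigma_{Yj} = 1/\sqrt{2 N_Y cf(1-cf)\cdot 2\mathrm{MAF}_j(1-\mathrm{MAF}_j)}$.
This is the standard two-sample MR simulation design; it deliberately does
*not* model individual-level genotypes, realistic LD decay, sample overlap,
or winner's curse, so passing tests demonstrate correctness of the
statistical machinery, not robustness to those real-data phenomena.

Design choices worth stating explicitly:

* **Effect orientation.** True instrument effects are half-normal
  ($|N(0, sd^2)|$) by default, i.e. reported for the trait-increasing
  allele. With sign-symmetric effects, directional pleiotropy has zero
  *average* effect on the IVW slope ($E[\gamma\alpha] = 0$) and
  directional-bias experiments would be vacuous; orientation to the
  trait-increasing allele is what published MR simulations do. A signed
  normal option exists.
* **Exposure effect scale.** The study-scale default
  `exposure_effect_sd = 0.05` makes a realistic majority of drawn
  instruments reach genome-wide significance at the default exposure
  sample size; power-focused experiments in the tests use 0.09–0.10 so a
  $\theta = 0.11$ log-odds effect is detectable with ~30–40 instruments at
  the Bonferroni threshold, mirroring the instrument strength (F from 30
  to ~1200) of real thyroid panels.
* **Instrument sharing.** By default all exposures have effects at the
  same instrument SNPs (required by multivariable MR). Because
  trait-oriented effects of two exposures then have a positive
  cross-moment, a null exposure sharing instruments with a causal one is
  *genuinely* confounded in univariable MR — an instructive artefact, but
  not the design of a study whose four traits have their own panels. The
  `instrument_assignment = "disjoint"` mode gives each exposure its own
  instrument blocks and is used for the four-exposure power experiment.
* **Pleiotropy.** `balanced`, `directional` and `inside_violating`
  (correlated with instrument strength) modes apply $\alpha_j$ to a
  configurable `invalid_fraction` of instruments; planted outliers add a
  fixed offset at chosen SNPs. The truth object records exactly which SNPs
  are invalid ($\alpha_j \ne 0$) and which are outliers.
* **LD.** Block-constant $r^2 = \rho^2$ within blocks, zero across; one
  instrument per block head so instruments are mutually independent and
  clumping is exercised without destroying the instrument panel.

## Numerical and statistical fine print

* Monte-Carlo p-values (MR-PRESSO) use $(1+k)/(n_{sim}+1)$; p-values from
  normal/t/χ² tests are clamped to be strictly positive.
* The weighted-median interpolation clamps to the extreme ratios when the
  0.5 weight point falls outside the half-weight grid (degenerate,
  dominant-weight cases).
* The multivariable median IRLS uses residual floor $10^{-8}$ (relative to
  the response scale) and converges to the weighted-L1 optimum (verified
  against direct Nelder-Mead minimization during development); with one
  exposure, constant $|\hat\beta_X|$ and constant $\sigma_Y$ it agrees
  with the univariable weighted median, but in general quantile
  *regression* weights ($w_j$ per observation) and weighted-median ratio
  weights ($w_j\hat\beta_{Xj}^2$) differ — both are reported faithfully.
* Under 40% one-sided directional contamination, the weighted median has a
  finite-sample quantile-shift bias of order
  $\sigma_{\text{ratio}}\,\Phi^{-1}(0.5/0.6)$; the bias-to-sampling-SD
  ratio is scale-free in every generator parameter, so the estimator's
  mean over many replicates is *not* expected to converge to the truth —
  the meaningful robustness statement, and the one the tests assert, is
  that its displacement stays within its own per-replicate spread and
  strictly below the IVW displacement, while the IVW bias exceeds many
  times its Monte-Carlo standard error.
* Orientation of weak instruments by $\mathrm{sign}(\hat\beta_X)$
  misclassifies some SNPs, which attenuates the Egger intercept's recovery
  of a planted pleiotropy mean by roughly 15% at the default instrument
  strength; the intercept test retains power.
* `1 - (1 - \mathrm{eaf})` is not exact in binary floating point, so
  harmonization round-trips reproduce effect columns bitwise but allele
  frequencies only to one ulp.

## Problem sizes used in the tests

Monte-Carlo experiments in the test-suite and acceptance script use 50
instruments and 200 replicates for parameter recovery, coverage and
robustness; 100 runs (30 instruments, $n_{sim}=1000$) for outlier
detection; 500 runs for global-test calibration; and 30–50 replicates of
the full four-exposure study for end-to-end power. These sizes give
Monte-Carlo standard errors a factor ~3 below the tested tolerances.

## Known limitations

No Steiger filtering, mode-based estimators, radial MR, or bidirectional
analyses; no VCF parsing or genome-build liftover (builds are the caller's
responsibility); LD is block-constant with $r^2$ only (no signed LD, hence
full-substitution proxies); indirect effects carry no formal mediation SE.
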