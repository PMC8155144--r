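---
title: "Methods: stress-induced mPFC glutamate change, MGR, and EMA scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stress-induced mPFC glutamate change, MGR, and EMA scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glustress)
```

## The design and its assumptions

The package analyzes a four-group acute-stress MRS design: two healthy
control samples and an unmedicated MDD sample complete an acute stressor
between two mPFC MRS scans, while a no-stress control (NSC) sample
completes a matched non-stressful task. The scientific object is the
moderation of the glutamate response by recent perceived stress: in healthy
controls, percent-change creatine-normalized glutamate (%ΔGlu) declines
linearly with the Perceived Stress Scale (PSS), whereas the MDD group —
despite far higher PSS — shows no such law. The pipeline's assumptions are
those of the constituent methods: creatine ratios as within-session
normalizers, a linear PSS law in the healthy calibration sample, OLS-valid
residuals for the calibration fit, and rank-based (Spearman) inference for
the modest per-group sample sizes.

Percent change is carried on the 0–100 scale throughout
(`percent_change(0.8, 1.0)` is 25, not 0.25), which is the scale on which
the published calibration intercept (35.647) lives.

## The maladaptive glutamate response (MGR)

The calibration law is fitted by OLS on *raw* (uncentered) PSS over the
designated calibration sample only — the printed equation has a raw-PSS
intercept, so centering would change the reported coefficients. Every other
stress-condition participant is scored strictly out of sample:
`MGR = observed − expected`. Two consequences are used as tests: the mean
MGR of the calibration sample itself is exactly zero (OLS residual
property), and permuting or translating the scored subjects' data can never
alter the fit. The pipeline names the calibration group in its config
(default `hc_stress_calibration`), so out-of-sample discipline is enforced
structurally rather than by convention.

Correlation analyses between PSS and metabolite changes use Spearman's
method; the calibration function itself is an OLS line because the
published expected-change equation is linear in raw units. Whether the
published coefficients were fitted before or after outlier exclusion is not
determinable from the text; this pipeline fits after QC and outlier
exclusion.

## Scan quality control

A scan fails when SNR < 9, FWHM > 0.15 ppm, or glutamate CRLB > 20 %. The
stated rules are strict inequalities, so boundary values (SNR = 9,
FWHM = 0.15, CRLB = 20) are retained; the thresholds are configurable
through `qc_thresholds()`. CRLB screening is applied to glutamate only —
whether other metabolites were CRLB-screened is unstated, so only the
stated rule is enforced. The 3-SD outlier rule is applied to %ΔGlu pooled
across all QC-passing participants, with sample (n − 1) standard
deviation and a zero-spread guard. Exclusion reasons are accumulated as
labels (`snr`, `fwhm`, `crlb_glu`, `missing_session`,
`glu_change_outlier`) so audits can attribute every drop.

## EMA filtering and scoring

Validity rules and the decisions behind their ambiguous points:

* *completed in less than 30 s* — measured start-to-completion (active
  filling time), configurable;
* *more than 24 h* — measured send-to-completion (staleness relative to
  delivery), configurable;
* *within 1 to 3 h following the prior survey* — inclusive bounds between
  consecutive completion times within the same calendar day; the rule
  never spans midnight. The walk compares each otherwise-eligible survey
  to the most recent survey that passed all rules, so invalid surveys are
  transparent: they neither anchor the window nor pick up a spacing
  reason on top of their own violations. This makes filtering idempotent.

Outcome–expectation pairs use adjacency of *valid* surveys (the outcome
prompt refers to the last chosen activity, and invalid surveys are
transparent); the first valid survey of a day contributes no pair.
"Accurate" is operationalized as delta exactly 0 — on the integer response
grid the three classes then partition all pairs, which is what makes the
reported class proportions sum to one. Directional means over an empty
class are *absent* (NA), never zero. "Usable survey data points" counts
valid surveys, not pairs, and inclusion requires at least 20 of them, with
"less than 20" excluding (19 is out, 20 is in).

## The statistical battery

* **Spearman** — Pearson correlation of average ranks, two-tailed p from
  the t approximation on n − 2 df.
* **Partial correlation** — correlation of OLS residuals of x and y on the
  covariates (plus intercept), df = n − 2 − k; two-level factors are
  dummy-coded. A second, independent computation path (the recursive
  partial-correlation identity) is used in tests to confirm the
  residualization to 1e-10. Pairwise exclusion: each correlation uses the
  complete cases of its own variable set.
* **Repeated-measures ANOVA** — split-plot F tests from the classical
  error-stratum decomposition; Greenhouse–Geisser ε from the pooled
  within-group covariance through orthonormal polynomial contrasts
  (ε ∈ [1/(k−1), 1], exactly 1 under compound symmetry); Mauchly's
  sphericity test delegated to the reference implementation in `stats` on
  the equivalent multivariate linear model. Under the default `"auto"`
  rule the correction is adopted when k > 2 and the pretest rejects at
  0.05; `"always"` reproduces reporting styles that print fractional df
  throughout. With unequal group sizes the omnibus table uses sequential
  sums of squares; polynomial contrasts are tested on per-subject contrast
  scores with sum-to-zero group coding.
* **Hierarchical stepwise regression** — block 1 forced; block 2 enters by
  smallest probability-of-F below 0.05 and removes block-2 terms above
  0.10 (the common defaults of the software family that popularized the
  procedure; configurable). Continuous predictors are mean-centered before
  products are formed; dummies stay 0/1. ΔR² F-change compares the block-1
  model against the final model; standardized β is b·sd(x)/sd(y) over the
  built design columns, dummy codes included.
* **Steiger's Z** — the Z1* variant with the averaged-correlation
  covariance term, appropriate for two dependent correlations sharing one
  variable; verified against an independent implementation to 1e-10.
* **Bootstrap** — percentile intervals from case resampling (B = 1000 by
  default); BCa is not used because nothing more than percentile
  bootstrapping is specified for the intervals being reproduced.
  Undefined resamples are redrawn and counted.
* **ICC** — single-measure two-way mixed absolute agreement (McGraw–Wong
  A,1), the variant that penalizes systematic session offsets; p from
  F = MSR/MSE.
* **Effect size for paired change** — the change-score-standardized mean
  change d = mean(Δ)/sd(Δ); a pre-score-sd standardizer is available as an
  option since the defining supplement is not part of the package inputs.

## What the synthetic generator emulates — and what it does not

`cohort_config()` defaults are the study conditions: group sizes
25/22/18/23; per-group PSS moments (10.12 ± 3.70, 9.00 ± 5.04,
12.11 ± 5.45, 27.43 ± 5.89); the calibration law 35.647 − 3.093·PSS with
slope multiplier 1 in the stressed healthy groups and 0 in NSC and MDD;
age moments per group with an age–baseline-glutamate Gaussian-copula
correlation of −0.237. The %ΔGlu residual sd defaults to 20 %, which puts
the implied PSS correlation near |r| = 0.5 in the calibration group — the
effect size regime of the original samples. PSS is drawn Gaussian and
rounded to the integer instrument grid; clipping to [0, 40] is available
but off by default because it biases the generating moments.

Baseline metabolite ratios (Glu/Cr 1.0 ± 0.1, Glx/Cr 1.6 ± 0.15, Cho/Cr
0.25 ± 0.03) are placeholder scales: the study's metabolite tables are
supplementary material not available to this package, so these are
plausible creatine-ratio magnitudes, clearly flagged in the config docs
and freely overridable. The post-stress ratio is derived exactly from the
baseline and the target percent change, so Eq.-style scoring inverts the
generator without error.

Cortisol responses are a percent rise (default +30 % at the first
post-stress timepoint, half retained at the second, slightly negative
drift under no stress) applied to a log-normal baseline, with a
between-subject rise sd of 75 % — the realistic responder/non-responder
mix, chosen so the standardized mean-change effect size sits near the
d ≈ 0.37 magnitude typical of acute stressors. VAMS mood is generated as a
negativity trajectory peaking after the stressor, stored under mixed item
polarities (so the polarity-reflection code path is always exercised),
with a shared per-administration noise component that makes the five items
of one timepoint correlate as real mood ratings do.

The EMA stream couples the subject-level mean shift of
(outcome − expectation) to MGR through a latent
`z = coupling · standardize(MGR) + sqrt(1 − coupling²) · noise`, with MGR
standardized *within diagnostic group* because the recovery analysis
partials group out — pooled standardization would attenuate the recovered
partial correlation below its nominal value by construction. Deltas are an
exact-zero accuracy mass (0.25) plus `round(0.5 + 1.3·z + N(0, 0.9))`,
clamped to the −4..+4 grid. The shift scale and noise were calibrated once,
against the generator's own Monte-Carlo recovery oracle at large n, so that
the scored pessimistic-expectation mean recovers a coupling of 0.5 to
within the design band after the unavoidable attenuation from
discretization, grid clamping and finite pairs per subject; at the study's
sample sizes the mean recovered partial correlation is ≈ 0.40. The
symmetric shift also moves the optimistic-side magnitudes slightly — a
simplification relative to data in which only the pessimistic side tracks
the biology.

What passing tests on this generator do **not** show about real data:
spectra are never simulated (QC metrics are drawn directly, not derived
from spectral fits); missingness is uniform rather than behaviorally
structured; EMA affect dynamics are exchangeable within person (no
autocorrelation, time-of-day or weekday structure); and the MGR–pessimism
coupling is linear-Gaussian by construction. The generator validates the
*pipeline*, not the biology.

## Numerical choices

* Exactly-zero effect sums of squares in the ANOVA are detected with a
  relative tolerance (1e-10 of the total SS) and reported as F = 0, p = 1
  rather than 0/0.
* A residualized variable whose sd falls below 1e-10·(sd + 1) of its
  source is treated as constant: the partial correlation is set to 0 with
  a warning rather than correlating numerical noise.
* Stepwise fits with undefined coefficient p-values (aliased or saturated
  models) treat the p as 1, so such candidates never enter and aliased
  terms drop.
* All random draws flow through a single seeded stream per generator call,
  consumed in a documented fixed order (participants by group, then scans,
  cortisol, VAMS; the EMA stream uses seed + 1 so it is reproducible
  independently of the cohort draw). Timestamps are generated at whole
  seconds so CSV round-trips are lossless.
* Survey corruption for filter testing injects at most one labeled
  violation per participant-day, so corruption types map deterministically
  to exclusion reasons.

## Problem sizes

The test suite exercises the generator at the study's sample sizes
(n = 88) for pipeline checks, n = 5,000 per group for law-recovery checks,
and n = 100,000 for distributional moments; recovery properties
(correlation signs, interaction and quadratic significance rates, the
MGR–pessimism coupling) are measured over 200 seeded replicates, and
bootstrap coverage over 500 replicates at B = 1000. These sizes make the
Monte-Carlo error small relative to each property's acceptance band while
keeping a full run of suite plus acceptance script under ten minutes on a
single CPU.

## Known limitations

The pipeline deliberately omits spectral fitting, water-referenced
quantification and tissue correction (upstream of its inputs), multilevel
EMA modeling, and any multiple-testing correction across the report (the
reproduced analyses are uncorrected two-tailed tests). The stepwise
procedure inherits the known instability of p-value-driven selection in
small samples; it is provided because it is the procedure the analysis
family uses, not as a recommendation. MGR inherits the calibration
sample's estimation error: with n = 25 the fitted slope varies
substantially around the generating value, and MGR for scored subjects
varies with it.
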