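#' Configuration for the synthetic cohort generator
#'
#' Builds the parameter set that [generate_cohort()] and
#' [generate_ema_streams()] consume. Defaults reproduce the structure of the
#' four-group acute-stress MRS design: two healthy-control stress samples
#' (one designated as the calibration sample), a no-stress control (NSC)
#' sample, and an unmedicated MDD sample, with per-group Perceived Stress
#' Scale (PSS) moments taken from the study's demographics table and the
#' healthy-control calibration law `%dGlu = 35.647 - 3.093 * PSS`.
#'
#' Percent-change glutamate is generated as
#' `multiplier * (intercept + slope * PSS) + N(0, residual_sd)`, with the
#' multiplier 1 in the stressed healthy-control groups and 0 in NSC and MDD
#' (no PSS-glutamate law). The post-stress Glu/Cr ratio is derived exactly
#' from the baseline ratio and the target percent change, so percent-change
#' scoring inverts the generator without error.
#'
#' Baseline metabolite levels (`baseline_glu_mean` and friends) are
#' placeholder scales: the source study reports them only in supplementary
#' tables that are not part of this package's inputs. They are plausible
#' creatine-ratio magnitudes and every one is overridable.
#'
#' @param seed Integer seed; the generator consumes a single seeded stream
#'   in fixed order, so identical configs give identical outputs.
#' @param n Named integer vector of per-group sample sizes. Names must be
#'   `hc_stress_calibration`, `hc_stress_replication`, `nsc`, `mdd`.
#' @param pss_mean,pss_sd Per-group PSS distribution moments (instrument
#'   range 0-40).
#' @param clip_pss Clip generated PSS to the 0-40 instrument range. Off by
#'   default because clipping biases the generating moments.
#' @param calibration_intercept,calibration_slope The linear law (percent,
#'   percent per PSS unit) used for stressed healthy controls.
#' @param slope_multiplier Per-group multiplier on the law (1 = full law,
#'   0 = flat).
#' @param residual_sd Residual sd of percent-change glutamate around the
#'   law, in percent. The default 20 puts the implied PSS correlation near
#'   |r| = 0.5 in the calibration group.
#' @param baseline_glu_mean,baseline_glu_sd,baseline_glx_mean,baseline_glx_sd,baseline_cho_mean,baseline_cho_sd
#'   Baseline creatine-normalized ratio moments (dimensionless).
#' @param glx_change_sd Extra noise (percent) of the Glx change around the
#'   Glu change (the two move together).
#' @param cho_change_sd Sd (percent) of the choline change, which carries no
#'   PSS signal.
#' @param age_mean,age_sd,age_range Per-group age moments and the clip range.
#' @param age_glu_cor Target correlation between age and baseline Glu/Cr
#'   (negative by default: baseline glutamate declines with age).
#' @param pct_female Per-group percent female.
#' @param snr_mean,snr_sd,fwhm_mean,fwhm_sd,crlb_mean,crlb_sd Scan-quality
#'   metric distributions (SNR dimensionless, FWHM ppm, CRLB percent).
#' @param qc_fail_fraction Fraction of scans corrupted to fail one quality
#'   rule, for exercising the QC filter.
#' @param cortisol_baseline_mean Median pre-stress salivary cortisol
#'   (nmol/L; drawn log-normally).
#' @param cortisol_peak_rise Mean percent rise at the first post-stress
#'   timepoint for stress-condition subjects.
#' @param cortisol_decay Fraction of the peak rise retained at the second
#'   post-stress timepoint.
#' @param cortisol_nsc_rise Mean percent change for the no-stress condition
#'   (slightly negative: cortisol drifts down without a stressor).
#' @param cortisol_noise_sd Between-subject sd of the percent rise at each
#'   post timepoint. The default 75 emulates the realistic mix of cortisol
#'   responders and non-responders, putting the standardized mean-change
#'   effect size near d = 0.37.
#' @param vams_baseline Baseline negative-affect level (0-100) for healthy
#'   controls.
#' @param vams_mdd_shift Additive negative-affect shift for the MDD group.
#' @param vams_amplitude Peak increase in negative affect after the
#'   stressor, for stress-condition subjects (0-100 points).
#' @param vams_noise_sd Per-item noise sd.
#' @param vams_tp_noise_sd Shared per-subject-per-timepoint noise sd (makes
#'   the five items of one administration correlate, as real mood ratings
#'   do).
#' @param rating_stress_mean,rating_nsc_mean Mean post-scan subjective
#'   ratings (1-5) for stress and no-stress conditions.
#' @param ema An [ema_config()] list.
#' @return A list of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(seed = 42, n = c(hc_stress_calibration = 10,
#'   hc_stress_replication = 10, nsc = 5, mdd = 5))
#' cohort <- generate_cohort(cfg)
#' names(cohort)
cohort_config <- function(seed = 1L,
                          n = c(hc_stress_calibration = 25L,
                                hc_stress_replication = 22L,
                                nsc = 18L,
                                mdd = 23L),
                          pss_mean = c(hc_stress_calibration = 10.12,
                                       hc_stress_replication = 9.00,
                                       nsc = 12.11,
                                       mdd = 27.43),
                          pss_sd = c(hc_stress_calibration = 3.70,
                                     hc_stress_replication = 5.04,
                                     nsc = 5.45,
                                     mdd = 5.89),
                          clip_pss = FALSE,
                          calibration_intercept = 35.647,
                          calibration_slope = -3.093,
                          slope_multiplier = c(hc_stress_calibration = 1,
                                               hc_stress_replication = 1,
                                               nsc = 0,
                                               mdd = 0),
                          residual_sd = 20,
                          baseline_glu_mean = 1.0, baseline_glu_sd = 0.1,
                          baseline_glx_mean = 1.6, baseline_glx_sd = 0.15,
                          baseline_cho_mean = 0.25, baseline_cho_sd = 0.03,
                          glx_change_sd = 5,
                          cho_change_sd = 8,
                          age_mean = c(hc_stress_calibration = 26.04,
                                       hc_stress_replication = 28.36,
                                       nsc = 23.44,
                                       mdd = 29.87),
                          age_sd = c(hc_stress_calibration = 6.20,
                                     hc_stress_replication = 8.21,
                                     nsc = 4.40,
                                     mdd = 10.61),
                          age_range = c(18, 60),
                          age_glu_cor = -0.237,
                          pct_female = c(hc_stress_calibration = 60.0,
                                         hc_stress_replication = 68.8,
                                         nsc = 77.8,
                                         mdd = 69.6),
                          snr_mean = 15, snr_sd = 2,
                          fwhm_mean = 0.08, fwhm_sd = 0.02,
                          crlb_mean = 8, crlb_sd = 3,
                          qc_fail_fraction = 0,
                          cortisol_baseline_mean = 8,
                          cortisol_peak_rise = 30,
                          cortisol_decay = 0.5,
                          cortisol_nsc_rise = -5,
                          cortisol_noise_sd = 75,
                          vams_baseline = 30,
                          vams_mdd_shift = 12,
                          vams_amplitude = 8,
                          vams_noise_sd = 10,
                          vams_tp_noise_sd = 8,
                          rating_stress_mean = 3.8,
                          rating_nsc_mean = 1.4,
                          ema = ema_config()) {
  groups <- c("hc_stress_calibration", "hc_stress_replication", "nsc", "mdd")
  per_group <- function(x, nm) {
    if (is.null(names(x)) && length(x) == length(groups)) names(x) <- groups
    if (!setequal(names(x), groups)) {
      abort(sprintf("`%s` must be named with the four group labels.", nm))
    }
    x[groups]
  }
  n <- per_group(n, "n")
  if (any(n <= 0) || any(n != as.integer(n))) {
    abort("`n`: all per-group sample sizes must be positive integers.")
  }
  pss_mean <- per_group(pss_mean, "pss_mean")
  pss_sd <- per_group(pss_sd, "pss_sd")
  if (any(pss_sd < 0)) abort("`pss_sd`: standard deviations must be >= 0.")
  if (clip_pss && any(pss_mean < 0 | pss_mean > 40)) {
    abort("`pss_mean`: means must lie on the 0-40 instrument scale when clipping is enabled.")
  }
  slope_multiplier <- per_group(slope_multiplier, "slope_multiplier")
  age_mean <- per_group(age_mean, "age_mean")
  age_sd <- per_group(age_sd, "age_sd")
  pct_female <- per_group(pct_female, "pct_female")
  for (nm in c("residual_sd", "baseline_glu_sd", "baseline_glx_sd",
               "baseline_cho_sd", "glx_change_sd", "cho_change_sd",
               "cortisol_noise_sd", "vams_noise_sd", "vams_tp_noise_sd", "snr_sd", "fwhm_sd",
               "crlb_sd")) {
    if (get(nm) < 0) abort(sprintf("`%s` must be >= 0.", nm))
  }
  if (abs(age_glu_cor) > 1) abort("`age_glu_cor` must lie in [-1, 1].")
  if (qc_fail_fraction < 0 || qc_fail_fraction > 1) {
    abort("`qc_fail_fraction` must lie in [0, 1].")
  }
  if (!inherits(ema, "ema_config")) abort("`ema` must be built by ema_config().")
  cfg <- as.list(environment())
  cfg$groups <- groups
  cfg$per_group <- NULL
  cfg$nm <- NULL
  structure(cfg, class = "cohort_config")
}

#' Configuration for the synthetic EMA stream generator
#'
#' Parameters of the ecological momentary assessment emulation: surveys are
#' sent six times on every other day over a four-week window, expectations
#' and outcomes live on the 9-point -4..+4 grid, and the subject-level mean
#' shift of (outcome - expectation) is coupled to the maladaptive glutamate
#' response (MGR) with a configurable strength.
#'
#' The coupling works through a subject latent
#' `z = coupling * standardize(MGR) + sqrt(1 - coupling^2) * noise`, where
#' MGR is standardized within diagnostic group (the recovery analysis
#' partials group out, so the coupled signal is the within-group
#' variation); each matched pair's delta is drawn as an exact-zero
#' "accurate" mass with probability `accurate_mass`, otherwise
#' `round(delta_base + delta_scale * z + N(0, delta_noise_sd))`, clamped so
#' the outcome stays on the instrument grid. Discretization and grid
#' clamping keep the marginals on-instrument while preserving a monotone
#' pessimism signal.
#'
#' @param days Number of active survey days (every other day; 14 days = a
#'   four-week window).
#' @param surveys_per_day Surveys sent per active day (at most 6).
#' @param completion_prob Probability a sent survey is completed.
#' @param invalid_fraction Fraction of completed surveys corrupted with a
#'   labeled validity violation (`too_fast`, `too_late`, `beyond_sixth`,
#'   `off_schedule`, `incomplete`) for filter testing.
#' @param coupling MGR-pessimism coupling strength in [-1, 1].
#' @param pos_affect_mean,neg_affect_mean Named (hc, mdd) mean levels of the
#'   1-5 positive and negative affect items.
#' @param affect_sd Affect item noise sd.
#' @param expectation_mean Named (hc, mdd) means of the planned-activity
#'   expectation before rounding to the -4..+4 grid (depressed
#'   participants expect less).
#' @param expectation_sd Expectation sd before rounding.
#' @param happened_prob Probability a planned activity is reported as having
#'   happened.
#' @param delta_base Baseline mean of (outcome - expectation); slightly
#'   positive (things go a bit better than expected on average).
#' @param delta_scale Scale mapping the subject latent to the delta shift.
#' @param delta_noise_sd Within-subject delta noise sd before rounding.
#' @param accurate_mass Probability mass of exactly accurate expectations.
#' @return A list of class `ema_config`.
#' @export
ema_config <- function(days = 14L,
                       surveys_per_day = 6L,
                       completion_prob = 0.844,
                       invalid_fraction = 0,
                       coupling = 0.5,
                       pos_affect_mean = c(hc = 3.5, mdd = 2.5),
                       neg_affect_mean = c(hc = 1.8, mdd = 2.8),
                       affect_sd = 0.7,
                       expectation_mean = c(hc = 0.6, mdd = 0.0),
                       expectation_sd = 1.5,
                       happened_prob = 0.9,
                       delta_base = 0.5,
                       delta_scale = 1.3,
                       delta_noise_sd = 0.9,
                       accurate_mass = 0.25) {
  if (days <= 0) abort("`days` must be > 0.")
  if (surveys_per_day < 1 || surveys_per_day > 6) {
    abort("`surveys_per_day` must be between 1 and 6.")
  }
  if (completion_prob < 0 || completion_prob > 1) {
    abort("`completion_prob` must lie in [0, 1].")
  }
  if (invalid_fraction < 0 || invalid_fraction > 1) {
    abort("`invalid_fraction` must lie in [0, 1].")
  }
  if (abs(coupling) > 1) abort("`coupling` must lie in [-1, 1].")
  if (!all(c("hc", "mdd") %in% names(pos_affect_mean)) ||
      !all(c("hc", "mdd") %in% names(neg_affect_mean)) ||
      !all(c("hc", "mdd") %in% names(expectation_mean))) {
    abort("affect and expectation means must be named vectors with entries `hc` and `mdd`.")
  }
  if (happened_prob < 0 || happened_prob > 1) {
    abort("`happened_prob` must lie in [0, 1].")
  }
  if (accurate_mass < 0 || accurate_mass > 1) {
    abort("`accurate_mass` must lie in [0, 1].")
  }
  structure(as.list(environment()), class = "ema_config")
}
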