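---
title: "Verifying the air kerma strength of assembled I-125 eye plaques"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying the air kerma strength of assembled I-125 eye plaques}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaqueqa)
```

## The problem

Episcleral plaque brachytherapy treats ocular melanoma by suturing a small
gold plaque loaded with radioactive seeds (here I-125) to the sclera over
the tumour. Plaques increasingly arrive pre-assembled and sterilised, so the
physicist cannot assay the individual seeds before use. Ordering and
fulfilment errors — air kerma strength confused with apparent activity,
transcribed digits, the wrong plaque shipped, a mismatch between ordered and
delivered seed strength — would otherwise reach the patient undetected.

The verification idea implemented by this package is simple: measure the
assembled plaque in an ordinary dose calibrator and compare the result with
the NIST-traceable assay certificate via a *plaque calibration factor*,

$$
CF \;=\; \frac{S_K^{\text{measured}}}{S_K^{\text{assay}}\cdot
          2^{-\Delta t / T_{1/2}}},
$$

where the measured air kerma strength comes from the mean of four
dose-calibrator readings taken at holder rotations of 0°, 90°, 180° and
270°, and the certificate strength is decayed over the signed interval
$\Delta t$ (days) from assay to measurement. The factor is far below 1 —
around 0.35 for the 17-slot Eye Physics EP917 and 0.25 for COMS plaques —
because the gold shell and, for the EP917, its collimating slots shield
laterally directed radiation from the calibrator's well. What matters is not
its absolute value but its stability within a plaque type: a plaque whose
factor deviates from its type's mean by more than an action limit is flagged
for investigation.

## Parameters and defaults

* **Half-life** `half_life_days = 59.4` d (I-125). Configurable through
  `plaque_constants()`; no other nuclide is special-cased — supply your own
  half-life if needed.
* **Activity conversion** `u_per_mci = 1.270` U per mCi (equivalently
  1 U = 0.787 mCi). The worksheet multiplies the mean activity by 1.270;
  `plaque_constants(u_per_mci = 1/0.787)` selects the inverse convention,
  which differs in the third decimal of reported strengths.
* **Reading-spread limit** `reading_spread_pct = 4`. The spread of the four
  angle readings, `100 * (max - min) / mean`, indicates how well the plaque
  was centred; above 4% the protocol is to reposition and remeasure, so the
  software raises a `READING_SPREAD` flag rather than an error. The
  denominator can be switched to the minimum reading
  (`spread_metric = "min"`); with careful centring both stay below a few
  percent and the choice is immaterial.
* **Action limit** `action_limit_pct = 5`, following AAPM low-energy
  source-calibration guidance for batch measurements of preloaded
  assemblies: a calibration factor more than ±5% from its type mean raises
  `ACTION_LIMIT`.
* **Cross-check limit** `cross_check_pct = 5`: planned and assay strengths
  (decay-aligned to the measurement date), and the plan- and assay-based
  factors, must agree within 5%; unit confusion shows up here as a 27%
  disagreement ($1/0.787 - 1$).
* **Group-mean provenance** is always explicit. `evaluate_worksheet()`
  accepts a constant, a per-type table, or computes the means from the
  records at hand; which cohort a mean came from is the analyst's decision,
  never inferred, because deviations are only meaningful against a stated
  baseline.

## Worked example

The bundled ten-plaque EP917 worksheet, evaluated against the established
cohort mean factor of 0.353:

```{r example}
ws <- example_data("worksheet")
ev <- evaluate_worksheet(ws, group_mean_factor = 0.353)
tidy(ev)[, c("plaque_id", "measured_strength_u", "decayed_strength_u",
             "cal_factor", "deviation_pct", "flag_action_limit")]
glance(ev)
```

One plaque sits at +5.9% and is flagged; the rest are within ±4.4%. Rounding
to the printed precisions (2 dp for strengths, 3 dp for factors, 1 dp for
deviations) happens only in `write_worksheet()`; all arithmetic upstream is
double precision. The 1-dp deviations of a historical worksheet computed
with intermediate rounding can differ from the full-precision pipeline by
up to 0.1 percentage point — that is the reproduction tolerance used in the
package's own tests, not an uncertainty claim about the method.

## Seed-position uniformity

Two measurement designs quantify each slot's share of a loaded plaque's
activity: placing a single seed in each position in turn
(`contributions_from_placements()`, fractions sum to one by construction),
and removing one seed at a time from a full plaque
(`contributions_from_removals()`, differences of two noisy totals, with
optional renormalisation). On three EP917 plaques the per-position averages
cluster at 1/17 ≈ 5.9% with a standard deviation across positions of 0.3
percentage points:

```{r seeds}
su <- seed_contribution_analysis(example_data("seed_contribution"))
glance(su)
```

This near-uniformity is what justifies applying the fully-loaded calibration
factor to partially loaded plaques. Per-position averages are unweighted
means of the per-plaque percentages, and the summary sd is taken over the
17 per-position averages, not over all 51 raw fractions — the convention
that matches how such tables are reported.

## Per-type statistics

`group_statistics()` uses the sample (n−1) standard deviation and reports
the coefficient of variation CV = 100·sd/mean; a single-plaque group has a
mean but no sd. `pooled_statistics()` reports both pooling conventions
side by side, because "the mean COMS factor" can mean the plaque-weighted
pooled mean (CV ≈ 4.8% when all COMS types are pooled) while "the average
CV" conventionally means the unweighted mean of per-type CVs (2.7% for the
eleven COMS types) — grouping by type is what makes the verification
tighter.

## What the simulator emulates

`simulate_records()` draws each plaque's true factor from a normal
distribution with the type's mean and CV (EP917: 0.353, 3.29%; COMS types:
their published per-type values), synthesises an assay certificate, decays
it to a measurement date, and generates four angle readings with independent
multiplicative lognormal noise. The noise scale (`reading_noise_sd = 0.01`)
was chosen once so the four-reading spread is typically around 2%,
consistent with a carefully centred plaque staying under the 4% limit. The
normal factor model is an assumption adopted for its closed-form
false-positive rate, not an empirical claim.

Two consequences worth keeping in mind:

* The evaluated factor's dispersion is the type CV plus the
  mean-of-four-readings noise in quadrature,
  $CV_\text{eff} = \sqrt{CV^2 + (100\,\sigma)^2/4} \approx 3.33\%$ at the
  defaults, so the expected clean false-positive rate at the 5% limit is
  $2(1-\Phi(5/CV_\text{eff})) \approx 13.3\%$, slightly above the 12.9%
  obtained from the type CV alone (`false_positive_rate_normal()`).
  That rate is per the action limit's design: it flags statistical outliers
  liberally and leaves disposition to human investigation.
* What the simulator does **not** model: calibrator geometry, plaque
  collimation physics, inter-session drift, operator repositioning after a
  spread violation, or correlated errors across a seed lot. Passing
  simulation-based tests therefore demonstrates the arithmetic and flag
  logic, not the physical measurement protocol.

`inject_error()` corrupts clean records with the four error kinds the
method is meant to catch — unit confusion (×1/0.787), adjacent-digit
transcription swaps, a wrong plaque type, and a uniform activity mismatch
(default −6.8%, the worst case a clinic reported) — and
`sensitivity_study()` tabulates detection and false-positive rates against
ground truth. Unit confusion (a 27% shift) is detected with probability 1
at the 5% limit; a −6.8% mismatch is detected with probability ≈ 0.71 under
the default EP917 dispersion, which is why flagged plaques are remeasured
rather than automatically condemned.

## Numerical and design choices

* Decay uses exact powers of two over signed whole-day intervals; the
  identity at Δt = 0 holds bit-exactly and composition over split intervals
  holds to 1e−9 relative, which the tests assert.
* Dates parse month-first (`9/16/2011`) by default, matching clinical
  worksheets; ISO-8601 is accepted everywhere and day-first is a flag.
* All-zero angle readings are rejected (spread undefined); a removed-seed
  total at or above the full-plaque total is rejected as a measurement
  error rather than clamped.
* Capacity checks (e.g. 17 slots for the EP917; COMS capacities shipped as
  an editable table spanning 5–24 seeds) warn and name the offending row
  and column; they never abort a batch, since partially loaded plaques are
  routine.
* Test and acceptance problem sizes — cohorts of 1 000–10 000 simulated
  records — were chosen so Monte-Carlo error is small against the effects
  being checked while the whole suite runs in seconds.

## Limitations

The package verifies source strength bookkeeping; it performs no dose
calculation (TG-43 or otherwise), no radiation-transport modelling of the
plaque, and no automated adjudication of whether a flagged plaque is a
statistical outlier or a true error. Whole-day decay intervals are
appropriate for a 59.4-day half-life; sub-day timing effects (< 0.05%) are
ignored.
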