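---
title: "Methods: adherence scoring, trial statistics and cost-utility analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adherence scoring, trial statistics and cost-utility analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compadhere)
```

## The problem

Daily wear of medically prescribed compression stockings is the mainstay of
venous leg ulcer (VLU) prevention in chronic venous insufficiency, but
adherence is poor and the barriers are patient-specific: heat, donning
difficulty, skin irritation, appearance, mood. `compadhere` implements the
full analysis pipeline for a two-arm randomised trial of a multidimensional
adherence intervention (a barrier questionnaire, a top-three barrier
selection algorithm, and barrier-tailored resources — the PAMCAI family of
decision aids), together with a synthetic cohort generator so that every
stage is testable without patient data.

All user-facing functions take a data frame first and return tibbles; a
cohort is one wide tibble, one row per participant, with `baseline_` /
`followup_` measurement blocks (see `cohort_dictionary()`).

## Adherence scoring

**Percentage of waking hours.** For each leg,
$\mathrm{pct} = \frac{\text{hours worn}}{\text{hours awake}} \times
\frac{\text{days per week}}{7} \times 100$, clamped to $[0, 100]$, and the
legs with a report are averaged. Self-reports are often *ranges*
("12–14 hours"). The range rules in the source protocol are only partly
operational (the stated rule for multiple ranges — use "the widest range" —
does not pick a scalar), so two resolution modes are provided:

* `"conservative"` (default): worn hours and days at their **lower** bounds,
  hours awake at its **upper** bound. This extends the protocol's one
  explicit rule (lowest number of days) to all intervals and biases the
  estimate downward in a known direction.
* `"midpoint"`: interval midpoints, the alternative the trial team itself
  suggested in hindsight.

Alongside the point estimate, `adherence_percentage()` always reports the
attainable `[pct_min, pct_max]` envelope over all bound orientations so the
sensitivity to the range rules is auditable. Worn hours exceeding awake
hours (self-report noise) are clamped to awake hours with a warning rather
than producing >100%.

**Modified Q10.** The VCSS compression-compliance item (Q10: 0 none, 1
intermittent, 2 most days, 3 fully comply) is quantified by banding the
percentage: 0 = 1–10%, 1 = 11–50%, 2 = 51–90%, 3 = 91–100%. The percentage
is rounded half-up to an integer before banding (so band edges are
unambiguous), and 0% is assigned to category 0, making the banding a total
function on $[0, 100]$ even though the printed bottom band starts at 1%.
The clinician-assigned *unmodified* Q10 is an input carried through, never
derived.

**Barrier resolution.** Each recorded barrier is scored 1–4 from its
addressed/resolved status (1 = neither, 2 = resolved without being
addressed, 3 = addressed but unresolved, 4 = both); a participant's Mean
Barrier Resolution Score is the mean over their active barriers (the mean,
not the sum, adjusts for participants with fewer than three barriers), and
is reported to 2 decimals as in the source tables.

## The decision-aid engine

The eligibility screen sums five 0–4 items with a *strict* threshold
(total > 3). Barrier selection sorts severities (Likert 1–5, used raw — no
reweighting, since none is specified) and returns the top three. When more
than three barriers share the cutoff weight, the selection is in principle
a clinician-discretion point; for reproducibility the engine breaks ties by
ascending barrier id and sets `tie_flag` so the discretion point stays
visible. The display contract is unordered even though a deterministic
internal order is kept. Resource recommendation is a pure lookup in a
configurable barrier-to-resource map (YAML); resource *content* is out of
scope.

Only some of the 24 catalogue item texts are public; the catalogue ships
the named items plus explicit placeholders so every id 1–24 is covered.

## Trial statistics

* **Mann–Whitney U** (primary adherence comparisons): midrank U; exact
  two-sided p by full enumeration of all $\binom{n_1+n_2}{n_1}$ assignments
  (doubling the smaller tail, capped at 1) for untied samples with
  $n_1+n_2 \le 20$; otherwise the normal approximation with tie and
  continuity correction — the realistic path, since ordinal change scores
  are heavily tied. Exact-with-ties enumeration exists only as a test
  oracle and via the explicit `exact = TRUE` override.
* **Somers' D** (association between barrier resolution and modified-Q10
  change): $D_{Y|X} = (C - D) / (\text{pairs untied on } X)$, counted on
  the contingency table. The p-value is a two-sided asymptotic z-test of
  $C - D$ under the null of no association, using the tie-corrected null
  variance (the same variance used by tie-corrected Kendall tests). The
  source names no variance formula; the null-variance choice is the
  conventional one for a test of association.
* **Baseline-adjusted group effect** (secondary outcomes, and the CUA's
  incremental QALY): OLS of the change score on arm + baseline value,
  `usual_care` as reference. Whether the original analysis modelled the
  change score or the follow-up value is not recoverable; change-score-on-
  baseline is implemented and documented as the adopted reading.
* **Sample size**: smallest integer per-group n whose exact noncentral-t
  power (ncp $(\delta/\sigma)\sqrt{n/2}$, df $2n-2$) reaches the target,
  floored at 2 for variance estimability; dropout inflates the total by
  $1/(1-r)$ rounded up to the next *even* integer to keep arms balanced
  (44 at $\delta = 1$, $\sigma = 1.14$ becomes 56 at 20% dropout). The
  Mann–Whitney plan divides the per-group n by an asymptotic relative
  efficiency and rounds up; the default ARE is 0.864, the distribution-free
  minimum, because the parent distribution is unspecified.

## Cost-utility analysis

Health-service perspective, one-year horizon, no discounting (horizon ≤ 1
year). Per-participant costs are appointment counts times unit prices
(defaults AUD 193 face-to-face, 177 phone) plus materials (unit costs
carried in the record, with a catalogue fallback by item label). QALYs are
the area under the utility-time curve: trapezoid from baseline to 6 months,
then the 6-month value carried flat to 12 months
($\mathrm{QALY} = \tfrac12 \cdot \tfrac{u_0+u_6}{2} + \tfrac12 u_6$). The
source says only "extrapolated to 1 year"; last-observation-carried-forward
is the default and a linear-trend continuation is available as
`extrapolation = "linear"`. A missing 6-month utility carries baseline
forward (flagged); a missing baseline excludes the participant with a
warning.

The incremental QALY is the arm coefficient of OLS on arm + baseline
utility — the standard reading of "baseline disparity accounted for using
univariate regression", and deliberately distinct from the raw per-arm QALY
difference (both are reported). The ICER is
$\Delta\text{cost}/\Delta\text{QALY}_{\text{adj}}$, defined only in the
trade-off quadrants; dominance is classified from the signs of the
increments, and cost-effectiveness is `dominant`, or north-east trade-off
with ICER at or below the willingness-to-pay threshold (default AUD 28,033
per QALY). If the baseline-utility adjustment is unavailable (degenerate
cohort with constant baseline), the analysis falls back to the raw
difference with a warning. Currency is reported at 2 decimals; full
precision is kept internally.

## The synthetic cohort generator

`pilot_config()` encodes the pilot's published world: per-arm baseline
adherence 52.09 (SD 11.74) vs 19.51 (7.23) percent of waking hours, mean
changes −24.82 (37.42) vs +38.574 (23.47); barrier counts averaging
2.8 vs 2.5 per participant; barrier outcomes with per-arm Bernoulli
probabilities reconstructed from the pooled counts (usual care 8/28
addressed and 1/8 of those resolved; intervention 25/25 addressed, 18/25
resolved; nothing resolves unaddressed in either arm); utilities 0.70
(0.34) vs 0.59 (0.42) changing by −0.054 (0.19) vs +0.17 (0.30); Poisson
appointment counts with means 1.9/0.5 vs 2.89/1.22 (face-to-face/phone) and
uniform materials costs with means 202.36 vs 323.81 AUD. Wear reports are
back-solved through the adherence formula (16 h awake, 7 days/week, worn
hours = pct/100 × 16 on both legs), which makes the generator invertible
through the scorer.

**Mean-calibrated truncated sampling.** Percentages live in $[0, 100]$ and
utilities in $[-0.6, 1]$, so draws must be truncated — but plain truncation
shifts the realised mean away from the configured one (for a normal with
mean 27 and SD 37 floored at 0, by more than 12 points), and the configured
values *are* the pilot's realised moments. The sampler therefore solves for
the pre-truncation location at which the truncated distribution's mean
equals the configured value (the truncated mean is strictly increasing in
the location with range the open interval between the bounds, so any
interior target is attainable). Follow-up values are baseline + change with
per-participant bounds keeping the follow-up in range; there a single
arm-level location offset is solved so the *expected arm mean* of realised
changes equals the configured change mean exactly — individual participants
near a bound keep their realistic ceiling/floor compression, but arm-level
parameter recovery is exact in expectation. Sampling is by inverse CDF
(exactly n uniforms per vector), so a cohort is a deterministic function of
the config and seed.

What the generator does *not* emulate: correlation between baseline
adherence and barrier count (unreported; independence assumed), clinician
drift between the modified and unmodified Q10 (the generated clinician
score is the band of the true percentage), VLU recurrence events (none
occurred), within-participant correlation across the quality-of-life
instruments, and missingness (cohorts are complete by default; missing
follow-up blocks are a first-class input to the pipeline and are exercised
in tests by blanking blocks). A green parameter-recovery test therefore
establishes that the pipeline recovers the moments the generator encodes —
not that real data obey them.

Secondary instruments not in the generator config (VCSS items 1–9, CIVIQ-14
and VAS trajectories) use fixed defaults chosen once to land in the pilot's
printed ranges; they exist to exercise the reporting surface, not as
calibration targets.

## Numerical and design choices

* Rounding is half-up (`round_half_up()`), not banker's, wherever the
  source prints rounded values (percentage banding, 2-dp scores and
  percentages).
* Interval serialization is `"lo-hi"` with degenerate intervals collapsed,
  decimal point only; missingness is the literal `NA` token, so a withdrawn
  participant's blank follow-up block is distinguishable from zeros.
* The Mann–Whitney two-sided exact p doubles the smaller tail (capped at
  1), matching the convention of standard exact implementations.
* The arm factor is fixed to `usual_care` reference / `intervention`
  treatment, so every "difference" in the package is intervention minus
  usual care.
* Pipeline tables never re-implement statistics: `run_pipeline()` calls the
  same exported functions users call, and a test asserts the equality.

## Known limitations

* The per-arm QALY means printed in the source's economic table are not
  reproducible from its printed group-level utilities because effective ns
  differ across timepoints; the package reports per-participant QALYs and
  their arm means instead of matching those two cells.
* The exact regression specification behind the source's adjusted
  incremental QALY of 0.125 is not recoverable; OLS of QALY on arm +
  baseline utility is one admissible reading and is documented as such.
* The headline ordinal association (Somers' D = 0.471) and the primary
  Mann–Whitney p = 0.002 require individual-level intervention-arm data
  that are unpublished; the package's correctness for these statistics is
  established by property tests against brute-force oracles instead.
* Eligibility screening data (the five-item screen) are not part of the
  cohort file; the screen is exposed as a standalone function.
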