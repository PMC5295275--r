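---
title: "Methods: dose modelling with Environmental Justice indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose modelling with Environmental Justice indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ejadd)
```

## The model

The package estimates chemical exposure dose with the Average Daily Dose
model,

$$\mathrm{ADD} = \frac{C \times IR \times EF \times conv}{BW},$$

in mg per kg body weight per day. `C` is the ambient concentration of the
contaminant (µg/m³ for air, mg/kg for soil or dust), `IR` the daily intake
of the medium (m³ of air inhaled or mg of soil ingested), `EF` the
dimensionless fraction of time in contact with the medium (contact hours
divided by averaging hours), `BW` body weight in kg, and `conv` a
unit-conversion multiplier on the `C × IR` product.

The model is linked to two tract-level Environmental Justice indicators.
Each indicator is a population fraction — the share of non-white residents,
and the share of residents whose income-to-poverty ratio is strictly below
1.5 — binned evenly over $[0, 1]$ into integer scores 1 to 10. Score 1
marks the least-burdened tracts, score 10 the most-burdened. Tract doses
are then stratified by score (singly, or over all 100 score pairs), and
the unweighted arithmetic mean dose per stratum is the quantity reported.

Mixtures are handled by dose additivity: each component dose is scaled to
index-chemical equivalents by its Relative Potency Factor — the ratio of
its inhalation unit risk to the index chemical's — and summed. The packaged
configuration uses benzene as index (unit risk taken as the midpoint,
5 × 10⁻⁶ per µg/m³, of its published 2.2 × 10⁻⁶–7.8 × 10⁻⁶ range), giving
RPF 6 for 1,3-butadiene and 0.44 for acetaldehyde. Additivity is an
explicit simplification: no chemical–chemical interaction is modelled.

## Parameters that matter

| parameter | units | default | rationale |
|---|---|---|---|
| `exposure_factor` | fraction | 1 | tract residents treated as constantly exposed to ambient air; community scenarios override it |
| `unit_conversion` | — | 1e-3 | µg→mg for inhalation; also the convention under which the packaged soil-ingestion scenario doses are reported (see below) |
| `open_ended_value` | years | 90 | representative age of the open-ended 60+ census group |
| `age_mode` | — | `"pooled"` | one national pooled age selects a single body-weight/intake pair for all tracts; `"per_tract"` uses each tract's own weighted age |
| `max_poverty_score` | score | 7 | strata with poverty score above 7 hold few tracts and are excluded from reporting (kept in an audit attribute) |
| `min_n` | tracts | 1 | empty strata are never reported as doses |
| poverty threshold | ratio | 1.5 | income below 1.5× the poverty level, strict inequality |

The unit-conversion choice deserves a note. For soil ingestion the
physically standard conversion of `C` (mg/kg soil) times `IR` (mg soil/day)
into mg/day is 10⁻⁶ (mg of soil to kg of soil). The packaged community
scenarios instead fix `conv = 1e-3`, because that is the convention under
which their reference doses are quoted; it is an explicit field of every
scenario, never implicit, and users working in strict SI can set 10⁻⁶.

Display rounding follows the dose-table convention `dose_display()`: three
significant figures in scientific notation below 0.1 mg/kg-day, two decimal
places above (3.91 × 10⁻⁴, 9.10 × 10⁻³, 0.23, 5.06). Ratios between
scenario doses are reported both ways — from display-rounded doses (the
convention under which such ratios are usually quoted, giving 12,941 for
the EJ/wealthiest pair) and from full-precision doses (12,952). CSV output
is always full precision; rounding is display-only.

## Age, body weight and intake rate

Grouped census age data (shares per interval and sex) reduce to a weighted
average age: interval midpoints weighted by shares, with the open-ended
group at `open_ended_value`. The pooled national age is the mean over sexes
of the per-sex tract means — the nesting matters when sexes have unequal
tract counts. That age indexes an exposure-factor lookup table of
half-open age intervals `[lower, upper)` mapping to a body weight and
daily intake rate. The packaged table is an illustrative synthetic stand-in
with plausible inhalation values (adult 80 kg, 19 m³/day at the 95th
percentile level), not a reproduction of any handbook; analyses that need
authoritative values should supply their own CSV, which
`validate_ef_table()` checks for gaps, overlaps and non-positive entries.

Whether the score-stratified analysis should use one pooled national age or
each tract's own age is genuinely open; the pooled mode is the default
because a single national body-weight/intake pair matches the narrative of
a nationwide screening exercise, and `age_mode = "per_tract"` is provided
for the alternative reading. With identical demographics the two modes
coincide, which the tests exploit.

## Numerical choices and degenerate inputs

- Score bins are half-open $[(k-1)/10,\, k/10)$ with the top bin closed at
  1.0: total coverage of $[0, 1]$, no overlap, and a fraction of exactly
  1.0 scores 10. Binning operates on the stored double values.
- "Below 1.5" is a strict inequality; a ratio of exactly 1.5 is not poor.
- Empty surface cells are `NA`, never 0 — zero is a valid dose. The count
  grid is always fully populated, and a cell is `NA` exactly when its
  count is 0.
- The mean per stratum is the unweighted arithmetic mean over tracts, not
  population-weighted.
- Age-share vectors must sum to 1 within 1e-6; per-tract mode drops tracts
  with invalid age data (with a warning naming them) rather than failing
  the run. The file reader likewise rejects invalid rows by line number
  and continues.
- In the generator, fractions produced by the logit link are clipped to
  $[0, 1]$ rather than resampled (simple and deterministic); the clip
  count is recorded as an attribute.
- Mixture layers must start with the index chemical; any chemical without
  an RPF is a hard error, never silently dropped.

## What the synthetic generator emulates

`simulate_tracts()` is the package's stand-in for joined national
air-toxics and census data. Its defaults define the reference conditions
used throughout the tests: the non-white fraction is Beta(2, 3.5)
(right-skewed, mean ≈ 0.36, as tract-level race fractions are); the
poverty fraction follows a logit-linear link,
$\mathrm{logit}(p) = -0.8 + 0.9\,\mathrm{logit}(r) + \varepsilon$,
$\varepsilon \sim N(0, 0.6)$, reflecting the well-documented positive
association between the two indicators without asserting a particular
real-world joint distribution; and each of six pollutants (acetaldehyde,
benzene, cyanide, toluene, 1,3-butadiene, diesel PM — the vehicular and
industrial emission set) is lognormal with log-mean rising in both
fractions (race effects 0.9–1.3, poverty effects 0.5–0.7 per unit
fraction, log-noise sd 0.25). Grouped age distributions jitter around a
near-national template (sd 0.02) and renormalize. Everything is
deterministic given the seed, and the output schema is identical to the
tract CSV the reader accepts, so synthetic and real data are
interchangeable downstream.

The generator does **not** emulate spatial autocorrelation, the heavy
upper tails and censoring patterns of modelled concentration fields,
population-size heterogeneity across tracts, or missing-data structure.
Consequently the passing trend tests establish that the pipeline
*recovers* a positive dose–score gradient when one exists and reports
*no* gradient when none exists — they say nothing about which gradients
real national data contain, and published percent-increase figures from
real releases are deliberately not asserted anywhere.

## Problem sizes and verification strategy

Grouped means and surfaces are verified exactly (tolerance zero) against
an independent brute-force accumulation on datasets of up to 100 tracts.
Trend recovery uses 5,000 synthetic tracts under fixed seeds: with the
default positive effects, mean ADD is strictly increasing over scores 1–7
for every chemical and both indicators; with effects set to zero, the
fitted slope of stratum mean against score stays below 10% of the grand
mean over the score span. Those sizes keep the full suite under half a
minute while leaving the stratum means' sampling error well inside the
margins the assertions need.

## Limitations

- Dose additivity for mixtures ignores interactions; other potency bases
  than inhalation unit risk would change the RPFs.
- The analysis is descriptive — stratum means with no inference — and
  tract-level aggregation cannot speak to individual-level exposure.
- An exposure factor of 1 for every tract is conservative and uniform;
  burden-differentiated exposure factors are plausible but need data the
  tract schema does not yet carry.
- The packaged exposure-factor table is illustrative; substantive analyses
  must supply authoritative body-weight and intake values.
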