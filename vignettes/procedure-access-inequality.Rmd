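---
title: "Measuring geographic inequality in inpatient-procedure access"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring geographic inequality in inpatient-procedure access}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Whether a patient can obtain an inpatient procedure depends in part on
where they live: some procedures are offered by nearly every hospital,
others by a small set of specialized centers. Comparing that inequality
*across* procedures is confounded by epidemiology — a procedure treating a
condition of the elderly will legitimately cluster in areas with older
populations. The Procedure Access Inequality (PAI) index implemented here
separates the two: it measures how unequally a procedure's recipients are
distributed across residential zip codes *relative to* an age–sex-adjusted
expected-utilization baseline, so that differences in underlying disease
burden are absorbed by the baseline and the residual reflects access,
capacity, and offering decisions.

## The model

For a procedure category and year, let $o_z$ be the share of recipients
residing in zip $z$ (over the full zip universe of the population table,
zips with no recipients included at share 0), and let $r_z$ be the
baseline share obtained by indirect standardization: population-wide
stratum rates $\lambda_{a,s}$ (events per person per year by age band
$a$ and sex $s$) applied to each zip's stratum populations,

$$E_z = \sum_{a,s} P_{z,a,s}\,\lambda_{a,s}, \qquad
  r_z = E_z \Big/ \sum_{z'} E_{z'}.$$

Dispersion is summarized by share concentration (the Simpson/Herfindahl
form on shares), $D(v) = \sum_z v_z^2$, which is $1/K$ for a uniform
distribution over $K$ zips and exactly 1 for a point mass. The index is
the normalized gap between realized and baseline dispersion:

$$\mathrm{PAI} \;=\; \frac{D(o) - D(r)}{1 - D(r)}.$$

By construction PAI $= 0$ when the procedure is distributed exactly like
the baseline ("perfect equality"), PAI $= 1$ if and only if every
recipient lives in a single zip code ("perfect inequality"), and PAI can
dip below 0 when the observed distribution is *more* uniform than the
baseline — a regime that real data do exhibit (obstetric procedures are
the canonical example).

**Why this functional.** The defining properties of the index (its
endpoints and the gap-between-dispersions construction) do not pin down
a unique dispersion functional, so the functional is a pluggable design
decision here. Share concentration is the default because it satisfies
every property the index must have — zero at the baseline, one at a
single zip, sub-zero possible — with a one-line closed form that admits an
independent brute-force oracle in the tests. Two reference-relative
alternatives (`gini_vs_reference`, a concentration-curve Gini, and
`theil_vs_reference`, the Kullback–Leibler/Theil divergence) are
selectable via `pai_config(functional = ...)`; for these the baseline
dispersion is 0 by construction and the normalization ceiling is the
largest value attainable by a single-zip point mass. Every result row
records the functional and reference mode used.

Market concentration is measured per category by the
Herfindahl–Hirschman Index on squared percent market shares of
hospitals, $\mathrm{HHI} = \sum_h s_h^2$ with $s_h$ in percent: equal
volumes across 40 hospitals give exactly 250, across 80 hospitals 125,
and a monopoly 10 000.

## Tunable parameters

* **Age bands** (default `0-17, 18-44, 45-64, 65-74, 75+`): the
  stratification of both population denominators and encounter ages.
  Configurable because sources differ; bands must be contiguous.
* **`reference_mode`** (default `all_hospitalizations`): the baseline's
  stratum rates come from *all* encounters of the year, matching the
  stated PAI = 0 condition (distributed like all hospitalizations).
  `category_specific` standardizes on the category's own rates — a closer
  prevalence proxy for strongly age-graded procedures — with an optional
  `min_stratum_events` fallback to pooled rates in sparse strata. Neither
  variant is privileged; both are first-class and recorded in the output.
* **`min_volume`** (default 1): smallest encounter count for which a
  (category, year) is scored; smaller cells are skipped and logged.
* **`bias_correct`** (default off): finite-sample correction
  $(D - 1/n)/(1 - 1/n)$ applied to both dispersions. Off by default:
  the uncorrected index is the defined quantity, and sub-zero scores on
  real data indicate that small-sample bias is part of the statistic as
  reported in practice.
* **Tercile split**: categories ranked by PAI are partitioned with sizes
  differing by at most one and remainders assigned to the lower
  terciles, which reproduces the 119/119/118 split of 356 categories.
* **Top-vs-bottom p-values**: Welch (unequal-variance) two-sample
  t-test, the conservative default when the underlying test is not
  named. Categories are the unit of analysis (patient-level
  characteristics are first averaged within category). With no
  within-group variance at either extreme the p-value is 1 when means
  agree, 0 otherwise; groups too small to test give NA.
* **Longitudinal fit**: the change analysis regresses the *level* change
  in PAI on the *percent* change in hospital count by default
  (`response = "delta"`), since the headline effect ("a 10% increase in
  hospitals ... a 0.035 reduction") is in index units; the
  percent-change response is available via `response = "percent"`.

## What the synthetic generator emulates

`simulate_encounters()` produces the three pipeline inputs with full
ground truth. The stated world: zips placed uniformly on a unit square
with log-normal populations (median 10 000, sigma 1 — the right order of
heterogeneity for US zip codes), split across strata by a fixed national
age–sex profile; per-category stratum rates with a rising age gradient
(log-normal base near 2 × 10⁻⁴ events/person-year, so a category yields
thousands of encounters per year at this scale); each category offered by
a fraction of hospitals; zip-stratum demand Poisson with mean
`population × rate × exp(-access_decay × distance)` to the nearest
offering hospital, suppressed demand being *lost* (forgone care), not
redistributed; patients assigned to the nearest offering hospital.
`offering_growth` optionally grows nested offering sets over years,
emulating the staged roll-out of a new technology across hospitals —
that is what makes longitudinal hospital counts move at all.

Because every zip shares the national age–sex profile, the baseline
reduces to population shares, and with `access_decay = 0` and full
offering the observed distribution matches it in expectation: the null
world, under which PAI should approach 0 as volume grows (the tests
assert |PAI| < 0.02 at 50 000 encounters and a decreasing |PAI| across
n = 10³–10⁵). The mechanism-recovery tests fix the gating strength at
`access_decay = 8` — on a unit square this makes demand fall by ~55% per
0.1 of distance, a strong but not degenerate planted mechanism — and vary
only `offering_fraction`, asserting that mean PAI falls strictly as more
hospitals offer the procedure and that the fitted PAI-versus-hospital
slope is negative.

What a green test does **not** establish: the generator has no real
geography, no between-zip age-composition differences (so the
age-adjustment machinery is exercised by unit fixtures, not by the
simulator's null), no payer/race/cost realism beyond simple categorical
draws, and no correlation between offering sets and hospital size. Green
means the estimator recovers planted mechanisms in a world obeying its
assumptions, not that real discharge data would yield any particular
value.

## Numerical choices and degenerate inputs

* Share vectors must sum to 1 within 1e-9; all result CSVs round-trip
  doubles exactly.
* The zip universe per category-year is *all* zips of the population
  table; encounters with zips absent from it cannot be standardized and
  are excluded from shares (with a logged count) while remaining in
  volume counts.
* Zero-share zips contribute 0 to every functional; no pseudo-counts.
* A reference that is itself a point mass makes the normalization
  degenerate and is an error, as is an all-zero expected-count vector.
* Ties in the ranked table are broken by volume descending; tercile
  remainders go to the lower terciles.
* `theil_vs_reference` is undefined when observed mass sits on a
  zero-reference zip; this errors rather than flooring the reference.

## Known limitations

* Real multi-state discharge extracts and census denominators are
  restricted or external data; nothing here validates against them.
  The package's verification anchors are closed-form worked numbers
  (equal-volume HHI, percent-difference arithmetic, the tercile split),
  exact index properties against a brute-force oracle, and
  mechanism-recovery on the synthetic world.
* Markets are pooled across the whole data extent; no
  hospital-referral-region or state sub-markets.
* The bootstrap CI treats the reference as fixed and resamples
  encounters only.
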