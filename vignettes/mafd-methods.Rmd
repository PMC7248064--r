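---
title: "Methods: minimum adult frog density from calling-male counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: minimum adult frog density from calling-male counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mafd)
```

## The model

The package estimates adult anuran density from counts of simultaneously
calling males. Two quantities are chained:

**Calling-male density.** A plot's waterbodies are stratified into small
(< 0.5 ha), medium (0.5–10 ha) and large (> 10 ha) lentic waterbodies and
ditches. Small waterbodies lie entirely within an observer's hearing range
and are treated as interchangeable units; medium/large waterbodies and
ditches are treated as linear shoreline habitat of which only the stretch
within hearing range is effectively surveyed. Within each category the
counted males are scaled up by the ratio of total to surveyed habitat:

$$Dc = \frac{\sum_i C_i \, Pt_i / Ps_i}{S}$$

with $C_i$ the summed per-site best counts, $Pt_i$/$Ps_i$ total/surveyed
habitat, and $S$ the plot area (km²).

**Minimum adult density.** Counting calling males misses (i) males present
but silent, (ii) males absent from waterbodies, and (iii) females. At the
peak of breeding activity these losses are bounded by the taxon parameters
$Ma$ (proportion of present males vocalising at peak), $Mp$ (proportion of
the male population present in waterbodies at peak) and $Ms$ (male
proportion of the adult population), so

$$MAFD = \frac{Dc}{Ma \cdot Mp \cdot Ms}$$

is a *minimum* adult density: real surveys rarely hit the peak exactly, so
the correction typically undershoots. This one-sidedness is intentional —
for conservation reporting, overestimates are the costly error.

### Assumptions

* Density per habitat unit is homogeneous within a category on a plot
  (the basis of the $Pt/Ps$ extrapolation); surveyed sites are a random
  subset of each stratum.
* The published $Ma$, $Mp$, $Ms$ averages transfer to the surveyed
  populations. On a large multi-site survey this holds on average even if
  individual sites deviate.
* Counts from different years are never pooled: whole choruses move
  between neighbouring waterbodies across years, so each year is a
  separate snapshot and only the best year is used.

## Parameters

`default_taxon_parameters()` ships the per-taxon values: $Ma$, $Mp$, $Ms$
(with SDs where several published estimates exist), minimum hearing
distances (500 m *Pelophylax*/*Hyla*, 150 m *B. bufo*, 100 m
*R. arvalis*/*B. bombina*, 50 m *R. temporaria*/*P. fuscus*), range areas
and plot-presence fractions. Three conventions matter:

* **Sex ratios are population ratios.** Operational sex ratios observed at
  breeding sites of terrestrial taxa overstate the male share; published
  operational proportions were reduced by 15% before being tabled.
  `adjust_operational_sex_ratio()` applies the same reduction for users
  supplying their own ratios; it is *not* applied to the shipped values.
* **Water-frog complex.** *Pelophylax* sex ratios differ between the two
  parental/hybrid forms, which sort by waterbody size: the *P. lessonae*
  ratio (0.47) applies to small waterbodies and ditches, *P. esculentus*
  (0.36) to large ones, their mean to medium ones. `compute_mafd()`
  therefore requires per-category densities for this taxon.
* **Category boundaries.** The published size intervals touch at 0.5 and
  10 ha; the implementation uses [0, 0.5) small, [0.5, 10] medium,
  (10, ∞) large, matching the verbatim "less than 0.5 ha" and assigning
  both touchpoints to medium.

### Sampled shoreline length

The field protocol measured audible shoreline by GPS but published no
formula. The default rule in `sampled_length()` is
`min(total, 2 × hearing distance × listening points)` — an observer at a
listening point hears along the shoreline in both directions — and any
explicit `sampled_length_m` measurement overrides it. A stratum with
habitat but no surveyed habitat and no counts contributes zero with a
warning (extrapolating from nothing would be undefined; zero is the
conservative minimum-density choice).

## Survey-quality metrics

* **WDP** — of the waterbodies with *any* evidence of adult presence
  (audial, or visual: adults, spawn, tadpoles, metamorphs), the fraction
  detected audially. Evidence types are unweighted. Computed per plot per
  year (default the best year; a flag pools years — the published
  convention is not explicit on this point).
* **IYF** — of the waterbodies call-positive in any year, the fraction
  call-positive in the best year. Defined only for plots with ≥ 2 survey
  years. True breeding-site shifts and detection failures are conflated,
  deliberately.
* **CMPS** — best single-survey plot total divided by the year's total
  score. The denominator is the sum over sites of per-site maxima (the
  same year score used everywhere else), *not* the sum over surveys: the
  best survey is usually best for only part of the sites, and this reading
  keeps CMPS ≤ 1.
* Best-year ties break to the earliest year (determinism; the choice is
  otherwise arbitrary).

## Visual correction

Visual observations bound how much the acoustic estimate misses.
Adults seen are divided by a visibility-class detection probability
(0.75 / 0.50 / 0.20 / 0.10); unknown-sex observations are multiplied by
$Ms$. Egg masses are divided by 0.90, read as one mass = one breeding
female, and converted to males via $Ms/(1-Ms)$. When both components exist
at a site the **maximum** is used, not the sum: both are noisy views of
the same male pool and summing would double-count (a `combine = "sum"`
switch exists). Estimated present males become virtual calling males via
$Ma$, and each site's count is raised to `max(recorded, virtual)` — the
correction can only add males that were missed, never remove heard ones.
Re-running the density chain gives $NDE \ge MAFD$ and the coverage
fraction $MAFD/NDE$. The comparison is only reported where visual checks
covered ≥ 75% of the plot's surveyed waterbodies.

## Range-wide extrapolation and uncertainty

`estimate_state()` multiplies the median plot MAFD by the fraction of
plots with the taxon present and the range area. Medians damp both
low-activity underestimates and overestimated chorus sizes. The shipped
reference inputs use presence fraction 1.0 for the two range-restricted
taxa (*B. bombina*, 470 km²; *H. arborea*, 4 000 km²), which were present
in every plot inside their ranges.

The published ± values state no method; the package provides two and
reports which was used. The default Monte-Carlo resamples $Ma$, $Mp$, $Ms$
from normals truncated to (0, 1] and rescales the estimate by the ratio of
point to resampled parameter product; the delta method uses first-order
propagation, $sd = N\sqrt{\sum_i (\sigma_i/\mu_i)^2}$. For *Pelophylax*
the small-waterbody ratio (0.47 ± 0.14) enters the uncertainty, since
small waterbodies carry > 70% of that taxon's density. Two numerical
caveats:

* For relative SDs ≲ 0.15 the two methods agree within ~10%; this is
  tested.
* For large relative SDs (the *Pelophylax* 0.30) the reciprocal of a
  truncated normal is heavy-tailed near zero — its variance formally
  diverges — so the Monte-Carlo SD is large and unstable across seeds.
  This is a property of the model, not a bug; the delta value is the more
  interpretable summary there, and neither is an acceptance-grade output.

## The synthetic world

`simulate_dataset()` is the generative mirror of the estimator: adults are
allocated to waterbodies proportionally to habitat (one small pond ≈
400 m of shoreline), then `males ~ Bin(adults, Ms)`, per survey
`present ~ Bin(males, Mp·activity(date))`,
`calling ~ Bin(present, Ma·daily)`, and for linear habitat only the
audible fraction `2·hearing/length` is counted. Because MAFD inverts
exactly this thinning, parameter recovery is a fair test of the estimator
rather than of the generator. Seasonal activity is a Gaussian around the
peak for lek breeders and a fast-rise/exponential-decay curve for
explosive breeders, with per-site peak offsets
(`site_asynchrony_sd`) emulating populations breeding at different times —
this is what drives the lek > explosive contrast in CMPS. Inter-year site
fidelity `phi` keeps each waterbody's adults with probability φ and
reallocates the rest, making mean IYF increase with φ.

Defaults state a realistic world: 25 km² plots, ~60 small / 5 medium /
1 large waterbody and ~6 ditch segments per plot, surveyed fractions
0.27 / 0.49 / 0.57 (and 0.5 for ditches), three surveys per season, true
density 30 adults/km². What it does **not** emulate: weather-driven
activity, observer heterogeneity, acoustic masking in dense choruses,
double counting across adjacent sites. A green recovery test therefore
establishes correctness of the estimator arithmetic under the model's own
assumptions, not robustness to these field realities.

### The best-count maximum bias

The estimator uses each site's *maximum* count over repeated surveys.
A maximum over several binomial draws exceeds a single draw in
expectation, so with several surveys near peak activity and small
choruses, MAFD can *overshoot* the true density (with the default
three-survey schedule the overshoot is ~15% at 30 adults/km²). The
minimum-estimate property "E[MAFD] ≤ truth" therefore holds when the
activity deficit dominates the maximum bias — guaranteed for schedules
whose peak activity is ≲ 0.6, which is how the property is tested. The
unbiasedness test uses a single survey exactly at peak, where MAFD is the
exact inverse of the generative thinning. Both regimes are properties of
the published best-count rule itself, worth knowing when interpreting
field MAFD values: they are minimum estimates *given* imperfect timing,
not unconditionally.

## Reproducing the published arithmetic

The worked example reproduces exactly: mean Dc 4.1 for *B. bombina* with
0.61 × 1.00 × 0.56 gives MAFD 12.0. All seven nationwide estimates
reproduce from the published medians, presence fractions and range areas
(157 thousand *P. fuscus* … 1.62 million *B. bufo*). Two published
inconsistencies are asserted as such rather than hidden:

* *P. fuscus*: printed mean Dc 2.1 with the tabled parameters gives 20.3,
  not the printed 17.0 (consistent with an unreduced Ms ≈ 0.65).
* Both *Rana* species fail the same consistency check beyond rounding
  slack (computed 52.6 vs printed 51.7; 38.0 vs 36.4 — the latter
  consistent with Mp ≈ 1.0 instead of 0.95). The corresponding acceptance
  test is deliberately left failing for these taxa; the package
  implements the stated formula, not the unstated deviation.

## Known limitations

* No occupancy or N-mixture modelling: detection is corrected by fixed
  published proportions, not estimated from the data.
* No spatial variance: the state-estimate SD reflects parameter
  uncertainty only, not between-plot variation of MAFD.
* Chorus-averaged (min–max averaged) counts are carried as flagged reals
  and never rounded; whether the original analysis rounded them is
  unstated.
* Counts at unsurveyed sites are rejected at load time; opportunistic
  records would need their waterbodies marked surveyed.
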