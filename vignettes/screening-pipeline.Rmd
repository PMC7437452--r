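---
title: "A dual-cytokine HTRF screening pipeline: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dual-cytokine HTRF screening pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htrfscreen)
```

## The assay and its statistics

The pipeline models a phenotypic screen for NLRP3-inflammasome inhibitors
in stimulated macrophages. Each 384-well plate carries compound wells at a
single screening dose plus 16 stimulated vehicle wells ("high controls",
maximal cytokine secretion) and 16 unstimulated vehicle wells ("low
controls", background). Two cytokines are read per supernatant by HTRF:
IL-1β, the inflammasome product of interest, and IL-6, an
inflammasome-independent cytokine used as a counter-screen against
nonspecific inhibition, secretion enhancement and cytotoxicity.

The raw readout is two emission channels per well; the assay signal is the
ratio `10000 × Em665 / Em620`. Working on the ratio scale cancels
well-to-well variation of the donor channel: the simulator exploits the
same identity in reverse, decomposing a target ratio into an `em620` draw
and the matching `em665`, so the ratio computation recovers the simulated
truth exactly (a property the tests assert).

**Percent inhibition.** Each compound well is expressed relative to the
DMSO controls *of its own plate and analyte*:
`100 × (μ_hc − x) / (μ_hc − μ_lc)`. This maps the stimulated control to
0 %, the background to 100 %, and secretion enhancement to negative
values, which matches the −100…100 display convention of screening
scatter plots. The normalization uses outlier-cleaned control means
(below); it is invariant to any common rescaling of both emission
channels, and strictly decreasing in the well ratio.

**Outlier rule.** Control wells occasionally fail (dispensing, bubbles).
A single pass computes the mean and SD (n−1 denominator) of each control
group, excludes values outside mean ± 3 SD, and recomputes. The pass is
deliberately not iterated: one round reflects how such exclusions are
flagged in practice, and iterating can chase the tail of a clean sample.
Re-running the rule on a cleaned set excludes nothing on the fixtures we
test. The **QC statistics are computed from uncleaned controls** — the
screening-window coefficient must reflect the assay as it ran, including
its outliers — whereas normalization uses the cleaned means.

**Plate QC.** Per plate and analyte, `Z′ = 1 − (3σ_hc + 3σ_lc)/(μ_hc −
μ_lc)` and `S/B = μ_hc/μ_lc`. A plate passes at `Z′ > 0.5` (strict, per
the usual "over 0.5 is excellent" reading). Failing plates are flagged,
not silently dropped; `exclude_failing_plates` removes their compounds
from triage when set, and the default keeps them because a well-calibrated
screen passes all plates.

## The triage cascade

Stages, applied in order, each configurable in `screen_config()`:

1. **Primary activity:** keep IL-1β inhibition strictly above 30 %.
   Ties fall on the excluded side ("more than 30 %").
2. **Counter-screen:** exclude compounds with `|IL-6 %| > 50`. The band
   is symmetric — strong IL-6 *enhancement* is as disqualifying as strong
   inhibition, both indicating inflammasome-independent action. The 50 %
   default encodes a deliberately more relaxed criterion than the IL-1β
   cutoff, because the IL-6 assay window (Z′ ≈ 0.47) is narrower than the
   IL-1β window (Z′ ≈ 0.77); it is echoed in every run manifest since it
   is a package choice, not a published constant.
3. **Steroids:** excluded from the annotation table's `is_steroid` flag;
   broad anti-inflammatory steroids suppress cytokines upstream of the
   inflammasome. Identification is annotation-driven, not structural.
4. **Duplicates:** screening libraries overlap; each `duplicate_group`
   keeps its strongest IL-1β inhibitor.

Stages 1 and 2 are per-compound predicates and therefore commute (tested
on random fixtures); the order shown is how the counts are reported. The
terminal categories partition the compound set — conservation is asserted
on every fixture.

**Confirmation.** A primary-selected compound is confirmed when its IL-1β
IC50 is strictly below 10 μM *and* IL-1β inhibition predominates over
IL-6 at ≥ 2 doses of the confirmation grid. "Predominance" at a dose is
quantified here as `(IL-1β % − IL-6 %) ≥ 30` with `IL-1β % ≥ 30` — the
margin and floor mirror the primary-screen cutoff and are exposed as
configuration because no published numeric definition exists. Replicates
are averaged per dose before the comparison; the first failing rule
(IC50, then predominance) is recorded.

## Dose–response model

The curve model is the rising four-parameter logistic
`r(d) = bottom + (top − bottom)/(1 + (IC50/d)^hill)`, fit by
Levenberg–Marquardt least squares in log10-dose space on all replicate
points (`minpack.lm::nls.lm`). Numerical choices:

* **Initialization:** asymptotes at the extreme per-dose means, IC50 at
  the dose nearest the half-maximum, Hill slope 1.
* **Bounds:** IC50 within `[min dose/10, max dose × 10]` — an IC50 more
  than a decade outside the tested range is extrapolation, not
  estimation; Hill within `[0.1, 10]`; asymptotes within 50 percentage
  points of the observed per-dose mean range. The asymptote bound
  matters: responses are control-normalized percent inhibition, and with
  unbounded asymptotes a shallow noisy curve lets the optimizer trade
  `top → ∞` against `IC50 → ∞`, a classic 4PL degeneracy. With the bound
  in place, 100 simulated confirmation experiments (5 half-log doses ×
  4 replicates, 10-point noise) recover a 2 μM IC50 with the median
  within 25 % and no fit at a bound.
* **Fallback:** if the optimizer fails, the IC50 is the 50 % crossing of
  the per-dose mean response, linearly interpolated in log-dose
  (`method = "interpolation"`). A curve whose per-dose means span less
  than 10 points is flagged flat and yields no IC50 — distinguishing
  "no effect" from "fit failed".
* **Tie-breaks:** exactly-50 % means count as a crossing; if a fitted
  `top < bottom` the labels are swapped so `top` is always the high-dose
  asymptote.

Noiseless data generated from the model are recovered exactly (tested to
1e-3 on the IC50), the fit is exactly scale-equivariant in dose, and
fixing the Hill slope at its generating value changes the noiseless IC50
by well under 1 %.

## The synthetic screen and its calibration

`simulate_screen()` emulates the assay at full scale: 16 plates × 384
wells, 16 + 16 controls (columns 23/24 in the generated map — but all
downstream code is map-driven and assumes no geometry), 4,825 compounds
at 1 μM filling 22 compound columns per plate sequentially, trailing
wells empty. For a well with true fractional inhibition *f* the target
ratio is `μ_lc + (1 − f)(μ_hc − μ_lc) + N(0, σ_well)`; high controls have
*f* = 0, low controls *f* = 1, and `σ_well` interpolates linearly between
`σ_hc` and `σ_lc` with *f*, since wells near the stimulated signal
plausibly carry stimulated-well noise. Noise is Gaussian on the ratio
scale — a stand-in, since the real well-level distributions are
unpublished.

The default control parameters (IL-1β: μ_hc 8980, μ_lc 1000, σ_hc 450,
σ_lc 160; IL-6: μ_hc 4290, μ_lc 1000, σ_hc 430, σ_lc 150) were chosen so
the closed-form population statistics are Z′ 0.7707 / S/B 8.98 (IL-1β)
and Z′ 0.4711 / S/B 4.29 (IL-6) — an excellent IL-1β window and a
distinctly narrower IL-6 window, as such dual-readout screens show. A
16-plate simulation's mean sample Z′ tracks the population value within
±0.03 and S/B within ±0.30 (sample SDs of n = 16 are slightly biased
low, inflating Z′ by ≈ 0.004 — well inside that band).

Effect classes default to inactive 0.94, selective inhibitor 0.01,
nonspecific inhibitor 0.02, enhancer 0.01, cytotoxic 0.02 — a ~1 %
selective-hit rate typical of annotated-library screens. Actives draw a
log-uniform IC50 from 0.01–0.6 μM (Hill 1, full efficacy), i.e. true
1-μM inhibition between 62.5 % and ~99 %: the simulator plants
*detectable* actives, so that triage sensitivity measures the pipeline
rather than the potency lottery. Enhancers sit at *f* = −0.5 and
cytotoxic compounds at *f* = 0.9 on both cytokines (invented, documented
values); both are rejected by the cascade — enhancers at the IL-1β
stage, cytotoxics by the IL-6 band — which is precisely the
counter-screen's job. `class_counts` pins exact class sizes (e.g. 50
planted selective inhibitors) for recovery experiments; `assignment =
"deterministic"` makes the mixture exact rather than multinomial.

What the simulator does **not** model: plate-position (edge) effects,
plate-to-plate drift, correlated channel noise, compound fluorescence
artifacts, partial-efficacy actives, or any biochemical kinetics. Passing
planted-hit recovery on simulated data therefore demonstrates the
pipeline's correctness, not robustness of the assay to those real-world
effects; a positional-correction step is deliberately out of scope
because the modeled screen applies none.

## Problem sizes in the test suite

The suite runs the full-size screen (16 plates, 4,825 compounds, both
analytes — ~12,300 wells) for the calibration and planted-hit checks,
100-replicate fit-recovery simulations, and 2-plate screens elsewhere;
the whole suite completes in a few seconds. The one check that cannot
run from this repository alone is the reproduction of the published
per-compound count (238 of 4,825 above the 30 % criterion), which needs
the supplementary per-compound workbook; the reader
(`read_compound_results()`) accepts a delimited export of it with
tolerant headers.
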