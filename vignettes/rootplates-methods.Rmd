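---
title: "Quantifying seedling root growth from soil-plate tracings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying seedling root growth from soil-plate tracings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootplates)
```

## The experiment this package quantifies

Cereal seedlings -- wheat is the motivating crop -- are germinated on
well-watered soil in transparent square plates, and at 30 h seedlings at a
uniform developmental stage are transplanted side by side into well-watered
(WW) plates and plates whose soil solution contains 20% PEG-8000, imposing a
defined water deficit of about -0.65 MPa (WW soil sits near -0.02 MPa).
The standard design is three plates of eight seedlings per condition, 24
replicates per treatment. Plates are photographed through the lid under
green light on day 0 (at transplant), day 1 and day 2; on day 2 each
seedling is photographed individually. Roots and the coleoptile (the
"shoot") are traced in the photographs with node-snapping software, and the
traced structures are exported as CSV tables of labelled lengths. Wheat
seedlings carry up to five (sometimes six) seminal roots: the shoot and
roots 1-3 are present at transplant, roots 4 and 5 emerge later than 24 h
after transplant.

`rootplates` is the quantification layer downstream of tracing: it parses
the label and filename grammars, recovers millimetre lengths from pixel
polylines, applies the replicate-accounting rules for hidden and
not-yet-emerged roots, summarises and tests the WS - WW contrast per
structure and timepoint, and draws the root plots and difference plots. A
seeded simulator of the whole experiment makes every stage testable without
wet-lab data.

## From pixels to millimetres

Tracings are polylines of sub-pixel node coordinates in image convention.
Length is the sum of straight Euclidean segments; no arc smoothing or
spline fitting is applied between nodes, because the tracing itself is the
measurement and smoothing would add unverifiable structure. Each plate
carries 16 mm white plastic strips flush with the soil; tracing one strip
fixes the scale (`calibrate()`), and by construction measuring the strip
under its own calibration returns exactly 16 mm up to floating round-off.
Lengths are invariant under translation and rotation of the image, which
the test suite asserts to a relative tolerance of 1e-9.

## Replicate accounting: measured, occluded, absent

The semantics of a missing tracing depend on the structure and they matter
for every downstream mean:

* The shoot and roots 1-3 exist from day 0. If one of them has no tracing
  in a day-1 photograph, the root is there but hidden (it grew around the
  plate edge or away from the transparent wall). It is scored **occluded**:
  excluded from the mean *and* from `n` for that structure and day, without
  touching any other structure's `n`.
* Roots 4-6 emerge after day 0. A missing tracing means the root has not
  appeared yet: **absent**, scored as a true 0 that *does* count toward the
  mean and `n`. A late root that is present but not fully visible is traced
  and labelled with an `_NA` suffix, which scores it occluded. The suffix
  is rejected on roots 1-3 and the shoot, where a missing tracing already
  encodes occlusion.
* A seedling with no tracings at all on a day is treated as a missing
  photograph: all of its structures are occluded that day. We chose this
  over a hard error because the photograph, not the plant, is the missing
  unit; day-0/day-2 gaps additionally warn because those photographs are
  expected complete.
* An emerged late root can never revert to absent: that pattern is a
  tracing error and compilation stops with an error naming the seedling and
  structure. Measured lengths that *shrink* across days are kept but
  flagged with a warning -- on real tracings they reveal calling mistakes
  and must stay visible rather than be silently repaired.

Day-0 lengths are expected near 10 mm for root 1 at transplant; all day-2
structures are photographed per seedling and hence visible.

Some varieties carry a sixth root. Root 6 enters plots, summaries and
statistics only when strictly more than `threshold` (default 3) of the
condition's 24 seedlings show direct evidence of one -- a measured positive
length or an `_NA` tracing. We extend the rule from plots to all summaries
so no table reports a structure its figure hides; the threshold is a
visible argument everywhere it applies. A day with a missing photograph is
deliberately *not* evidence of a sixth root.

## The treatment contrast model

Per structure, lengths are modelled as

```
length_mm ~ condition * day + (1 | plate) + (1 | seedling-in-plate)
```

with day categorical (three levels), fitted by REML. Day is categorical
because the deliverable is a per-timepoint contrast, not a growth-curve
slope. Plates are the unit the treatment is applied to and seedlings are
measured repeatedly, which motivates the two random intercepts. Occluded
rows are dropped; absent late roots enter as true zeros because they count
toward replicate numbers. The WS - WW contrast within each day is computed
from estimated marginal means with Satterthwaite degrees of freedom, and a
point is called significant below a flat alpha of 0.05 per structure and
day with no multiplicity correction by default (a Holm option exists but is
off), matching how difference plots are conventionally read in this assay.

Variance components estimated at zero make the fit singular. The fallback
ladder is deterministic and recorded on the fit object: drop the seedling
intercept, then also the plate intercept, at which point the model is a
fixed-effects-only least-squares fit and a warning is issued. This is
common and benign for late roots whose day-0 and day-1 values are all zero.
On balanced designs with no plate or seedling variance the ladder lands on
least squares, where the per-day contrast equals the raw difference of
condition means exactly -- the test suite asserts agreement to 1e-6 mm and
checks p-values against a two-sample t-test within 10% relative.

## Plots as data

Root plots arrange one stacked bar per structure in the seedling's own
anatomy -- roots 2 and 3 flank root 1, later roots outermost, the shoot
drawn upward at the centre (`root4, root2, root1, root3, root5, root6`, and
configurable, since the exact left-right order is an aesthetic). The three
stack segments are the day-0 mean and the two between-day changes in day
means, so the stack top equals the day-2 mean identically. Negative mean
increments are rendered as dashed red overlays rather than dropped.
Difference plots facet per structure and show the WS - WW estimate at each
day with a +/- 1 standard error bar (the interval type is a package choice;
gray points are non-significant, black significant).

Plot *specs* are plain data structures built separately from rendering, so
the suite asserts geometry (stack conservation, bar directions, colours)
without comparing images. Rendering goes to vector PDF (optionally PNG),
and a combined three-panel report (WW root plot, WS root plot, difference
plot, tagged A/B/C) is what a full `analyze()` run exports.

## What the simulator emulates

`simulate_experiment()` regenerates the full experiment: 2 conditions x 3
plates x 8 seedlings, days 0/1/2, per-plate exports on days 0-1 and
per-seedling exports on day 2, every file named by the filename grammar and
every structure labelled by the label grammar. Defaults are the design
constants above; the growth defaults encode the qualitative features of the
assay: root 1 at 10 mm on day 0 (shoot 8, roots 2-3 at 8 and 7 mm);
decelerating piecewise-linear growth (root 1 at 15 mm/day then 12 mm/day --
the growth rate is greatest between transplant and 24 h); roots 4 and 5
emerging at 1.25 and 1.5 days; water stress multiplying root rates by 0.6
and the shoot rate by 0.4 (stress inhibits the shoot more than the roots).
Piecewise-linear trajectories were chosen over logistic curves because only
between-timepoint rates are observable at this sampling density; the rate
magnitudes themselves are plausible placeholders for a wheat cultivar at
28 degrees C, not reproductions of measured values.

Randomness enters as Gaussian plate and seedling intercepts (sd 0.5 and
1.0 mm) shared across a seedling's structures -- deliberately the same
family as the analysis model so parameter-recovery tests are fair -- plus
Gaussian noise (sd 0.5 mm) on the day-0 length and on each growth
increment, truncated at zero so simulated lengths never shrink. Day-1
occlusion hits each structure with probability 0.05, doubled for the
outward-facing roots of the outermost plate positions (root 2/4 of the
left-most seedling, root 3/5 of the right-most), which is where real
occlusions concentrate. Occlusions are emitted exactly as a root caller
would: early structures are skipped from the file, emerged late roots are
written with `_NA` labels.

What the simulator does *not* emulate: tracing bias (every tracing is the
true length plus noise), non-Gaussian measurement error, germination
failure, seedling death, root-shoot overlap errors, or soil-water dynamics
(water potentials are carried as metadata only). Passing tests therefore
demonstrate that the quantification rules, model and plots behave correctly
under a faithful rendering of the design -- not that the package fixes bad
tracings.

## Numerical and design choices

* Coordinates are continuous; single-node polylines measure 0 mm.
* Simulated lengths are rounded to 3 decimals (a micrometre) when emitted,
  so written CSVs and in-memory tables agree exactly and runs are
  byte-deterministic for a given seed.
* The genotype is the single token after the first space of a filename
  ("`20160413 Zak wt WW1 day0.csv`" yields `"Zak"`); other tokens are free
  text. Condition tokens must be unique; the label grammar is
  case-insensitive but whitespace-intolerant, so hand-typed typos surface
  early. Duplicate labels within a file are errors, not last-wins.
* Required export columns default to `root` and `length` with
  case-insensitive matching and configurable overrides, since exporter
  column schemas vary by version.
* Merged ("combined") CSVs carry a `SourceFile` column so the merge is
  losslessly reversible with `read_combined()`.
* The whole-pipeline checks in the test suite run at the design's own scale
  (24 seedlings per condition), with 200 simulated experiments for the
  type-I-error property and 100 for effect recovery.

## Known limitations

* No imputation of occluded lengths; a structure occluded at an endpoint
  simply drops out of that growth interval.
* The mixed-model configuration of the original assay software is not
  published, so exact p-values from any particular historical analysis are
  not a reproduction target; what is guaranteed is the documented model,
  its deterministic fallbacks, calibrated day-wise size (the suite checks
  the null rejection rate lands in [0.02, 0.09] at alpha = 0.05) and
  contrast recovery.
* With only three plates per condition, degrees of freedom for the
  condition contrast are inherently small (Satterthwaite df around 4-10);
  confidence statements lean on the t distribution's heavy tails there.
* Filename grammar supports plates 1-3 per condition; larger designs need
  label-grammar extensions.
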