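---
title: "Models and methods for flanked letter identification analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for flanked letter identification analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowding)
```

## The scientific problem

Visual crowding is the failure to identify a target stimulus when flanking
stimuli fall within a critical spacing of it. In healthy vision crowding is
essentially a peripheral phenomenon; in posterior cortical atrophy (PCA) it
can invade central vision, so that ordinary printed letters become
unreadable when neighboured by other characters. The canonical assay is
flanked letter identification: a target letter, flanked left and right,
must be named aloud. Manipulating the edge-to-edge spacing (condensed,
0.1 degrees, versus spaced, 1.0 degrees), the flanker category (letters,
outline triangles, digits) and the contrast polarity of the flankers
relative to the target dissects which mechanism limits performance.

This package implements the full analysis pipeline for such experiments —
stimulus construction, error taxonomy, latency trimming, crowding indices,
similarity-based error modelling and group contrasts — together with a
synthetic cohort generator that plants known error mechanisms, so that
every stage can be exercised and validated without patient data.

## Stimulus geometry and rendering

Sizes convert between millimetres and degrees by the exact relation
$\theta = 2\arctan(s/2d)$ at viewing distance $d$ (default 500 mm). A
10.5 mm glyph subtends 1.20 degrees at 50 cm; this is the default letter
height. Glyphs are rendered from a bundled 5x7 bitmap font, upscaled by
nearest-neighbour resampling to the pixel height implied by the pixel
pitch (default 0.25 mm/px, i.e. 42 px letters), so rasters are
bit-identical across platforms. Ink is signed: +1 for dark-on-background,
-1 for light ink, 0 background. Reverse-polarity flankers simply flip the
sign of their raster, which makes polarity effects emerge naturally when
images are averaged.

Arrays place left flanker, target and right flanker on one line, centred
in the flanked fixation box (6.4 x 2.9 degrees; the unflanked box is
3.2 x 2.9). Gaps are measured edge-to-edge between ink bounding boxes and
are accurate to one pixel. The canvas width is snapped down by at most one
pixel so left and right margins are exactly equal; this makes composition
exactly mirror-symmetric, which the tests exploit.

Because an equilateral outline triangle is invariant under 120-degree
rotation, the three triangle orientations are 0, 40 and 80 degrees —
maximally separated within the 120-degree symmetry period. Triangles match
the letters' height and stroke width.

## Pixel-overlap similarity

The similarity between two images is a fuzzy Jaccard coefficient on ink
magnitude:

$$S(a,b) = \frac{\sum_{ij}\min(|a_{ij}|,|b_{ij}|)}
                {\sum_{ij}\max(|a_{ij}|,|b_{ij}|)}.$$

On binary masks this is exactly intersection-over-union pixel counting
(the test suite verifies bit-exact agreement with a brute-force loop); on
grey-valued composites the min/max fuzzy-set operators extend it while
keeping symmetry, the [0, 1] range, and the property that 1 occurs only
for magnitude-identical images. Jaccard normalisation was chosen because
the raw overlap count grows with glyph size; the raw intersection is
available via `metric = "intersection"`.

Before comparison the second image is shifted by the integer-pixel
difference of the ink centres of mass (ties round toward zero shift):
letter identity, not position, drives the similarity construct, and the
tests verify exact translation invariance. Similarity is computed on
contrast magnitude, so a reverse-polarity flanker attenuates the averaged
composite (signed averaging) but does not change how the composite is
compared against candidate letters.

## Error taxonomy and behavioural preprocessing

Flanked naming responses partition into: correct; Type A (no response);
Type B (a flanker named instead of the target, e.g. ZNH -> Z); and Type C
(a letter in neither target nor flankers, e.g. YMT -> V, 3T6 -> C, the
signature of feature integration). The classifier is order-invariant in
the flankers, and the four classes partition every flanked table.

Latency trimming is two-stage. Stage 1 removes latencies of erroneous,
prompted or overtly distracted responses. Stage 2 computes each
participant's mean and sample standard deviation (n-1 denominator) on the
stage-1 survivors in a single pass — no iterative re-trimming — and
removes latencies more than 2 SD from that mean; participants with fewer
than two surviving latencies are skipped and flagged. The removal ledger
reports the conservation identity (stage-1 + stage-2 + retained = total)
on every run. Latencies enter linear models as reciprocal rates (1/s),
which normalises the residuals of right-skewed naming-time distributions.

A prompt ("Is that the letter in the middle?") is recorded when the named
response is a flanker. Prompted trials keep their accuracy but lose their
latency, and prompted responses do not count as correct for crowding
indices, which use only unprompted first responses. Crowding indices are
raw correct-count differences (spaced minus condensed for Tasks 3, 4 and
their combination; reverse minus same polarity for Tasks 5-6 overall and
condensed-only), not percentages. A missing task yields a missing index,
never zero.

Behavioural covariates map linearly onto 0-100, with 0 and 100 anchored
at the minimum and maximum score achieved by any patient; a degenerate
range is an explicit error rather than a silent NaN.

## The averaging-versus-substitution error models

The central question is whether crowding errors look like *compulsory
averaging* (target and flanker features pooled into one percept) or
*flanker substitution* (a flanker reported in place of the target). Three
models operationalise this for Type B and C errors:

* **Model 1** — similarity of the error response to the *averaged*
  target/flanker image (`sim_avg`);
* **Model 2** — similarities to each *individual flanker* (`sim_left`,
  `sim_right`);
* **Model 3** — Model 2 plus similarity to the target (`sim_target`).

The outcome is constructed by candidate expansion: each error trial
contributes one row per candidate letter — the 20-letter permitted target
alphabet minus that trial's target, i.e. 19 rows — with a binary
indicator marking the candidate actually named. How the original analysis
turned "error identity and frequency" into a regression outcome is not
fully determined by its description; candidate expansion is this
package's documented reading, chosen because it predicts both which
letter is reported and how often. A consequence is that every Type B
response must lie inside the candidate space, so the cohort generator
draws letter flankers from the permitted target alphabet, and
`build_design()` rejects responses outside it.

Each model is a logistic mixed-effects model with crossed random
intercepts for participant and for error-response letter (the candidate
identity), estimated by maximum marginal likelihood with the Laplace
approximation (`lme4::glmer`, nAGQ = 1, bobyqa optimizer). Wald z and p
values are reported, matching the reporting style of the original
analyses. Complete separation — easy to trigger because a Type B
response has similarity exactly 1 to the named flanker — is detected from
diverging coefficients and answered by a Firth (Jeffreys-prior) penalized
refit of the fixed effects, always flagged, never silent.

The test suite validates the Laplace likelihood against a hand-written
adaptive Gauss-Hermite quadrature oracle (mode-centred, curvature-scaled
product rule over the joint random-effects vector). Two facts emerged and
are worth stating plainly:

* At freely estimated parameters on very small crossed designs the
  Laplace approximation can deviate from the exact marginal likelihood by
  more than 1e-3 whenever the variance estimate is substantial; agreement
  to 1e-3 and far better holds in the small-variance regime that the
  real candidate-expansion designs occupy. The oracle itself is
  self-consistent (15- and 25-node rules agree to ~1e-12).
* The features of Models 1 and 2 are intrinsically correlated: each
  flanker contributes one third of the composite, and flanker candidates
  score similarity 1 on Type B errors. Simulation studies with a single
  planted mechanism therefore show cross-talk — a pure-averaging cohort
  produces nonzero power in the Model 2 flanker terms, and a
  pure-substitution cohort produces strong Model 1 effects. The
  mechanism-recovery study in the acceptance suite quantifies this
  honestly rather than assuming the models are orthogonal; attenuation
  also means the fitted Model 1 coefficient sits below the generator's
  softmax temperature (the design excludes the target from candidates
  while the generator's softmax includes it).

## The synthetic cohort generator

The generator is a first-class module that defines the study conditions:
26 PCA-like, 17 typical-Alzheimer-like and 14 control participants;
Task 1 presents the 20 permitted letters unflanked; Tasks 2-6 (letter,
shape, number, same-polarity letter, reverse-polarity letter flankers)
each present 12 target/flanker triplets under both spacing conditions —
24 trials per task, 72 across Tasks 2-4, with condensed/spaced ordered in
six-item ABBA blocks. Whether the original 24-item tasks comprised 24
unique triplets in one condition each or 12 probed under both conditions
is not stated in the source description; 12 unique triplets shown twice
is adopted because it matches both the per-task totals and the statement
that the same flanker combination appeared under both spacings.

A trial's response is drawn from a mechanism mixture gated by crowding
strength $s(g) = \max(0, 1 - g/g_c)^k$ — a linear ramp (default
$k = 1$) from 1 at zero gap to 0 at the participant's critical spacing
$g_c$, multiplied by $\rho \in [0,1]$ under reverse polarity. With
probability $s \cdot (w_{mask} + w_{subst} + w_{avg})$ one mechanism
engages, in proportion to its weight: masking yields no response
(Type A); substitution names a flanker (digit and triangle flankers map
to their most-similar letter, because participants answer with letters);
averaging samples a candidate letter with probability proportional to
$\exp(\beta \cdot S(\text{candidate}, \text{composite}))$. Otherwise the
target is named, up to a small lapse rate.

Defaults were chosen once to emulate the study conditions: PCA-like
weights 0.10/0.14/0.09 (mask/substitution/averaging) with median critical
spacing 1.4 degrees (log-normal across participants, log-SD 0.25) place
the condensed gap deep inside and the spaced gap near the edge of the
interference zone, reproducing a flanked error rate near 18%, condensed
well below spaced accuracy, a mixture of all three error types, and a
condensed-only reverse-polarity advantage ($\rho = 0.35$); the
typical-AD group is near ceiling with latency-only spacing costs;
controls make no flanked errors. In peripheral vision the critical
spacing would be about half the target eccentricity (the Bouma fraction,
kept as a parameter); central presentation in this model instead takes a
pathological central critical spacing directly.

Latencies are log-normal around a base plus a crowding cost proportional
to strength, with a participant-level multiplicative random effect and
2% scale-5 outlier contamination; the trimming tests verify that the
2-SD rule removes at least the planted contamination (plus the expected
log-normal tail).

Reproducibility: a seed is mandatory; the generator uses R's
Mersenne-Twister stream (with inversion sampling for normals) and
restores the caller's RNG state, and the same seed yields bit-identical
trial tables. The stimulus catalogue can be prebuilt and shared across
replicate cohorts, mirroring a fixed test battery.

What the generator does *not* emulate: drift-diffusion latency dynamics,
eye movements, attentional lapses correlated over time, perceptual
similarity beyond pixel overlap, and item-level difficulty other than
through glyph geometry. Passing tests therefore show that the pipeline
recovers what this generative family plants — not that real patient data
obey the model.

## Group-level contrasts

Accuracy is analysed by logistic regression and inverse latency by linear
regression, both with spacing, flanker type, their interaction and group
interactions (latency models additionally adjust for accuracy), and both
with cluster-robust sandwich standard errors over participants. The
default flavour is CR0 — no small-sample correction — with an HC2-type
CR2 adjustment behind a flag, since the original description specifies
clustering but not the flavour. With one observation per cluster CR0
reduces to the ordinary HC0 estimator (tested). Wilcoxon rank-sum and
signed-rank utilities cover simple between- and within-group score
comparisons; p-values are reported unadjusted, with a Holm helper
available. Covariate adjustment refits the contrast once per covariate
and reports whether the effect of interest survives at 0.05.

## Problem sizes and numerical choices

The simulation studies in the test suite use: 100 replicate cohorts per
planted mechanism (20 participants, full flanked battery, one engaged
mechanism at weight 0.30, roughly 15-20 Type B/C errors per participant)
for mechanism recovery; 500 replicate null cohorts (12 participants,
letter and shape tasks) for the size of the composite-similarity test;
and 200 random rasters for the similarity oracle. These sizes give stable
power and size estimates while keeping the full suite quick to run.
Convergence of the mixed fits uses lme4 defaults with bobyqa and up to
20000 function evaluations; fits report a convergence flag, and
non-converged fits are never silently accepted.

## Known limitations

* The bitmap font is deliberately minimal; pixel-overlap values depend on
  the font, so similarity values are comparable only within one font and
  geometry. Anti-aliased or outline-font rendering is out of scope.
* The candidate-expansion outcome construction is one defensible reading
  of the original modelling description; aggregate per-letter counts are
  another, and coefficients are not numerically comparable between the
  two.
* CR0 sandwich inference is asymptotic in the number of clusters; with
  very few participants its z tests are anticonservative.
* The Firth fallback refits fixed effects only; random-intercept
  variances are not penalized and are reported from the diverged fit.
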