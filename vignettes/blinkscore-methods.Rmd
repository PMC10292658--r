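---
title: "Scoring delay eyeblink conditioning and cerebellar morphometry with blinkscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring delay eyeblink conditioning and cerebellar morphometry with blinkscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blinkscore)
```

## The measurement problem

Delay eyeblink conditioning is a cerebellum-dependent form of classical
conditioning. A head-fixed mouse receives a light conditioned stimulus (CS,
280 ms) that co-terminates with a corneal airpuff unconditioned stimulus (US,
30 ms), so the US begins 250 ms after CS onset. With training, the animal
learns to close its eyelid *before* the puff arrives; that anticipatory
closure is the conditioned response (CR). Performance is quantified from
videos of the eye: percent CR per session, and the timing of the CR peak on
CS-only probe trials. `blinkscore` implements that scoring pipeline, the
Purkinje-cell and vermal-section morphometry that typically accompanies it
in strain-comparison studies (Sholl profiles, spine density, soma area,
arbor height, linear density, layer thickness), and the group statistics
(unpaired t-tests, two-way ANOVA with and without repeated measures,
Bonferroni-corrected planned comparisons).

No public raw data exist for this class of experiment at the scale needed
for testing, so the package ships a first-class synthetic generator for
every input: trial schedules, eyelid kinematics, rendered eye videos,
Purkinje-like morphologies, and cohort tables. All generators are seeded
and bit-reproducible, and each stores its ground truth so recovery can be
verified end to end.

## Trial structure and schedules

A training session is 22 blocks of 10 trials, each block holding 9 paired
trials and 1 CS-only trial at a seeded pseudorandom position, with
inter-trial intervals of at least 12 s. The generator samples the ITI as
12 s plus an exponential excess with mean 3 s; only the lower bound is a
protocol constant, the tail shape is a modelling choice (memoryless waiting
time is the conventional default for self-paced trial starts).

```{r schedule}
sched <- generate_schedule(1, seed = 7)[[1]]
table(sched$trial_type)
range(sched$iti_s)
```

## Eyelid kinematics and the video model

The trace generator composes, in camera pixel units: a baseline
(`baseline_px`, default 40), a UR on paired trials (linear rise over 40 ms
to 400 px, exponential decay with a 250 ms time constant), a CR with
probability `cr_probability` (linear rise from a Gaussian onset — default
mean 150 ms, SD 20 ms after CS onset — over `cr_rise_ms` = 100 ms to 60% of
the UR amplitude, same decay), Poisson spontaneous blinks (default
0.05 Hz, UR-shaped) that exercise the exclusion rule, and Gaussian pixel
noise (SD 8 px). The CR shape is deliberately the simplest waveform that
drives every classifier branch; it is not a biomechanical eyelid model. The
CR peak sits at onset + rise, which the peak-time metric should recover.

The default frame rate is 200 Hz (5 ms resolution, so the 100–250 ms CR
window holds ~30 frames), configurable down to 60 Hz to emulate consumer
cameras.

The renderer draws each frame as a dark face, a rectangular eye ROI, and a
bright lid region whose pixel count equals the rounded trace value. Lid
pixels are filled in a fixed nested order growing outward from the ROI
corner. Early versions filled the ROI in raster order; the resulting
1-pixel-wide strips at low trace values were diluted below threshold by the
box smoothing in the extraction stage, collapsing small signals to zero and
inflating normalised noise. The compact fill keeps the mapping from trace
value to post-smoothing white-pixel count monotone and invertible across
the whole range, which the roundtrip tests check by rank correlation
(> 0.99).

## Trace extraction

`extract_trace()` smooths each frame with a box filter (radius 2 px by
default; the protocol only states that frames are "smoothed", so the radius
is exposed), binarises at a threshold, and counts white pixels in the ROI.
The default threshold is Otsu's method computed on the smoothed ROI of the
first frame. Restricting Otsu to the ROI matters: on the full frame the
dark face pixels form a third intensity class and Otsu can separate
face/background instead of background/lid, saturating the count at the ROI
area. Frames are never temporally resampled; all scoring windows are
evaluated on native timestamps.

## Normalisation and CR classification

For each paired trial, the signal within 1500 ms of US onset is mapped
affinely so that the minimum over the 280 ms after CS onset is 0 and the
maximum over the 500 ms after US onset is 1. The classification rule is:

* **excluded** if the normalised signal exceeds 0.15 at any sample in
  `[0, 100)` ms after CS onset (the eyelid was already moving);
* else **CR** if it exceeds 0.15 at any sample in `[100, 250]` ms;
* else **no_CR**.

Percent CR is the percentage of *counted* (non-excluded) paired trials with
a CR. CS-only trials are normalised to the mean UR amplitude
(`us_max − cs_min`) of up to the 9 preceding paired trials and are CRs iff
the normalised signal exceeds 0.15 in `[100, 400]` ms *and* stays below
0.05 throughout `[0, 99]` ms.

Several conventions had to be fixed where the verbal rule is silent:

* Window endpoints: detection windows are closed (`[100, 250]`), the
  exclusion window half-open (`[0, 100)`), so no sample belongs to both.
* The exclusion window is interpreted as `[0, 100)` after CS onset rather
  than the pre-CS baseline, because the normalisation anchors are defined
  only from CS onset onward; pre-CS samples are not inspected.
* The early-quiescence clause for CS-only trials is read as the interval
  `[0, 99]` ms.
* A single supra-threshold sample counts; no minimum crossing duration is
  imposed (none is stated).
* A flat paired trace (`us_max == cs_min`) cannot be normalised; such
  trials are excluded with reason `degenerate_normalization` instead of
  propagating NaN, and contribute no reference UR.
* CS-only baseline subtraction uses the mean of the pre-CS samples (mean
  rather than minimum, to avoid biasing the zero point low under noise),
  falling back to the minimum over the 280 ms post-CS window if the trace
  starts at CS onset.
* Fewer than 9 usable preceding paired trials (start of a session) means
  the mean of the available ones; none at all excludes the CS-only trial.

The classifier is invariant to positive affine transforms of the raw trace
by construction (the normalisation removes gain and offset); the suite
verifies this and checks exact agreement with an independent brute-force
implementation that scans every sample against the literal rule.

```{r scoring}
p <- blink_params(cr_probability = 0.7)
ss <- simulate_scored_session(generate_schedule(1, seed = 1)[[1]], p,
                              frame_rate_hz = 100, seed = 2)
summarize_session(ss, animal_id = "demo", strain = "C57", sex = "M",
                  session_index = 10)
```

## Peak time

The CR peak time on CS-only trials is the argmax of the normalised curve
after smoothing with a centred 25 ms moving average, averaged per animal
over the CS-only CRs of the final three training sessions (10–12). The
argmax is restricted to a `[0, 500]` ms search window so a late spontaneous
blink cannot masquerade as the CR peak. Smoothing an asymmetric
rise/decay waveform biases the argmax slightly rightward (about one frame
at 200 Hz for the default kinematics); the recovery tests budget for this.

## Morphometry

* **Sholl profiles**: intersections of the dendritic arbor with concentric
  circles at 8 µm steps from the soma centre, computed exactly by
  segment–circle intersection (quadratic roots per segment, parameterised
  half-open on `[0, 1)` so a crossing at a shared vertex is counted once;
  tangencies count once). Radii stop at the largest multiple of 8 µm within
  the arbor's maximal radial extent. The tests compare against dense 0.01 µm
  resampling.
* **Spine density**: distal dendrites are sampled as every seventh
  branchlet from a seeded random starting offset; density is pooled spines
  over pooled length. "Branchlet" is taken to be a terminal segment (from
  the last branch point to a tip), matching the distal-dendrite sampling
  the assay describes.
* **Soma area** is the shoelace area of the traced contour
  (self-intersecting contours are rejected); **arbor height** is the
  maximal perpendicular distance of any branch node from the horizontal
  axis through the soma centre. The height axis is genuinely
  slice-orientation dependent; the horizontal soma-base axis is the
  convention here.
* **Linear density** is calbindin-positive cells per 100 µm of layer
  midline; **layer thickness** uses the ribbon approximation
  area / midline length, which recovers the true width of a gently curved
  ribbon to well under 2%.

The synthetic morphology generator grows planar binary trees (matching the
2-D nature of the measurements), scales them to a target arbor height, and
draws branchlet spine counts as Poisson with mean density × length, so
Sholl counts and densities have known ground truth.

## Statistics

The statistics layer mirrors the reporting conventions of strain × factor
designs: equal-variance unpaired t-tests by default (Welch by flag),
two-way ANOVA via `aov()`, repeated measures via error strata
(`Error(animal_id/factor2)`) with no sphericity correction by default, and
Bonferroni adjustment `min(1, p·m)` over the planned per-level family. A
one-level design collapses to a one-way ANOVA whose F equals the squared
pooled t — the suite requires agreement to 1e-9 relative tolerance — and
the repeated-measures strain test on 500 null synthetic cohorts is required
to hold its nominal 5% type-I rate within Monte-Carlo error.

```{r stats}
co <- generate_cohort(data.frame(strain = c("C57", "BTBR"), sex = "M", n = 8),
                      effects = list(spine_density = -0.4), seed = 3)
stats_report(co, measure = "spine_density")$anova
```

## Problem sizes and what the tests show

The validation suite runs at deliberately chosen desk scales: schedule
invariants over 100 seeds; classifier–oracle agreement over 10,000
randomised trials; affine invariance over 1,000 trials; Sholl exactness
over 100 random trees; the full video pipeline (render → extract → score →
aggregate) over 8 animals per group for the three terminal sessions at
60 Hz with a 40 × 30 px camera; and 500 replicate null cohorts for ANOVA
calibration. Recovery criteria are stated in sampling units (binomial or
Poisson standard errors at those sizes), so they test correctness, not
luck.

The generator emulates the statistical structure of the assay — trial
composition, UR/CR timing and amplitudes, exclusion-triggering artefacts,
Poisson spine counts — but not camera optics, biomechanics of the lid,
3-D dendritic geometry, or histological staining variability. Passing the
suite therefore demonstrates that the scoring and measurement code is
correct under the stated model, not that the model captures every property
of real recordings; with real videos the ROI and threshold remain the
experimenter's responsibility (both are exposed as configuration).

## Known limitations

* Video input is multi-page TIFF (plus a YAML sidecar for timestamps);
  interactive ROI tracing, pupil tracking and learned segmentation are out
  of scope.
* CR amplitude and latency-to-onset metrics are not computed.
* Morphologies are planar; no attempt is made to correct Sholl counts for
  z-projection.
* Folia counts are consumed as supplied; the package does not segment
  folia from images.
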