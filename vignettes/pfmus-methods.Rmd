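---
title: "Automatic evaluation of pelvic floor muscle contraction from bladder ultrasound: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic evaluation of pelvic floor muscle contraction from bladder ultrasound: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pelvic floor muscle training (PFMT) works best with biofeedback: the
trainee needs confirmation that a contraction was actually performed
correctly. Transabdominal B-mode ultrasound of the bladder offers a
non-invasive signal — a correct pelvic floor muscle (PFM) contraction
elevates the bladder base (the inferior bladder wall moves cranially),
while failed attempts typically displace the whole bladder through
abdominal breathing or probe motion without any differential base
movement. Reading such videos requires expertise, so an automatic
classifier of contraction quality is the enabling component for
home-based biofeedback.

`pfmus` implements that analysis chain as a reusable, tested package:

1. **Segmentation** of the anechoic (dark) bladder region per frame.
2. **Five landmarks** per contour: the endpoints of the maximum bladder
   diameter (`Left`, `Right`), its midpoint (`Center`), and the vertical
   bladder-wall extents through that midpoint (`Top`, `Bottom`).
3. **Stride-sampled time series** of the ten landmark coordinates per
   contraction clip (every 10th frame of a 24 fps video, i.e. 2.4 Hz).
4. **Featurization**: a fixed catalogue of per-channel time-series
   features plus two bespoke quantities — the bladder-area surrogate
   `|Right_x − Left_x| · |Bottom_y − Top_y|` (a urine-volume proxy) and
   the bladder-base elevation `max(Bottom_y) − min(Bottom_y)`.
5. **Four-class supervised protocol**: stratified 70/30 split, 5-fold
   cross-validated comparison of gradient boosting, random forest and a
   multinomial-logistic reference, grid-search tuning of the winner,
   held-out evaluation (accuracy, macro one-vs-rest AUC, macro recall /
   precision / F1 from the one-vs-rest confusion-matrix formulas) and a
   top-10 feature-importance ranking.

The four classes are `UNDETERMINABLE` (unreadable video), `CORRECT`,
`FAILURE` (attempted contraction without base elevation) and `NONE`.

Because clinical recordings of this kind are not publicly available, the
package ships a seeded synthetic generator that emulates the statistical
structure this analysis relies on, with full ground truth. The generator
is first-class, tested code: it defines the study conditions under which
every quantitative claim in the test suite is made.

## The synthetic generator

A recording is `n_contractions` cycles of `contraction_s` + `rest_s`
seconds rendered at `fps` frames/s, with one *contract* and one *rest*
call per cycle in the event log. The bladder is an ellipse-derived
polygon (120 vertices) rendered dark (urine is anechoic) on a bright
background multiplied by a unit-mean gamma speckle field of variance
`speckle_var`. Image coordinates follow the raster convention — origin
top-left, x rightward, y downward, 0-based — so base *elevation* means
*decreasing* `Bottom_y`. All in-scope features (extrema differences,
mean-removed spectra) are invariant to this orientation choice.

Class-specific motion, driven by a raised-cosine activation $s(t) =
\tfrac12\bigl(1 - \cos 2\pi\frac{t-t_0}{t_1-t_0}\bigr)$ supported on the
contraction interval $[t_0, t_1]$ (smooth and compactly supported; no
kinematic profile is prescribed by the physiology, so the simplest
smooth bump is used):

* `CORRECT` — the inferior half of the wall moves up by
  `base_amplitude_px`·s(t)·max(0, sin θ); the superior wall is static.
  The true Bottom landmark swings by exactly `base_amplitude_px` per
  cycle.
* `FAILURE` — the whole contour translates rigidly by
  `translation_amplitude_px`·s(t) vertically plus a horizontal sinusoid
  at `breathing_freq_hz` (amplitude half the translation): bladder
  *position* changes, but the base never moves relative to the top.
  This encodes the clinically observed failure mode — whole-bladder
  displacement from abdominal breathing and probe motion.
* `NONE` — static.
* `UNDETERMINABLE` — static motion, but each frame inside the cycle
  window is corrupted with probability `dropout_prob` by a bright
  occluding band over the inferior bladder boundary, which makes
  segmentation fail. The class is defined by unreadability, not by a
  distinct motion pattern, so corruption rather than kinematics
  generates it.

Isotropic Gaussian vertex jitter (`jitter_px`) is added to every
rendered contour as measurement noise; ground-truth contours and
landmark trajectories are the jitter-free motion model. Jitter is drawn
even when an amplitude is zero, so zero-amplitude configurations are
RNG-identical to `NONE` under the same seed — a tested collapse
property.

### Default study conditions

| parameter | default | rationale |
|---|---|---|
| frame size | 128 × 128 px | geometry is resolution-independent; desk-scale frames keep simulation tractable |
| `fps` | 24 | the acquisition rate of the handheld probe |
| cycles per recording | 4 | the protocol calls 4–10 contractions per recording; the desk-scale default uses the lower bound |
| `contraction_s`, `rest_s` | 3 s, 3 s | a typical contract-hold-relax cue cadence |
| semi-axes | (32, 20) px, scaled ±25% per recording | different urine volumes between recordings |
| `base_amplitude_px` | 10 | clearly above noise; real displacement in pixels is not quantified, so this is a free parameter |
| `translation_amplitude_px` | 8 | same order as the base elevation — failures and correct contractions must not be separable by motion *energy* alone |
| `breathing_freq_hz` | 0.25 | ~15 breaths/min |
| `jitter_px` | 0.5 | sub-pixel boundary noise |
| `speckle_var` | 0.02 | keeps Otsu segmentation reliable on clean frames |
| `dropout_prob` | 0.6 | undeterminable clips are majority-corrupted: their features are largely missing, which is what makes them unreadable |

The experiment default is 60 recordings across 20 participants (three
per participant, emulating repeat visits) × 4 cycles = 240 clips,
balanced over the four classes.

### What the generator does *not* emulate

No physical wave propagation, probe geometry, 3-D anatomy, shadowing,
or inter-patient anatomical variation; the bladder is convex and
star-shaped; jitter is white rather than spatially correlated. Passing
tests therefore demonstrate that the *pipeline* is correct and that the
protocol recovers class structure when the assumed motion signatures are
present — they say nothing about segmentation robustness or classifier
accuracy on real clinical images.

## Segmentation and landmarks

Segmentation is a deliberately simple stand-in for the external
bladder-extraction system used with real recordings (whose internals are
not public): Otsu threshold → dark mask → morphological closing (disc,
5 px) → largest connected component → traced outer boundary. Two guards
make failure explicit rather than silent: the component must reach
`min_area_frac` (1%) of the frame, and it must be *anechoic* — mean
intensity below `max_contrast` (0.5) of the rest of the frame. The
traced boundary is offset outward by half a pixel because boundary pixel
centres sit, on average, half a pixel inside the true edge; this removes
a ~perimeter/2 area bias and brings the enclosed area of a noiseless
ellipse within 2% of πab. Failure is a status flag, never a zero-area
contour, and propagates downstream as a missing sample.

The maximum-diameter chord is found by exhaustive search over all vertex
pairs (the quantity is defined, not an algorithm; rotating calipers
would be an optimization but the exhaustive form is the reference and is
fast at contour sizes of a few hundred vertices). Deterministic
tie-breaks: `Left` is the endpoint with smaller x (then smaller y), and
equal-length chords resolve to the lexicographically smallest
(left, right) tuple. Vertical extents interpolate along edges and take
the global min/max y among all crossings, so concave contours with more
than two crossings are handled.

Stride sampling starts at the clip's first frame (the convention is
fixed for reproducibility), giving samples at frames 0, 10, 20, … and a
2.4 Hz effective rate at the defaults. Clips are call-to-call windows
padded by 0.5 s per side (clamped to the recording), capturing onset and
offset motion.

## Featurization and missing values

The catalogue (`featureCatalogue()`, version `pfmus-catalogue-1`) is a
fixed set of 19 per-channel features: moments (mean, min, max, median,
SD, variance, range), dynamics (mean absolute change, count above mean,
lag-1 autocorrelation, linear trend slope, strict peak counts with
support 1 and 3) and spectral summaries of the mean-removed series
(|FFT| coefficients k = 1..4, dominant frequency in Hz, spectral
energy). Applied to the 10 coordinate channels plus the Area channel,
plus the bespoke base-elevation scalar, a clip yields 11 × 19 + 1 = 210
features. A large external feature library could generate thousands of
features here; a fixed, documented catalogue was chosen instead so that
every feature has a testable definition, while still representing the
signals that matter for this problem (base-elevation extrema and the
Bottom_y spectrum).

Missing-value semantics: moment-type features are computed on the
non-missing samples (each with a minimum sample count: 1 for locations,
2 for spreads and slope, 3 for the autocorrelation, 2n+1 for support-n
peaks); spectral features require a gap-free series of ≥ 4 samples,
because a DFT of gapped data is ill-defined. Clips with *zero* usable
samples are dropped as rows (logged); afterwards any feature column
still containing a missing value anywhere in the dataset is excluded
column-wise, so the table entering the classifier is complete. Exclusion
is per-column, not per-row, mirroring how a feature count shrinks after
missing-value exclusion while the clip count stays fixed. Under the
default conditions the undeterminable clips are what drives exclusion:
their gaps remove all spectral columns (and, depending on the seed, the
higher-order moment columns), while the location/spread/count features
survive.

## Classification protocol

The split is stratified by class at the clip level by default,
reflecting the original protocol; a participant-grouped split is
available (`group_by_participant`) because clip-level splitting leaks
participant identity between train and test — fidelity first, rigor
available. Model comparison uses stratified 5-fold cross-validation over
a roster of three algorithms (gradient boosting via xgboost, random
forest via ranger, and the multinomial-logistic reference via nnet);
the roster is configurable, and the logistic reference is always
included in the ranking. Grid search evaluates every combination with
the same fold assignment, ties resolving to the first-listed
combination, and refits the winner on the full training set.

Metrics follow the one-vs-rest confusion-matrix formulas: per class,
TP = C[c,c], FP = column sum − TP, FN = row sum − TP, TN = total −
TP − FP − FN; accuracy (TP+TN)/total, recall TP/(TP+FN), precision
TP/(TP+FP), F1 = 2PR/(P+R). Macro (unweighted) averaging is used for
recall/precision/F1 and for the one-vs-rest AUC — the most common
multiclass convention, and the one consistent with a macro recall
falling below overall accuracy on imbalanced classes. 0/0 ratios are
reported as 0 and flagged, so degenerate predictors still produce
defined metrics. Feature importances use the ensemble's split-gain
(impurity for the forest), ties broken alphabetically. For importance
*structure* readouts the random forest is the more legible instrument:
boosting tends to solve a cleanly separable contrast with a single
split variable (gain 1.0 on one feature), whereas the forest's
per-split feature subsampling spreads importance across all the
correlated informative features and yields a full top-10 ranking.

## Numerical choices and degenerate inputs

* Scanline rasterization fills pixel centres with even-odd parity and a
  half-open row rule, so shared edges are never double-counted;
  odd crossing counts (tangencies) drop the unpaired crossing.
* The multinomial-logistic reference standardizes features internally
  (zero-variance columns get unit scale) — the tree ensembles are
  scale-free.
* All stochastic stages (simulation, splits, folds, fits) derive their
  seeds from one experiment seed, so a run is reproducible end to end;
  the feature table serializes byte-identically across repeated runs.
* Degenerate cases are contracts, not accidents: empty grids, unknown
  labels, non-grayscale frames, contours exceeding frame bounds, <3
  vertex contours, and all-failed clips raise errors (or emit fully
  missing series where the spec of the operation is to continue).
* A single recording cannot be split and cross-validated: the run
  aborts at the stage that first detects it, naming the stage. With the
  stratified rounding rule a singleton class stays in the training
  side, so detection happens at cross-validation rather than at the
  split.

## Problem sizes used by the tests

The test suite and the acceptance script run the default 60-recording /
240-clip experiment (about 35,000 rendered frames, a few minutes of
compute), a 10-run importance study on two-class (CORRECT vs NONE)
datasets of 8 recordings at 96 × 96 px, and a 20-seed permutation null
on the default feature table. These sizes were chosen as the smallest
at which the protocol's behaviour is stable across seeds.

## Known limitations

* Synthetic validation only: no claim transfers to clinical images
  without re-validation of segmentation and features.
* The segmenter assumes a single dominant anechoic structure; bowel gas
  shadows, probe decoupling, or a second fluid structure would defeat
  it (on real data the external extraction system would take its
  place).
* Undeterminable clips are modelled purely as segmentation dropout;
  real unreadable videos may instead yield *wrong* contours, which this
  pipeline would not flag.
* The importance ranking identifies channels, not physiology: with only
  base motion differing between classes, base-related features dominate
  by construction, which mirrors — but does not validate — the clinical
  reading.

## A worked run

```{r}
library(pfmus)

cfg <- experimentConfig(seed = 1L)
report <- runExperiment(cfg)
report            # CV ranking, held-out metrics, confusion, importances

# inspect one synthetic recording
rec <- simulateRecording(simulationConfig(seed = 7L),
                         c("CORRECT", "NONE", "FAILURE", "UNDETERMINABLE"))
clips <- trimClips(rec)
series <- extractSeries(clips[[1]])
baseElevation(series)
```
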