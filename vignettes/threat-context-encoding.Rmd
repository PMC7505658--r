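---
title: "Analysing social threat and spatial context encoding in hypothalamic calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing social threat and spatial context encoding in hypothalamic calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialscope)
```

## The experimental setting

`socialscope` analyses single-neuron calcium imaging recorded from the
ventrolateral ventromedial hypothalamus (VMHvl) of mice undergoing social
defeat assays.  A typical experiment places the subject in a three-part
apparatus (home chamber, corridor, far chamber).  On the defeat day the
animal is enclosed in the far chamber with an aggressor; after the defeat
the door is opened and the animal expresses approach–avoidance behavior
(risk assessment, flight).  A day later the animal re-explores the empty
apparatus (context session), and in separate sessions it may itself attack
a subordinate intruder in its home cage (aggression session).

The scientific questions the pipeline addresses are: which neurons respond
to which behavioral or spatial predicate (responder classification); do
responses change abruptly at behavior onsets (peri-event statistics); does
the population activity separate spatial contexts or drift between
repeated sessions (ensemble analysis); and do responder sets overlap more
than chance (overlap statistics).

## From movies to traces

Raw endoscope movies are preprocessed in four steps, each exposed as a
function and bundled in `preprocess_stack()`:

1. **Background estimation** (`estimate_background()`): the smooth,
   out-of-focus component of each frame is the Gaussian-smoothed frame
   with `sigma = low_cut / 4` pixels (replicate boundary).  The defaults
   `low_cut = 100`, `high_cut = 10000` mirror the band limits commonly
   used with ImageJ-style bandpass filtering of endoscope stacks; since
   `high_cut` exceeds any frame, only the lower band is operative, and the
   parameter pair is validated rather than applied twice.
2. **Background division** (`divide_background()`): each frame is divided
   by its background, flattening illumination so that flat regions sit at
   ratio 1.
3. **Translation registration** (`register_translation()`): each frame is
   aligned to the first frame by the integer-pixel shift maximizing
   normalized cross-correlation.  Only rigid translations are modeled —
   the standard choice for head-mounted miniscope data where slow lateral
   drift dominates.  The reported `shifts` are the detected displacement
   of each frame; their negatives are applied.  Sub-pixel registration is
   deliberately out of scope.
4. **ROI extraction and ΔF/F** (`extract_traces()`, `compute_dff()`):
   mean in-ROI intensity per frame, then `(x − F)/F` with `F` the
   whole-recording mean, so every ΔF/F trace has mean zero by
   construction.

ROIs drawn on one session are carried to later sessions with
`track_rois()`, which searches a single global translation of the mask
(maximizing summed max-projection brightness under the mask) and drops
ROIs that no longer cover a bright source; uncovered bright components
become new ROIs.  Per-ROI deformation is not modeled, matching the
practice of projecting one mask onto each recording.

## Behavioral predicates

Ethograms are interval tables (`onset_s`, `offset_s`, `behavior`) over a
twelve-word vocabulary (`behavior_vocabulary`).  Calcium frame `f` covers
`[f/rate, (f+1)/rate)`; a frame is labeled with a behavior when more than
half of its window overlaps that behavior's intervals.  The 50% rule is
symmetric and frame-rate independent; no threshold is stated in the
literature for this rasterization, so the choice is documented here.

Four predicate constructors convert annotations into frame labels:

* `behavior_predicate()` — positive during the behavior, negative
  elsewhere; the bout count is carried along because recordings with
  fewer than two instances are excluded from classification.
* `flight_predicate()` — the 2 s before each flight onset is negative,
  the 2 s after positive, everything else excluded.  Frames claimed
  positive by one flight and negative by another are excluded rather than
  prioritized, keeping both label sets clean.
* `chamber_predicate()` — positive in the target chamber, negative
  elsewhere.  Corridor frames count as negative: the corridor shading
  seen in published figures is treated as visualization, not labeling.
* `phase_predicate()` — positive during the enclosed-defeat phase,
  negative during the post-defeat approach–avoidance phase, habituation
  excluded; this drives the tonic Social+/Social− classification.

## Responder classification

For each neuron and predicate the area under the ROC curve (auROC) is
computed by the rank-sum identity with average ranks, so ties contribute
one half.  The null distribution comes from shuffling the frame labels
1000 times; a neuron is classified `+` when its (day-averaged) auROC
exceeds 0.65 **and** lies at least 3 null SDs from the null mean, `−`
below 0.35 under the same SD rule, and `none` otherwise.  Both cutoffs
and the dual criterion follow the published procedure.  Plain label
permutation is used for the null exactly as described; because white
shuffles ignore temporal autocorrelation the null SD is, if anything,
optimistic, which the dual criterion's fixed 0.65/0.35 cutoffs guard
against in practice.

When several recordings of the same neuron exist, auROCs are averaged
across recordings first and the averaged value is classified against a
pooled null (mean of null means; SDs pooled by root mean square).  The
choice to pool rather than re-shuffle the averaged statistic is recorded
here: the published text states that auROCs were averaged across days but
not how the null was combined; the RMS pool is the variance-correct
combination when each day contributes equally.  `not_evaluable` (no
eligible recording) is kept distinct from `none` throughout.

In `classify_all()` the 1000 label permutations are shared across the
neurons of one recording–predicate pair (a matrix product over the rank
matrix).  Each neuron still receives a valid permutation null — only the
Monte-Carlo draws are common — and the population run is an order of
magnitude faster.

## Peri-event statistics

Traces are z-scored per recording (population-SD denominator), segments
are cut around event onsets (default 5 s before/after, configurable), and
per-trial before/after means are compared with a two-sided Wilcoxon
signed-rank test.  The test is implemented directly: zeros are dropped
(all-zero differences give `p = 1` by convention), tied magnitudes
receive average ranks, and the exact distribution of the signed-rank sum
is computed by dynamic programming over doubled ranks for up to 25
trials, with a tie-corrected normal approximation above.  The direct
implementation exists because the required conventions (ties, zeros,
exactness) are outside the exact path of the stock test function; it is
validated against full sign-pattern enumeration in the test suite.

## Ensemble analysis

Frames are expressed as vectors of z-scored activity over the neurons
common to all compared recordings (`build_frame_dataset()`), optionally
restricted to frames of close social encounter
(`close_contact_frames()`: defeat, upright, orientation, sniffing,
follow).  `fit_lda()` solves the Fisher criterion with the pooled
within-class scatter via symmetric whitening, using a pseudo-inverse when
the scatter is singular, and projects frames onto the leading
`n_labels − 1` discriminants.  Cluster separation
(`cluster_distance()`) is the mean Euclidean distance between every frame
of one cluster and every frame of the others, computed in the full
discriminant space rather than the 2-D visualization plane — the
distance is then monotone in all discriminative directions, not only the
two plotted ones.

Chamber encoding before vs after defeat is compared per subject with a
paired two-sided t-test on Home–Far cluster distances
(`compare_separation()`); zero-variance difference vectors are flagged
explicitly rather than producing an unstable t statistic.

### Session-remodeling test

`session_separation_ks()` asks whether ensemble activity occupies
different regions across two sessions of the same kind, via a two-sample
Kolmogorov–Smirnov test on first-discriminant projections.  The naive
version — fit the LDA on all frames of both sessions and KS-test the same
frames — is anti-conservative for three reasons, which we quantified on
synthetic stable pairs (identical tuning across sessions):

1. the discriminant is chosen to separate the very frames being tested;
2. frames within a bout are serially dependent (the indicator kernel has
   a ~2 s decay), so the nominal frame count overstates the information;
3. bout counts and durations are random per session, so the *behavior
   composition* of the frame sets differs persistently between sessions
   even when tuning is identical.

The default estimator therefore (i) splits each session's restricted
frames into contiguous blocks (bouts) and fits the discriminant on
alternate blocks only; (ii) applies the KS test to held-out blocks
thinned to one frame per second; and (iii) when per-frame strata are
supplied (`behavior_signature()` labels), balances the held-out sets
across sessions within stratum × within-block-position × preceding-gap
cells, so that the composition confound is removed by matching rather
than assumption.  Because bouts are exchangeable draws within a session,
held-out blocks of the two sessions are identically distributed under
the no-remodeling null, while a genuine tuning change persists across
blocks and is detected.  On synthetic data this estimator rejects a
stable pair in roughly 1 of 20 runs at α = 0.05 and detects 50%
tuning remodeling at p < 10⁻³ in every run we simulated.  The in-sample
variant is retained (`holdout = "none"`) for descriptive use; its
p-value should be read as a separation index, not a calibrated test.

`decode_sessions()` is the predictive counterpart: stratified k-fold
cross-validated LDA classification of session labels, built on the
reference `MASS::lda` implementation.

## Overlap statistics

Responder sets are intersected over the neurons evaluable for all
compared predicates (`common_universe()`), following the convention that
every Venn analysis has its own universe.  Two conventions are
reproduced deliberately and should not be "fixed": the observed overlap
fraction is reported **conditionally** (`|A∩B| / |A|`, e.g. "81/152 =
53%"), while the chance level is the **unconditional** product of the
per-predicate responsive proportions (`chance_overlap()`).  The two are
on different scales; the mismatch reproduces how such results are
reported.  Significance uses the classic two-sided Fisher exact test.
Chance values are computed from headline per-predicate proportions by
default because that reproduces the published numbers; universe-restricted
proportions can be supplied instead via the `chance` argument.

## The synthetic-experiment generator

Every stage is validated against `generate_experiment()`, which plants
known ground truth:

* **Ethograms** — bout counts per behavior are Poisson with mean
  `bout_rate_hz × duration` (default 0.02 Hz, i.e. ~12 bouts per behavior
  in a 10-min session, matching the cadence of repeated attacks in a
  defeat session); durations are exponential (mean `bout_duration_s`,
  default 5 s); bouts are placed without overlap inside the phase window
  where the behavior can occur.  Defeat sessions have a
  habituation / enclosed-defeat / approach–avoidance phase structure
  (20% / 40% / 40% of the session).  Every relevant behavior is
  guaranteed ≥ 2 bouts (resampled, bounded retries), since 2 instances is
  the analysis eligibility floor.
* **Chamber tracks** — a semi-Markov walk home ↔ corridor ↔ far with
  exponential dwells (25 s chambers, 5 s corridor), resampled until every
  compartment is visited twice.
* **Traces** — each neuron has one primary class (tonic: Social±, Far+,
  Home+; phasic: Defeat±, Assessment±, Flight±, Sniff+, Attack+; or
  none).  The signal is `amplitude × sign × (kernel ∗ drive)` where the
  kernel is a difference of exponentials with rise 0.2 s and decay 1.8 s
  (GCaMP6s-like; the indicator is named in the source protocols but its
  kinetics are not, so slow-indicator textbook values are used),
  normalized to unit sum so tonic drives plateau at `amplitude`.
  Gaussian noise of SD `noise_sd` (default 0.2, i.e. signal-to-noise 5
  with the default amplitude 1 — the upper end of realistic miniscope
  transients) is added.  Default class fractions echo the relative
  prevalence of the main responder types with a non-responder remainder.
* **Movies** — neurons are Gaussian spots (brightness `1 + trace`) over a
  smoothed low-spatial-frequency background, with optional planted
  integer drift; the ground-truth mask is emitted alongside.
* **Remodeling** — for the second of two like sessions exactly
  `round(remodel_fraction × n)` neurons have their class resampled.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: sub-pixel and non-rigid motion, neuropil
and overlapping-cell contamination, photobleaching, indicator
nonlinearity, behaviorally correlated artifacts, and non-Poisson bout
statistics.  The generator exists to verify the estimators' logic
(planted-parameter recovery, calibration of nulls), not to claim realism
of the simulated biology.

## Problem sizes and numerical choices

The test-suite and acceptance runs use 10 Hz recordings of 40–200
neurons and 600 s sessions (6000 frames), 1000 label shuffles, and five
seeded replicate cohorts per property — comfortably sized for the
population statistics being checked while keeping a full run in the
minutes range.  Numerical conventions: frame windows are half-open;
times are seconds; pixel shifts are integer; the LDA eigenproblem is
solved on the symmetrized whitened scatter with a relative eigenvalue
tolerance of 1e-10; auROC ties use average ranks; Fisher p-values follow
the "sum of tables no more probable than observed" two-sided rule; KS
p-values use the stock two-sample implementation (exact where its
small-sample path applies).

## Worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(
  n_neurons = 40,
  session_plan = data.frame(kind = c("defeat", "context"),
                            duration_s = c(600, 600)),
  seed = 1)
exp <- generate_experiment(cfg)

s <- exp$sessions[["defeat_1"]]
nf <- ncol(s$recording$traces)
preds <- list(
  defeat = behavior_predicate(s$track, "defeat", cfg$frame_rate_hz, nf),
  flight = flight_predicate(s$track, cfg$frame_rate_hz, nf))
tab <- classify_all(list(s$recording), list(preds), seed = 1)
table(tab$predicate, tab$class)

ctx <- exp$sessions[["context_1"]]
ds <- build_frame_dataset(list(ctx$recording),
                          labels = list(ctx$track$chamber_track))
cluster_distance(fit_lda(ds), "home", others = "far")
```

## Known limitations

* No automated ROI detection (CNMF-E-style factorization), non-rigid
  registration, or neuropil decontamination beyond background division.
* No multiple-testing correction across neurons or comparisons — matching
  the published analysis, which applies none.
* The permutation null ignores temporal autocorrelation by design
  (fidelity to the published procedure); an autocorrelation-preserving
  null would be more conservative for tonic predicates.
* Venn analyses support at most three sets.
* The chamber predicate treats corridor-adjacent zones as negative; if
  the original analysis counted them as positive, far-chamber responder
  counts would shift slightly (ambiguous in the source figures).
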