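---
title: "Methods: lick-locked choice activity in auditory cortex populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lick-locked choice activity in auditory cortex populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lickchoice)
```

## The scientific problem

Head-fixed mice learn a delayed tone-detection task: a 6 or 16 kHz tone is
followed by a 1.5 s delay window (licking here is an early lick, EL), a
1.5 s high-water window (a correctly timed lick, HIT, earns a large reward
one second after the lick), and a 1.5 s low-water window (a late lick, LL,
meets a small droplet dispensed unconditionally at onset + 3 s). Catch
trials without a tone yield false alarms (FA) or correct rejections (CR).
Trials are separated by 5–10 s of silence drawn from a truncated
exponential, so tone timing cannot be anticipated. Sessions are grouped
into six experience bins: bins 1–3 are a Pavlovian training phase (reward
at onset + 3 s regardless of lick timing), bins 4–6 the testing phase under
the timing rules above.

Two-photon calcium imaging of layer-2/3 auditory cortex yields, after
motion correction, segmentation and spike deconvolution (all upstream of
this package), a non-negative event-rate matrix (cells × frames, 30 Hz)
per session, together with a 500 Hz lick train, tone onsets and trial
outcomes. The package asks how decision-related, lick-locked activity in
this population develops with task experience: functional cell classes,
their pairwise noise correlations, the geometry of their latent dynamics
across bins, and the decodability of lick context.

## Windows and frame arithmetic

All peri-event statistics use half-open intervals on a 1-based frame grid
with nearest-frame rounding, so 165 ms is exactly 5 frames at 30 Hz and
every 330 ms window is exactly 10 frames. The lick-onset frame counts as
the first post-lick frame. The window set:

* *during*: [−165, +165) ms around lick onset;
* *before* (baseline): [−495, −165) ms; *farther*: [−825, −495) ms —
  contiguous, disjoint, equal length;
* sound windows: 500 ms before/after tone onset;
* lick-probability windows: 4.7 s after onset and the matched 4.7 s before
  it, of which 3.7 s draws on the preceding quiet period. When a quiet
  period is shorter than 3.7 s the available span is used and recorded.

Events whose windows would leave the recording are dropped and counted;
every stage reports `used + dropped = total`.

Lick times are down-sampled to the frame grid by flooring
(`floor(t·30)/30`), collapsing same-frame licks, mirroring the reduction
of 500 Hz behavior data to the neural sampling rate.

## Behavioral statistics

Outcomes are assigned from the first post-onset lick by interval
membership; in the training phase labels are still assigned (bookkeeping)
while reward is unconditional. Sensitivity is d′ = z(H) − z(F) with H the
HIT rate over tone trials and F the FA rate over catch trials; rates are
clipped to [1/(2n), 1 − 1/(2n)] so extreme rates stay finite (the standard
log-linear alternatives would change d′ by a constant offset here and were
rejected for simplicity).

Lick bursts are maximal runs of ≥2 licks whose inter-lick pauses are
≤500 ms (a pause *greater* than 500 ms separates bursts, so a gap of
exactly 0.5 s stays inside a burst); single licks are singletons, excluded
from burst-length analyses but retained as peri-lick anchors. Burst
duration categories are half-open and low-inclusive — native 500 Hz:
short [0.002, 0.15), intermediate [0.15, 0.5), long [0.5, 1); 30 Hz grid:
short [0.033, 0.2), intermediate [0.2, 0.5), long [0.5, 1.33) — durations
outside the outer bounds are excluded.

## Cell classification

Anchors are *isolated licks*: no lick or stimulus onset in the open
330 ms interval before the lick (exactly 330 ms counts as clear). Each
anchor is tagged PRE_SOUND or POST_SOUND by whether it falls within 4.7 s
of the governing tone onset. Cells averaging under 1 event/s across the
session are excluded.

Per cell, the mean rate in the during window is paired with the mean rate
in the preceding 330 ms baseline window across anchors and tested with a
two-sided Wilcoxon signed-rank test; significant cells are ENHANCED or
SUPPRESSED by the sign of the median paired difference. Defaults:
α = 0.05, no correction across cells (class *fractions* are the readout;
a `p_adjust` option exposes correction), minimum 10 anchors per context.
We use the normal approximation without continuity correction: deconvolved
rates are heavily tied and zero-inflated, so exact p-values are
unavailable; at ≥10 pairs the approximation is accurate, and with Poisson-
like data the test errs conservative (the type-I calibration tests
therefore run on the generator's continuous noise law).

Sound-responsive cells are flagged by the same paired test on 500 ms
pre/post tone windows across tone trials. Peri-lick summaries report each
cell's z-scored trace (mean/SD over the peri-event concatenation of all
anchors — not the whole session; zero-variance cells are omitted from z
summaries only), the absolute z peak within ±165 ms, and raw pre/post
means with delta and the symmetric proportional change
(post − pre)/(post + pre + 1e−9); ε guards 0/0 and the symmetric index is
bounded in [−1, 1]. Spatial structure is probed by within-group and
sound-responsive-cross-group pairwise Euclidean distances of cell
coordinates.

## Noise correlations

For each window (during/before/farther) and outcome subset (all, HIT, EL,
LL), the trial × cell matrix of window means is built from isolated
post-sound anchors; trials with zero activity across the *entire
population* in the window are discarded (the literal reading of the
discard rule; a per-pair alternative would change n per pair). Cells'
trial vectors are z-scored within the (session, window, outcome) cell —
"normalized activity" is not further specified, and z-scoring removes
mean-rate differences; a raw option is retained. Pearson correlations are
averaged by group pairing. At least 3 trials are required; smaller cells
are reported missing, never imputed. Window and outcome contrasts are
summarized with mean differences and a two-way ANOVA with Bonferroni post
hocs, as descriptive utilities.

## Latent dynamics, CCA alignment and distances

Latents are built per session: cells are not matched across days (the same
area is re-imaged, not necessarily the same cells), so a pooled-bin matrix
would mix incompatible cell spaces. Trials of the HIT and LL conditions
are equalized by seeded subsampling, cut to a fixed peri-lick grid
(−0.5 s to +1.0 s, 45 frames), and concatenated in condition-ordered
blocks. The PCA basis is taken from the *condition-averaged* trajectories
and single-trial segments are boxcar-smoothed (5 frames) before
projection: with spike-like event rates the per-frame noise variance
(~30 × rate) dwarfs the lick-locked signal variance, so the top principal
components of the raw concatenated matrix are noise directions and carry
no alignable structure; the trajectory basis is the standard construction
for latent population dynamics. The spec-literal concatenated-matrix basis
remains available (`basis = "concatenated"`). Default dimensionality
m = 10; only the three leading canonical correlations are reported.

Bins 5 and 6 are aligned to bin 4 session-by-session (i-th session with
i-th session). Rows are matched across the pair by resampling both sides
to the common per-condition trial count on the identical peri-lick grid.
CCA (`stats::cancor`) yields the canonical transformations and
correlations. The upper bound is the mean over 500 within-day split-half
CCAs of the reference bin (halves matched by condition); the lower bound
is the top-3 absolute correlations between corresponding unaligned latent
dimensions.

Condition distances are computed per peri-lick timepoint between the
HIT and LL mean trajectories, in the aligned space *projected back* to
each side's latent (rate-unit) coordinates and restricted to the three
leading canonical dimensions. Back-projection matters: unit-variance
canonical variates divide away each bin's physical activity scale, which
cancels exactly the experience-dependent growth the comparison is after.
Pre-lick (τ < 0) and post-lick (τ ≥ 0) epochs are reported separately.
Later-bin distances are tested against the reference with a one-sided
t-test over timepoints and a label-permutation test (condition labels
shuffled at the trial level within each bin; 1,000 permutations in the
pipeline, fewer in fast tests).

## Decoding lick phase

One row per isolated lick, features the per-cell during-window means of
the chosen cell group, labels PRE vs POST sound. Class imbalance is
handled by SMOTE-style oversampling: synthetic minority samples
x_i + u·(x_nn − x_i), u ~ U(0,1), x_nn among the k = min(5, n−1) nearest
minority neighbors; originals are never altered. PCA retains the fewest
components reaching 80% cumulative variance; an RBF-kernel SVM
(`e1071::svm`, C = 1, γ = 1/d on scaled features) is evaluated by
stratified 10-fold cross-validation; accuracy is 1 − misclassification.

The default order — oversample, then PCA, then CV — follows the original
procedure and is optimistically biased: synthetic test-fold samples
interpolate training-fold parents. The `per_fold` variant refits
oversampling and PCA inside each training fold, leaving only real samples
in test folds; calibration tests use it, and with it null designs decode
at 0.50 and shuffled labels stay at chance (imbalanced designs drift a few
points above 0.5 because test folds keep the real imbalance). Per-group
decoding repeats the procedure 100 times for an accuracy distribution;
groups are compared by a two-sample permutation test on mean accuracy
(5,000 resamples).

## The synthetic-session generator

The generator stands in for the recorded dataset and defines the study
conditions under which every stage is verified. Firing model per cell and
frame: `rate = baseline · (1 + e_b · A · g(τ) · gate) + sound + shared +
noise`, rectified at zero, with

* `g(τ)`: linear ramp from −165 ms, peak at +100 ms, zero by +330 ms —
  modulation begins before the lick without extra structure;
* `gate`: 1 inside the 4.7 s post-sound period, 0.2 elsewhere (the
  pre-sound leak that makes post-sound licks decodable);
* `e_b` = (0.30, 0.65, 1.00, 0.35, 0.70, 1.05): grows within each phase
  and resets toward the bin-1 level at the bin 3→4 rule change;
* amplitudes A: +1.2 (enhanced), −0.6 (suppressed), ×0.8–1.2 per-cell
  jitter; fractions 0.25/0.15, 20% sound-responsive (independent flag);
* baseline 5 events/s — typical of deconvolved cells passing the 1 event/s
  floor, and high enough that a gain of e·A ≈ 1 is detected in ≥90% of
  sessions with ~60 anchors, the regime the analysis operates in;
* a per-lick shared Gaussian factor (sd 0.25 × baseline × e_b) added to
  each modulated group over the exact 10 frames of the during window —
  planted noise correlations, window-gated, heightening with experience;
* an extra post-lick gain on enhanced cells in HIT trials
  (choice_amp = 2, scaled by its own curve 0.10…1.10) — the HIT-vs-LL
  separation that compounds with experience faster than the overall
  modulation, without which the normalized alignment analysis could not
  see a growing contrast;
* noise: Poisson counts per frame (deconvolved traces are spike-like),
  converted back to events/s; a rectified-Gaussian law is available and is
  used for constructions that need an exactly planted correlation
  (`plantedNoiseCorr()` gives the implied window-mean ρ in closed form).

Behavior: 100 trials/session (matching the scale of ~200 licks per
recorded session), 20% catch, quiet periods 5 + min(Exp(1.5), 5) s,
outcome propensities per bin shifting from EL/MISS-heavy to HIT-heavy,
false-alarm and spontaneous pre-sound burst probabilities declining with
experience, intra-burst licking at ~7 Hz with burst lengths shrinking
across bins. Outcomes are written by running the package's own outcome
classifier on the generated licks, so generator and classifier agree by
construction; the intended outcome is kept in the ground truth for
cross-checks. Cell identities are resampled per session.

What the generator does *not* emulate: calcium-indicator kinetics and
deconvolution artifacts, slow drift and motion residuals, behavioral
states (satiety, disengagement), reward-evoked activity, and any
anatomical organization of the classes (coordinates are uniform).
Passing tests therefore validate the analysis logic and its statistical
calibration under the planted model, not the biological claims on real
data. Effect magnitudes are calibrated only to reproduce qualitative
orderings (the source quantifies none), and defaults are fixed once.

## Numerical choices and degenerate inputs

* Wilcoxon: normal approximation, no continuity correction; all-tied
  pairs give NA → NONE.
* Zero-variance cells: dropped from correlation pairing and z summaries,
  retained in raw summaries, with reasons recorded.
* CCA rank deficiency: dimensions reduced with a warning; canonical
  correlations are clamped to [0, 1] by validity checks.
* Sessions below the anchor or trial minima contribute nothing rather
  than noisy estimates (all-NONE with a flag; bins skipped with a log
  entry).
* All randomness flows from one root seed through named substreams
  (31-bit string hash), so stages are independently reproducible and the
  pipeline is byte-deterministic given config, seed and inputs.
* Analysis problem sizes in the tests (two sessions per bin, 100 cells,
  100 trials) are the package's reference conditions; they run the full
  pipeline in about a minute on a laptop core.

## Known limitations

* The per-session CCA pairing (i-th with i-th) is one of several
  reasonable designs; with many sessions per bin a full cross-pairing
  would use the data better.
* The paper-order decoding pipeline (oversample before CV) is kept as the
  default for fidelity despite its optimism; comparisons between groups
  are unaffected because the bias is shared.
* d′ uses the strict HIT outcome as the hit rate; an alternative
  detection-style reading (any post-sound lick) would shift d′ upward
  without changing trends.
* The 4.7 s pre/post lick-probability window is taken literally from the
  source convention; its relation to the 4.5 s response structure is not
  modeled further.
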