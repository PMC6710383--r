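---
title: "An oscillator-ensemble model of rhythmic sequence learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An oscillator-ensemble model of rhythmic sequence learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscseq)
```

## The model

When a stimulus sequence is repeated, every item recurs rhythmically: in
`-H-V-V-V-V` repeated over and over, the `H` patch recurs once per
sequence, each `V` slot recurs once per sequence, and pixels that look the
same in both patches are driven at the fast item rate. `oscseq` models a
learner that captures this polyphony with ensembles of
discrete-time phase oscillators — one ensemble of `N = 100` oscillators
per input channel (one channel per pixel, plus one auditory channel in the
audiovisual configuration).

Each oscillator carries a phase $\phi \in [0, 2\pi)$ and a frequency $f$
(cycles per time step) and free-runs as

$$\phi(t+1) = \phi(t) + 2\pi f(t) + \eta,$$

with Gaussian phase noise $\eta$. Each input symbol is associated with a
target phase ($\hat\phi_B = \pi/2$, $\hat\phi_W = 3\pi/2$ for black and
white pixels; low/high pitch use the same two phases on the auditory
channel; the bright disc of the crossmodal visual stimulus uses $3\pi/2$).
An oscillator "predicts" a symbol when it occupies that symbol's target
phase at the moment the symbol arrives.

At every non-blank input, each oscillator is classified by the circular
distance $d$ between its phase and the *nearest* target phase:

* **locked** ($d < \theta_{locked} = \pi/60$): dynamically stable; no
  retuning while the input matches its target;
* **locking** ($\theta_{locked} \le d < \theta_{locking} = \pi/6$):
  actively retuned by every input;
* **in transit** (otherwise): left alone — a pool of free oscillators.

A locking oscillator whose nearest target matches the input is reset onto
the target phase and retuned by the signed circular phase error, scaled by
the time $\Delta T$ since its last reset:

$$\phi \leftarrow \hat\phi_i, \qquad
  f \leftarrow f - \frac{\phi - \hat\phi_i}{2\pi\,\Delta T}.$$

This match update is a one-step quantizer: it moves $f\,\Delta T$ to the
nearest integer, so an oscillator repeatedly matched by a period-$P$
stream lands exactly on a harmonic of $1/P$ (the frequency-recovery
property tested in the suite).

When the input *contradicts* the nearest target — including the case of a
locked oscillator whose learned slot suddenly shows the other symbol —
the phase is inverted to $2\pi - \hat\phi_i$ and the period is lengthened
or shortened so the target phase is reached one recurrence slot later or
earlier (see the next section).

Every reset increments the error signal by the oscillator's age since its
previous reset,

$$e(t) = \sum_i \delta_i(t)\,\Delta T_i,$$

pooled by summation across all ensembles. An attuned ensemble is quiet;
an item that violates the learned cycle resets oscillators that had been
stable for a long time, so their large $\Delta T$ makes $e(t)$ spike. The
trial-level decision needs no free parameter: the test item is called
incongruent if and only if $e(t)$ strictly exceeds every earlier error of
the trial.

## The mismatch frequency rule

The mismatch *frequency* update is the one genuinely open design point.
The formulation this model derives from admits two literal readings of
the printed rule,

$$f \leftarrow f + \frac{1}{\Delta T}\Big(f -
    \frac{\phi + (2\pi - \hat\phi_i)}{2\pi\,\Delta T}\Big)
  \quad\text{or}\quad
  f \leftarrow f + \frac{1}{\Delta T}\Big(f -
    \frac{\phi - (2\pi - \hat\phi_i)}{2\pi\,\Delta T}\Big),$$

and both are dynamical *repellers*: the $+f/\Delta T$ term makes the
frequency run away from the fixed point, so under repeated mismatches
frequencies collapse to the floor or grow without bound and the ensemble
never attunes. Neither reading can produce the documented behavior of the
model (stable attractors at 0.5 and 0.1 cycles/step for stable and
alternating pixel streams). Both remain available for inspection via
`eq5_variant = "a"` / `"b"` in `model_params()` and `--eq5-variant` on the
command line.

The default reading (`"intent"`) implements the stated intent of the rule
directly. Let $n = \mathrm{round}(f\,\Delta T)$ be the number of cycles
the oscillator completed since its last reset. On a mismatch the phase is
inverted as printed, and

* if the phase *leads* the target (or the oscillator was locked, in which
  case the violated item must be found at a later slot), the frequency is
  stepped one cycle down on the revisit grid: $f \leftarrow (n-1)/\Delta T$
  — over the same revisit interval the target phase is now reached one
  recurrence slot later;
* if the phase *lags*, one cycle up: $f \leftarrow (n+1)/\Delta T$;
* if the shifted cycle count would fall below one (slow oscillators for
  which a period extension would stall the cycle entirely), the frequency
  instead relaxes toward one cycle per revisit interval,
  $f \leftarrow f - \frac{1}{\Delta T}\big(f - \frac{2\pi + (\phi -
  \hat\phi_i)}{2\pi \Delta T}\big)$ — the literal formula with its leading
  sign read as a relaxation.

This reading is stable at every frequency scale and reproduces the
model's characteristic attractors: ensembles driven by `0W0W0W0W0W`
adopt a modal frequency of 0.5 (one cycle per item pair), ensembles
driven by `0B0W0W0W0W` adopt 0.1 (one cycle per full five-item sequence,
with phase clusters at both target phases), and the auditory-module
ensemble stays in its [5, 6] base band after crossmodal learning. One
deviation from the published account remains: the first auditory input
arrives two steps into the trial, and the match quantizer at
$\Delta T = 2$ places roughly half of the auditory band on half-integer
frequencies (5.5 in particular, which is exactly 44 cycles per 8-step
sequence and therefore permanently stable), so the majority modal bin
across runs lands at 5.1–5.5 rather than exactly 5.0.

## Conventions and numerical choices

* **Time base.** One time step is one stimulus-onset slot; a blank
  occupies its own step, so an item (stimulus + blank) spans two steps.
  This reproduces the printed frequencies: 0.5 = one cycle per item pair,
  0.1 = one cycle per five-item sequence.
* **Order within a step.** Phases advance first (the free-running map),
  then states are classified, then learning updates are applied. The
  reset overwrites the current phase, so an oscillator matched at one
  input is locked at the next input two steps later iff $2f$ is integer —
  which is what anchors 0.5 as the stable-stream attractor.
* **Circular arithmetic.** All phase comparisons use the minimal circular
  distance, and the error terms in the update rules use the minimal
  signed difference in $(-\pi, \pi]$. Phases are wrapped into $[0, 2\pi)$
  after every step.
* **$\Delta T$ bookkeeping.** Reset clocks start at 0, so the first reset
  of an oscillator at step $t$ has $\Delta T = t$; $\Delta T$ is clamped
  to $\ge 1$ inside the update rules and the error sum. $e(t)$ is
  evaluated with the $\Delta T$ values *before* the reset is recorded.
* **Frequency floor.** Frequencies are clamped to $10^{-6}$ cycles/step
  after learning updates; a non-positive frequency has no reading in the
  phase map.
* **Noise.** The default phase noise is $\sigma = 10^{-10}$ radians —
  numerically almost irrelevant, but kept as the model's stated operating
  point; it occasionally frees oscillators frozen exactly on a
  classification threshold.
* **Empty decision history.** The decision rule's maximum over an empty
  set is undefined; with no prior errors the item is accepted as
  congruent. The model is only queried after at least one full
  presentation.
* **Boundary classification.** The state bands are half-open:
  $d = \theta_{locked}$ counts as locking, $d = \theta_{locking}$ as in
  transit. Ties between equidistant targets go to the earlier map entry.

## Stimuli

The generator renders the study's two stimulus families directly as
symbolic per-channel streams; no audio or display-resolution imagery is
produced, and the psychophysical timing (150 ms stimulus, 550 ms blank)
is collapsed onto the two-slot time base.

* **Unimodal sequences**: five items, each a horizontal or vertical Gabor
  patch (32 sequences, indexed by a 5-bit code with H = 0). A patch is an
  ideal grating of 0.5 cycles/degree over a 10° field, thresholded at its
  mean into black/white inside a circular aperture, sampled at 20×20
  pixels (background pixels provide no input). The structural fact that
  drives the cluster analyses — the (H, V) pixel classes are exactly
  {background, BB, WW, BW, WB} — holds by construction because the two
  orientations are transposes of one grating.
* **Crossmodal sequences**: four items, each visual (bright disc above or
  below the midline, 6° across on a 12° field) or auditory (high/low
  pitch), excluding the 32 strictly unimodal combinations (224 sequences).
  Whether the two disc positions share pixels is not determined by the
  published geometry; the default `"disjoint"` geometry has the discs
  touch at the midline (no shared pixels), and the `"overlap"` geometry
  (centers at ±1.5°) realizes the shared-footprint location class at the
  cost of each disc crossing the midline.
* **Test items** continue the cyclic sequence (congruent) or flip the due
  item's label — orientation for unimodal items, feature level (modality
  preserved) for crossmodal items.

Synthetic streams are what the model is *defined* on, so passing tests
demonstrate the internal consistency of the model, not fidelity to human
psychophysics: there is no trial-to-trial timing jitter, no contrast or
volume variation, no attention, and the gray levels of the real stimuli
are binarized.

## Experiments and their reduced scales

`run_trial()` presents the cyclic continuation up to a tested item,
pools $e(t)$ by summation over all ensembles and applies the decision
rule at the test step; a trial is correct when the decision matches the
test item's ground truth. `accuracy_curve()` averages correctness over
sequences, paired congruent/incongruent items and seeds (run $r$ uses
seed `base_seed + r - 1` in every cell, so curves are paired), and
`per_sequence_accuracy()` aggregates by sequence and by sequence entropy
(0, ≈0.72 and ≈0.97 bits — the three complexity levels of the 32
sequences). Fig.-4-scale sweeps (100 runs × 32 sequences × all tested
items at 20×20) are supported but deliberately not exercised by the test
suite; the suite and the acceptance script use reduced problem sizes —
10×10 or smaller grids, 4–50 runs per cell, a handful of tested items —
chosen so that each check still has clear statistical margins.
Accuracy-curve *shape* is verified on these reduced sweeps: early
congruent accuracy exceeds early incongruent accuracy, detection of
violations depends on the tested item's position within the cycle, and
combined accuracy rises far above chance with more repetitions.

The decision rule makes early trials nearly uninformative about
congruence — at the first testable item the reset-weighted error is
dominated by how *rare* the tested pattern was during the single
presentation, which averages out to chance accuracy over the full
sequence set — and this is exactly what the chance-level acceptance
check measures.

## Analysis

`phase_freq_histogram()` bins oscillators on a phase × frequency grid
(bin widths $\pi/12$ and 0.1, frequency bins centered on multiples of
0.1; a value exactly between two centers rounds up). Attuned ensembles
show their rhythm as the modal frequency bin (`dominant_frequency()`,
ties to the lowest bin). `cluster_ensembles()` groups channels whose
ensembles attuned to similar phase-frequency combinations: cosine
similarity between flattened relative histograms, single linkage over
the graph of similarities ≥ 0.9, with channels that never received input
assigned a reserved background cluster. The threshold is deliberately the
only tunable; an `"oracle"` mode that labels channels by their exact
input-stream pattern provides the ground truth against which the
similarity mode is validated. With 100 oscillators per channel the
histograms of richly structured (alternating-input) classes are noisy
samples, so occasional channels fall below 0.9 against all their
classmates and split off as singletons; the similarity mode therefore
sometimes reports 6–8 clusters where the oracle reports 5. We keep the
documented threshold rather than tuning it to the test.

Two known limitations surface in the property suite:

* the *instantaneous* locked count is not strictly monotone under
  congruent input, because an oscillator locked to a slow harmonic (one
  cycle per sequence, say) occupies its target phase only at its own
  recurrence slot and is formally "in transit" at the other inputs; the
  locked count therefore ratchets up to a plateau and then oscillates
  with the sequence period. The monotone-trend claim holds at the
  resolution of repetitions, not steps.
* the auditory modal bin question discussed above.

## Reproducibility

Every randomized computation takes an explicit seed; identical seeds give
bit-identical trajectories, decisions and files. The command-line
interface (`simulate`, `accuracy`, `analyze`, `enumerate`) writes plain
CSV/JSON artifacts plus a resolved `config.yaml` recording the seed, the
package version and the mismatch-rule variant beside every output set.
`scripts/acceptance.R` recomputes the headline quantities (chance-level
start; the 0.5 / 0.1 modal bins; the auditory modal bin) from scratch.
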