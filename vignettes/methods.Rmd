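---
title: "Methods: neuro-fuzzy characterization of arm movements from surface EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neuro-fuzzy characterization of arm movements from surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgfis)
```

## Overview

`semgfis` characterizes seven arm/hand movements from multi-channel surface
electromyography. The pipeline has three stages: preprocessing (per-channel
filtering and windowing down to one RMS value per channel and movement
execution), rule generation and training (subtractive clustering seeding a
Sugeno fuzzy inference system, refined by hybrid ANFIS learning against
fixed per-movement target codes), and decoding (nearest-code assignment of
the continuous network output to a movement class). A synthetic sEMG
generator reproduces the cued acquisition protocol so that every stage can
be exercised, and every claim in this vignette verified, without recorded
data.

This vignette documents the model and its assumptions, the tunable
parameters and their defaults, the numerical choices, what the generator
does and does not emulate, and the known limitations.

## Preprocessing

Surface EMG is a zero-mean stochastic interference signal whose usable
energy lies roughly between 20 and 450 Hz, with the dominant band around
70–300 Hz at 1 kHz sampling. The preprocessing chain per channel, in order:

1. **Calibration** — affine `(x − offset) × gain`. No calibration standard is
   assumed; the default derives the offset from a designated rest segment
   (`rest_calibration()`), with gain 1, and a rest-RMS-normalizing gain as an
   option. Calibration must precede filtering only for the offset bookkeeping;
   the band-pass would remove a static offset anyway.
2. **DC removal** — mean subtraction.
3. **Band-pass 20–450 Hz** — 4th-order Butterworth applied forward-backward
   (`signal::filtfilt`), i.e. zero phase, so that window boundaries are not
   skewed by filter delay. The lower edge rejects motion artifact; the upper
   edge stays below the 500 Hz Nyquist limit of 1 kHz sampling.
4. **Notch 60 Hz** — Butterworth band-stop of width `f0/Q` (default Q = 30,
   i.e. 2 Hz wide), removing power-line pickup while leaving the neighbouring
   EMG band essentially untouched (≤ 1 dB at 100 Hz).
5. **Windowing** — one cue-aligned window per movement execution, spanning
   cue + 0.4 s to cue + 7.5 s: the active portion of the 0.4 / 2.9 / 1.25 /
   2.9 / 0.8 s rest–forward–hold–backward–rest animation, excluding the final
   rest. Windows are clipped to the recording; cues outside it are skipped
   with a warning. An energy-based detector (`detect_active_window()`, moving
   RMS above k × rest RMS, k = 3) is provided as an alternative for data
   without reliable cue times.
6. **RMS** — `sqrt(mean(x^2))` of each window, per channel. This single
   amplitude feature per channel is deliberately minimal; it is what makes
   the downstream 8-input network small enough to train from one session.

A note on the filter specification: published descriptions of this
acquisition chain sometimes quote a "high-pass 500 Hz, low-pass 20 Hz" pair,
which as written passes nothing at 1 kHz sampling; the 20–450 Hz band-pass
used here is the physically sensible reading and is consistent with the
stated dominant band. Similarly, the animation phases quoted above sum to
8.25 s although the total is sometimes quoted as 8.3 s; this package uses the
phase durations as given, and nothing downstream depends on the 0.05 s
difference because the analysis window ends at 7.5 s.

## Sugeno inference and hybrid learning

Rule *i* has one Gaussian membership function per input,
$\mu_{ij}(x_j) = \exp(-(x_j - c_{ij})^2 / 2\sigma_{ij}^2)$, firing strength
$w_i = \prod_j \mu_{ij}(x_j)$, normalized strength
$\bar w_i = w_i / \sum_k w_k$, and output
$\gamma(x) = \sum_i \bar w_i f_i(x)$. The Gaussian family is used throughout:
it is strictly positive (so normalization never divides by zero in exact
arithmetic), differentiable (required by the premise gradient step), and maps
naturally onto cluster centers. Far from every premise the raw strengths
underflow in floating point; `fis_eval()` therefore computes strengths in the
log domain and rescales by the row maximum before normalizing, which leaves
all ratios intact.

**Rule generation.** Subtractive clustering (`subclust()`) on the training
features, min-max normalized to the unit hypercube: point densities
$D_i = \sum_j \exp(-\|x_i - x_j\|^2 / (r_a/2)^2)$, iterative selection of the
densest point, subtraction of its influence with squash radius $r_b$, until
the accept/reject criteria stop the search. Defaults: $r_a = 0.5$ in
normalized units, $r_b = 1.5 r_a$, accept ratio 0.5, reject ratio 0.15 with
the usual in-between distance test ($d_{\min}/r_a + D/D_1 \ge 1$), ties
broken toward the lowest point index so the result is invariant to input
order. An optional `max_clusters` cap (60 in the default pipeline
configuration) bounds the rule count the way a fixed-size rule base would.
Each center becomes the premise-center vector of one rule, with width
$\sigma_j = r_a \cdot \mathrm{range}_j / \sqrt 8$ — a seeding convention that
scales the membership width with both the cluster radius and the data spread.

**Consequent order.** Both zero-order (constant $f_i$) and first-order
(affine $f_i$) consequents are implemented. The constructors and trainer
default to first-order, the richer form under which the least-squares
identification is usually derived. The *pipeline* default, however, is
zero-order: with 35 training vectors and $L$ rules, first-order consequents
contribute $9L$ free parameters, the least-squares system is rank-deficient,
and although the minimum-norm solution interpolates the training session it
extrapolates violently on held-out sessions (outputs of magnitude $10^6$ were
observed). Zero-order output is a convex combination of rule constants,
hence bounded by them, which keeps nearest-code decoding stable — and a
constant consequent per clustering-seeded rule is exactly the model the rule
generation assumes.

**Hybrid training** (`hybrid_fit()`). Per epoch: consequents solved exactly
by least squares (via SVD; rank-deficient systems take the minimum-norm
solution with a warning), then one batch gradient-descent step on all
premise centers and widths, using analytic gradients of the summed squared
error (verified against central finite differences at 1e-5 relative). The
step is scaled by the sample count, so the learning rate acts on the mean
squared error. Defaults, stated as this package's conventions since no
standard exists: 50 epochs, learning rate 0.01, early stop when the
epoch-to-epoch error change falls below 1e-6, widths clamped at 1e-4 of each
dimension's range (clamping, not reparameterization — simpler and directly
testable), learning rate halved after 5 consecutive error increases and
training abandoned (`converged = FALSE`) below 1e-8 of its initial value.

A caution on interpreting premise parameters: the normalized-Gaussian gating
is only weakly identifiable. With shared widths the two-rule gate is exactly
a logistic in the input, so only the midpoint of the two centers and the
ratio $\sigma^2 / (c_2 - c_1)$ are determined by the data; center pairs and
widths can trade off with no effect on the output. Recovery experiments in
the test suite therefore perturb the premise layer along its identifiable
direction (a common translation of all centers) and verify that training
pulls it back; componentwise recovery of an arbitrarily perturbed premise
layer is not a property this model family has.

## Movement codes and decoding

The seven classes carry fixed scalar targets: 0, 0.083, 0.166, 0.249, 0.333,
0.416, 0.499 for M0–M6 (hand contraction, wrist extension, wrist flexion,
forearm flexion, forearm rotation, hand abduction, hand adduction). The codes
are stored exactly as published rather than as the idealized k/12 grid, so
the table reproduces bit-exactly. Decoding assigns the class whose code is
nearest to the network output, with ties broken toward the lower code and
out-of-range outputs clamped to the endpoint classes; nearest-value matching
is the minimal decision rule consistent with fixed per-class targets.
Sessions are scored as per-movement hit rates (100 × hits / repetitions),
aggregated into a session × movement table with a per-movement average row
and an overall mean, plus a 7 × 7 confusion matrix.

## The synthetic generator

`generate_session()` emulates the cued acquisition protocol: 5 repetitions
of each of the 7 movements in seeded-random order, each animation preceded
by 3 s of rest, at 1 kHz on 8 channels. Each channel is amplitude-modulated
band-limited Gaussian noise — the standard interference-pattern surrogate
for surface EMG — plus 60 Hz mains interference and a per-channel DC offset:

* the unit-RMS carrier is white Gaussian noise band-passed to 20–450 Hz;
* its instantaneous amplitude is `rest_noise_rms + gain × activation(t)`,
  where the activation is the protocol trapezoid (ramp up over the forward
  movement, hold, ramp down over the backward movement);
* `gain` comes from a 7 × 8 movement-by-channel activation map: each
  movement's primary muscle/channel at 1, physiologically coupled channels
  at a crosstalk gain (default 0.4), all others at a 0.05 baseline.

The channel–muscle assignment follows the standard montage for these seven
movements (biceps, flexor carpi ulnaris, flexor carpi radialis, extensor
digitorum, pronator teres, brachioradialis, palmaris longus, extensor carpi
ulnaris). The crosstalk structure encodes the known hard pair: forearm
flexion (M3, biceps-primary) and forearm rotation (M4, pronator-primary)
share the biceps and brachioradialis, so raising the crosstalk gain moves
those two classes toward each other in feature space and produces M3↔M4
confusion first — the qualitative error structure seen with real
recordings.

Default noise settings — rest noise RMS 0.05, mains amplitude 0.1, DC offset
0.2, all in the arbitrary volt-proportional units of the signal — were
chosen once as a plausible rest-to-active contrast (active RMS roughly 15×
rest on the primary channel) and are free knobs. Repetition-to-repetition
force variation is off by default, matching a protocol that places no
constraint on exerted force; an optional ±20% per-repetition amplitude
jitter models it, and the confusion-monotonicity experiments enable it,
since without any within-class variability the RMS features are nearly
noiseless (a 7 s window at 1 kHz averages thousands of samples) and even
heavily overlapping activation maps remain separable.

Seeding: one master seed; per-session seeds derived by fixed offsets
(`seed + 9973 × session`, reduced modulo the 32-bit integer maximum). Every
generated recording, feature table and trained model is bit-reproducible
from (configuration, seed).

**What passing tests do and do not show.** The generator produces stationary
per-class amplitude profiles with Gaussian carriers, no electrode shift, no
fatigue drift, no inter-subject anatomy differences and no mislabeled cues.
End-to-end accuracy on this surrogate (at ceiling under default settings)
therefore demonstrates the correctness and stability of the pipeline — not
the field accuracy of the method on real recordings, which is limited by
exactly the factors the surrogate omits. The published figure of ~86% for
this system family on 30 real subjects is not reproducible from synthetic
data, and this package does not claim to reproduce it; what it reproduces is
the arithmetic and structure of that evaluation (accuracy tables, error
rates, rule-base shape) and the qualitative confusion behaviour.

## Numerical choices and degenerate inputs

* Normalization of a constant feature dimension maps it to 0.5 (hypercube
  midpoint); its membership width falls back to 1 unit to stay positive.
* Density, revision and the forward pass are vectorized but verified to
  1e-12 against straight-line loop implementations in the test suite.
* Least squares uses the SVD with tolerance
  `max(dim) × eps × max(singular value)`; rank deficiency warns and returns
  the minimum-norm solution rather than failing.
* All-coincident clustering input yields exactly one center (the revision
  step zeroes every density).
* `decode_movement()` rejects non-finite outputs rather than guessing.
* Problem sizes in the test suite and acceptance script: full-protocol
  sessions (35 movements, ~400 s at 1 kHz) for the benchmark runs, with
  5 seeds for the accuracy average and 10 seeds × 3 crosstalk levels
  (two-session subjects) for the confusion-monotonicity experiment; oracle
  equivalences use 100 random instances each.

## Limitations

* The classifier is windowed/offline: it assumes cue times (or an energy
  detector) and does not do continuous streaming classification.
* One feature per channel (RMS) is by design; richer feature sets would
  need a different input contract.
* Premise parameters are only weakly identifiable (see above); the trained
  system should be interpreted by its input–output behaviour, not by
  individual membership-function positions.
* The generator's realism limits are listed in the previous section;
  inter-subject variability is represented only by the seed.
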