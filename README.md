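# semgfis

Neuro-fuzzy characterization of arm movements from surface electromyography
(sEMG).

`semgfis` implements, end to end, a myoelectric movement-characterization
system of the kind used in upper-limb prosthesis control research: up to 8
bipolar surface-EMG channels placed over the main forearm/upper-arm muscle
groups are preprocessed into one RMS feature per channel and movement
execution, and a Sugeno fuzzy inference system — seeded by subtractive
clustering and trained with hybrid ANFIS learning — maps each 8-value feature
vector to a single continuous output in [0, 1] that decodes into one of seven
arm/hand movements (hand contraction, wrist extension/flexion, forearm
flexion/rotation, hand abduction/adduction). A synthetic sEMG generator
reproduces the cued acquisition protocol so the whole pipeline can be
trained, evaluated and tested with no recorded data and no hardware.

It is aimed at biomedical-signal-processing researchers and students who want
a complete, inspectable, testable reference implementation of this classifier
family in R.

## The model

**Features.** Each channel is calibrated, DC-removed, band-pass filtered
(20–450 Hz, zero-phase 4th-order Butterworth), notch filtered (60 Hz), and
windowed around each movement cue (cue + 0.4 s to cue + 7.5 s). The single
feature per channel is the window RMS, so a movement execution becomes the
vector x = (x_1, …, x_n), n ≤ 8.

**Sugeno FIS / ANFIS forward pass.** Rule i has one Gaussian membership
function per input, mu_ij(x_j) = exp(−(x_j − c_ij)² / (2 sigma_ij²)). Its
firing strength is the product w_i = prod_j mu_ij(x_j); normalized strengths
are wbar_i = w_i / sum_k w_k, and the output is

    gamma(x) = sum_i wbar_i f_i(x)

with f_i either a rule constant (zero-order) or an affine function
p_i·x + s_i (first-order). Both orders are implemented.

**Rule generation.** Subtractive clustering on the min-max-normalized
training features: the density at point x_i is
D_i = sum_j exp(−‖x_i − x_j‖² / (r_a/2)²); the densest point becomes a
cluster center, its influence is subtracted with the squash radius r_b, and
the process repeats under accept/reject thresholds (optionally capped, e.g.
at 60 rules). Each center seeds one fuzzy rule.

**Training.** Classic hybrid learning: per epoch, the consequent parameters
are identified by least squares (they enter the output linearly once
premises are fixed), then the premise centers and widths take one batch
gradient-descent step on the squared output error.

**Decoding.** Each movement has a fixed target code (0, 0.083, 0.166, 0.249,
0.333, 0.416, 0.499 for M0–M6); a continuous output decodes to the class
with the nearest code.

## Worked example

```r
library(semgfis)

# simulate one subject (5 sessions, 5 reps x 7 movements each),
# train on session 1, evaluate sessions 2-5
res <- run_pipeline(pipeline_config(seed = 11))

res$accuracy$table
#>            M0  M1  M2  M3  M4  M5  M6
#> Session 2 100 100 100 100 100 100 100
#> Session 3 100 100 100 100 100 100 100
#> Session 4 100 100 100 100 100 100 100
#> Session 5 100 100 100 100 100 100 100
#> Average   100 100 100 100 100 100 100

res$accuracy$overall
#> [1] 100

res$model
#> <sugeno_fis> 8 input(s), 7 rule(s), zero-order consequents
```

Each row is one held-out session's per-movement hit rate (%); the `Average`
row is the per-movement mean over sessions, and `overall` the mean of that
row — the layout used to summarize a subject's test. At the generator's
default settings the seven classes are cleanly separable, so the classifier
is at ceiling; raising the shared-muscle crosstalk between forearm flexion
(M3) and forearm rotation (M4), which share the biceps and brachioradialis,
degrades exactly that movement pair first:

```r
cfg <- pipeline_config(amap = activation_map(crosstalk = 0.9),
                       noise = noise_model(rep_jitter = 0.2), seed = 11)
run_pipeline(cfg)$confusion   # errors concentrate in the M3/M4 block
```

A command-line front end with `simulate`, `featurize`, `train`, `classify`,
`evaluate` and `run-all` subcommands is installed under
`system.file("cli", "semgfis", package = "semgfis")`.

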