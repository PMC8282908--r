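---
title: "Collaborative motor-imagery BCI: task allocation, fusion, and the simulated ERD cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collaborative motor-imagery BCI: task allocation, fusion, and the simulated ERD cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A single-user motor-imagery (MI) brain-computer interface decodes which of
several imagined movements a user is performing from the event-related
desynchronization (ERD) of their sensorimotor rhythms: imagining a movement
attenuates alpha (8-13 Hz) and beta (14-28 Hz) band power over the
corresponding motor-cortical area. Six-class MI decoding from EEG is hard;
single-user accuracies in the 30-40% range are typical.

A collaborative BCI (cBCI) pools concurrent EEG from several users to drive
one output. `cobci` implements a six-instruction, five-user MI-cBCI in which
the interesting design variable is *task allocation*: under the
**common-work** strategy all five users imagine the same movement, while
under **division-of-work** each user handles only a subset of `k`
instructions (`k = 2..5`; `k = 6` is common work). Every subset contains a
shared **reference instruction** — both feet, the class whose scalp ERD is
the weakest and hence most separable from the others — and users not
responsible for the current input perform the reference task. The package
reproduces the accuracy-versus-`k` experiment end to end on synthetic data:
pseudo-online classification over many random five-user groups, for both a
feature-level and a decision-level fusion rule.

## Pipeline and model

Per instruction class `i`, trials are `N x T` matrices (60 channels x 800
samples: 4 s at 200 Hz after decimation), conditioned by common average
reference and a zero-phase 4th-order Butterworth band-pass at 8-28 Hz.

**One-vs-rest CSP.** With `R_i` the trial-averaged, trace-normalized spatial
covariance of class `i`, the summed covariance `R = sum_i R_i = U0 L U0'`
gives the whitening `P = L^{-1/2} U0'`. For each class the whitened
covariance `Y_i = P R_i P'` is eigendecomposed, `Y_i = U_i L_i U_i'`, and
`W_i = U_i' P` is that class's spatial filter matrix; because
`P (R_i + R_i') P' = I`, the filters simultaneously diagonalize the class
and its complement with eigenvalues summing to one. Trials are reduced to
`2m = 4` log-variance-share features from the first and last `m = 2` filter
rows.

Two numerical points deserve note. Common average referencing removes
exactly one spatial direction, so `R` is always rank `N - 1`; whitening
drops eigenvalues below `1e-8` of the largest and proceeds in the signal
subspace (`P` is `r x N`). Eigenvector sign and order are fixed
(descending eigenvalue; each filter row's largest-magnitude entry positive)
so filters are reproducible across platforms.

**Submodels and weights.** A user's submodel for target instruction `c` is
target-vs-rest within their subset: CSP filters for `c` against the other
subset classes, four features, and a linear SVM (cost 1, no per-fold
tuning). Its leave-one-out accuracy `acc` — with the *whole* pipeline,
covariances included, refitted inside each fold so the held-out trial never
leaks into its own fold — yields the weight `lambda = acc^2`. Whether the
original procedure refit CSP inside each LOO fold is not something the
pipeline description fixes; the leak-free choice is implemented because the
alternative overestimates `acc` and hence `lambda`.

**Allocation.** For `k` tasks per user, the five non-reference instructions
(ascending) are labelled `0..4` and user `u` (0-based, A-E) receives the
reference plus labels `(u + m) mod 5`, `m = 0..k-2`. This balanced cyclic
design gives every non-reference instruction to exactly `k - 1` users and
reduces to common work at `k = 6`. Each input instruction induces a
*collaborative mode*: holders perform the input, everyone else the
reference; the mode's *collaborative model* takes from each user the
submodel targeting their assigned instruction.

**Fusion.** Decision fusion averages the members' signed SVM scores,
`Dv = (1/5) sum lambda_i dv_i`; the predicted instruction is the argmax of
the six model values (ties to the lowest instruction number; if no value is
positive the argmax is still returned, flagged, because a forced-choice
system must emit an instruction). Feature fusion instead concatenates the
five lambda-scaled 4-feature blocks into 20 columns, ranks them by plug-in
mutual information with the positive/negative label (equal-frequency
binning, 10 bins, edges fit on training data; ties by ascending column),
keeps the top 4, and trains one SVM per mode; prediction reorders the
20-feature row by the stored ranking before scoring. MI uses
`MI(Y,X) = H(Y) + H(X) - H(Y,X)` in bits with plug-in entropies and
`0 log 0 = 0`. Quantile binning is monotone-invariant, which also makes the
ranking indifferent to whether lambda scaling happens before or after
binning.

**Pseudo-online evaluation.** Subjects are recorded independently, so group
trials must be formed by convention: the j-th held-out test trial of each
user's assigned class is paired index-wise (any pairing is statistically
exchangeable; index pairing is deterministic). Twelve test trials per class
give 72 group trials per evaluation. Group selections are ordered 5-tuples
(order matters under the cyclic allocation for `k < 6`) drawn uniformly
without replacement, and the same selections are reused across strategies
and methods — a paired design that lowers comparison variance. Accuracy is
aggregated per selection, then mean and sd across selections.

## The synthetic ERD cohort

The recorded study data this design emulates (19 subjects, 14 blocks x 36
trials, 84 trials per class, 60 channels at 200 Hz) is not publicly
deposited, so the package ships a generator whose defaults *are* the study
design; it exists so the full experiment is runnable and testable, not to
reproduce any particular accuracy figure.

Each trial is 5 s at `fs_raw = 1000` Hz (1 s baseline + 4 s MI),
anti-alias filtered and decimated by 5 to 200 Hz:

* **Background**: per-channel pink (1/f) noise, spatially mixed by a fixed
  per-subject smoothing-plus-random matrix as a volume-conduction
  surrogate.
* **Rhythms**: narrowband-filtered noise in the alpha (8-13 Hz) and beta
  (14-28 Hz) bands (amplitude ratio 1:0.6) — filtered noise, not pure
  tones, so trial covariances have full rank. `snr` (default 0.7) is the
  rhythm-to-noise amplitude ratio.
* **ERD**: during the MI window the rhythm amplitude at channel `ch` is
  multiplied by `1 - depth_class x map_class[ch] x gain`, with a 100-ms
  raised-cosine onset ramp. The class topographies are Gaussian bumps at
  the hand areas (under C3/C4) and the mesial foot area (under Cz):
  left hand -> C4 cluster, right hand -> C3 cluster, both hands ->
  bilateral, both feet -> small midline patch (the weakest total mass of
  the six, which is why it serves as the reference), and the
  hand-plus-opposite-foot compounds -> one hand cluster plus midline
  weight. The five non-reference maps are normalized to equal total
  attenuation mass: real MI classes differ far more by spatial pattern
  than by overall band-power change, and an unequal mass would be a
  give-away amplitude cue.
* **Variability**: a per-subject lognormal-ish gain on depth
  (`subject_variability = 0.2`), a per-trial lognormal depth gain
  (`erd_trial_variability = 0.3`), and — most importantly for realism — a
  per-trial random shift of the whole ERD focus
  (`focus_jitter = 0.3` head-radius units). The focus jitter is what
  brings six-class single-user accuracy down from near-ceiling to the
  40% region, in line with the difficulty of real six-class MI; without
  it the planted topographies are implausibly stable and every method
  saturates.

What the generator does *not* model: biophysical forward fields, eye/muscle
artifacts, electrode noise and drifts, non-stationarity across blocks,
learning or fatigue. Passing tests on this cohort therefore demonstrate
that the decoding and fusion machinery recovers planted structure under
realistic variability — not that any particular accuracy would be attained
on real recordings.

Default depths are 0.55 for the five non-reference classes and 0.40 for
both feet (peak fractional amplitude attenuation). Together with the
defaults above these were chosen once so that the planted effect is
strong enough for a single user's target-vs-reference submodel to exceed
0.85 LOO accuracy while the six-class problem stays hard; they are
deliberately not tied to any published effect size, which the source
experiments do not report at this granularity.

## Worked example

```{r example}
library(cobci)

cfg <- sim_config(n_channels = 23)      # reduced montage, full trial design
cohort <- generate_cohort(cfg, n_subjects = 6, master_seed = 101)
prepared <- lapply(seq_along(cohort), function(i) {
  prepare_subject(cohort[[i]], split_seed = 200 + i)
})

curve <- accuracy_curve(
  prepared,
  experiment_config(n_selections = 50, master_seed = 17),
  cache = submodel_cache()
)
print(curve)
```

## Problem sizes

The full 19-subject, 60-channel, 300-selection experiment runs in hours;
the package's own tests and the bundled acceptance script use a
down-scaled but structurally identical configuration — a 21-23 channel
sensorimotor montage (a pair-complete prefix of the 60-channel one, so all
planted topographies keep their geometry), 5-6 subjects, and 12-50 group
selections — which preserves every structural constant of the design (6
classes, 5 users, 84 trials per class where stated, 72/12 splits, 20->4
fused features) while keeping a full sweep in the minutes range. The
number of distinct ordered groups (e.g. `6*5*4*3*2 = 720` for six
subjects) remains far above the selections drawn.

## Known limitations

* Decision values of independently trained SVMs are compared by argmax
  without calibration, exactly as in the original design; the feature
  fusion method at `k = 2` suffers most from this.
* The generator's trial independence (no slow drifts) makes LOO slightly
  optimistic relative to block-wise cross-validation on real data.
* EDF ingestion and HDF5 containers are not provided; cohorts and models
  are R objects with RDS persistence and TSV/JSON exports.
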