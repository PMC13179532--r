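---
title: "Detecting lateralised sound reactions: models, parameters and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting lateralised sound reactions: models, parameters and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latreact)
```

## The problem and the procedure

Behavioural hearing assessment in infants and toddlers relies on an observer
judging subtle reactions — head turns, gaze shifts, facial movements — to
sounds presented from a left or right loudspeaker. `latreact` implements an
unsupervised pipeline that makes the directional part of that judgement from
non-identifiable facial features alone:

1. **Feature tables.** Per-frame features in the OpenFace 2.x column dialect:
   35 facial action-unit activations (dimensionless, ≥ 0), unit gaze-direction
   vectors per eye plus averaged horizontal/vertical gaze angles (rad), head
   position (mm) and rotation (rad), and 6 rigid shape parameters — 55
   features per frame.
2. **Single-frame extraction.** For each trial the frame nearest
   `onset + 2 s` is kept (the group-mean absolute-yaw timecourse peaks 2–3 s
   after onset, so a single 2-s frame captures most of the reaction). Trials
   with no frame within tolerance are marked invalid and excluded.
3. **2-D feature sets.** Head rotation (yaw, pitch); left-eye gaze (world x,
   y); both-eyes gaze angle (x, y); the first two principal components of all
   55 features.
4. **Clustering.** A three-component bivariate Gaussian mixture with full
   covariances is fitted by EM on the toddler training split only.
5. **Labelling and validation.** Clusters are labelled left/centre/right;
   predictions on the held-out toddler trials and all infant trials are
   tabulated against the true speaker side.

The core assumption is geometric: most trials show no directional reaction
and concentrate near the origin of each 2-D feature space, while genuine
reactions displace the features toward the responded side. Three clusters —
one central "no decision" cluster and two lateral ones — express exactly that
structure. A full covariance per cluster absorbs the within-cluster
correlation between the two axes (a head turn usually drags gaze along), so
correlated axes do not masquerade as extra structure.

## The EM protocol

`fit_gmm3()` implements the complete fitting loop:

* **Exhaustive initialisation** (`n_exhaust_starts = 5`): five random starts
  (means at three distinct sampled points, shared data covariance, uniform
  weights). Each candidate is run to its capped short-EM fixed point
  (relative log-likelihood tolerance `short_em_tol = 1e-4`, cap
  `burn_in_iter = 100`) and the highest-likelihood candidate wins. Comparing
  candidates at a fixed small iteration count instead proved unreliable:
  poor basins can hold transiently high likelihoods early and win the argmax,
  then converge to merged components. Comparing converged candidates removes
  that failure mode while keeping the same five-start budget.
* **Sign-opposition restart loop** (`max_restarts = 100`): after short EM the
  fitted means must satisfy `sign_opposition_criterion()` — over all six mean
  coordinates, the maximum `M` and minimum `m` satisfy `m < 0 < M`,
  `M ≥ |m|/2` and `|m| ≥ M/2`. This encourages two clusters of opposite sign
  and comparable magnitude without pinning them to a particular axis. The
  criterion is evaluated on **all three** means (the literal protocol); set
  `exclude_centre = TRUE` to restrict it to the two non-centre clusters. On
  failure the loop restarts with a deterministically derived seed
  (`seed + restart index`). If no restart succeeds, the highest-likelihood
  candidate is used and flagged (`criterion_met = FALSE`). The loop is
  disabled for the PCA feature set, whose axes have no left/right sign
  semantics.
* **Final EM** to `final_tol = 1e-6` (relative), `max_iter = 1000`.

Numerical choices: covariances are re-symmetrised each M-step and their
eigenvalues floored at `cov_floor_rel = 1e-8` times the mean per-axis data
variance, preventing singular components (a floor hit emits a warning).
Responsibilities and log-likelihoods are computed in log space via Cholesky
factors, so well-separated clusters cannot underflow. Degenerate inputs
(fewer than three distinct points, zero variance) are errors, not silent
fits. Fits are reproducible bit for bit from `(data, seed)`; "best
performing" is judged by total log-likelihood throughout.

## Cluster labelling and decision statistics

`label_clusters()` takes the cluster with the smallest mean norm as *centre*
(two clusters tied for centre within 1e-9 is an error); the decision axis is
the axis separating the two lateral means most; left/right assignment
maximises agreement with the speaker sides of the training trials assigned to
those clusters, with exact ties broken by the sign convention (negative
coordinate → left; positive yaw means a turn toward the right speaker from
the child's perspective — `flip_yaw` accommodates mirrored camera output).
Note a consequence of agreement-based labelling: mirroring the data mirrors
which spatial side is called "left", because each cluster keeps the label of
the trials it contains.

The correct-decision rate ("specificity" in this field's usage — a precision
of decisions, not the epidemiological quantity) is
`(n left-decisions after left presentations + n right-decisions after right
presentations) / n decisions`; it is undefined (`NA`) when no decision was
made. `binom_p_one_sided(k, n)` is the exact binomial tail `P(X ≥ k | n,
0.5)`. Cross-feature-set averages are unweighted means over the four rates,
as integer percentages; p-values are reported to the precision of the
summaries they appear in; no multiple-testing correction is applied (raw
per-feature-set p-values are reported). `combine_decisions()` merges
head-based and gaze-based predictions: a single deciding source wins,
agreement keeps the shared class, and conflicts follow a policy (default:
gaze wins, the empirically better-calibrated source); combination can only
add decisions.

## The synthetic-session generator

`simulate_session()` emulates the sound-booth protocol the pipeline targets:
10 trials per participant, each of five stimuli (0.5/1/2-kHz warble tones,
"ba", "da") exactly twice in random order, side drawn per trial, onsets
separated by 6 s plus a gamma-distributed re-centring delay. Frames span
onset −1 s to +5 s at 30 Hz.

Response kinematics (defaults per group in `response_model_params()`):

| parameter | toddler | infant | meaning |
|---|---|---|---|
| `responder_prob` | 0.25 | 0.25 | probability of an overt response (in line with reported unreinforced head-turn rates) |
| `correct_side_prob` | 0.80 | 0.65 | response directed to the presentation side |
| `peak_yaw_rad` | 0.30 | 0.21 | group-mean peak of the absolute-yaw timecourse |
| `latency_peak_s` | 2.5 | 2.0 | time of the response peak after onset |
| `baseline_yaw_rad` | 0.175 | 0.175 | mean absolute resting off-centre yaw (10°) |
| `gaze_head_corr` | 0.8 | 0.8 | correlation of horizontal gaze with yaw |
| `noise_sd` | 0.02 | 0.02 | per-feature Gaussian noise (rad) |
| `missing_frame_prob` | 18/300 | 2/280 | extraction frame absent |

Two modelling choices deserve explanation:

* **Unimodal baseline.** The resting yaw is drawn from a centred Gaussian
  with sd `baseline_yaw_rad / sqrt(2/π)`, so its mean *absolute* value is
  exactly `baseline_yaw_rad` ("about 10° off-centre on average") while the
  resting distribution stays unimodal at the origin. Drawing the baseline as
  ±10° with jitter instead would make the no-reaction population bimodal and
  destroy the central-cluster geometry the analysis rests on.
* **Group-level peak calibration.** `peak_yaw_rad` is defined as the value
  the across-trials mean of |yaw| reaches at the peak of the timecourse.
  Responder trials rotate from baseline toward a target angle
  `(peak_yaw_rad − (1 − p)·baseline_yaw_rad)/p` (with `p = responder_prob`,
  small multiplicative jitter of mean one), along a raised-cosine envelope
  rising from 0.5 s after onset, peaking at `latency_peak_s` and returning
  to baseline by 5 s. Mixing responders with non-responders then reproduces
  the group-level peak for any responder rate, and with `p = 1` the target
  equals `peak_yaw_rad` itself.

Gaze angles follow yaw with the configured correlation; per-eye gaze vectors
are exact unit vectors derived from the angles. Action units and shape
parameters are white noise around fixed means by default (an optional
`au_reaction` mode adds a stimulus-locked activation bump on a few AUs);
they carry no directional information, which is precisely what makes them a
useful null channel for the PCA feature set.

What the generator does **not** emulate: habituation across the session,
test-assistant re-centring interventions, reaction-time variability between
trials, asymmetric left/right response propensities, and any coupling of the
head-shape channel to behaviour. Passing tests on synthetic data therefore
show that the algorithms recover the structure they assume, not that real
recordings satisfy those assumptions.

## Data splits, PCA and reproducibility

The training split takes 80% of the valid **toddler** trials (seeded,
trial-level by default; `split_unit = "participant"` switches to a
participant-level split). Infant trials are never used for training — this is
enforced structurally, not by configuration. The PCA is fitted on the
training split only (centring, z-scoring with unit scale substituted for
constant features, top-two axes via `stats::prcomp`) and applied unchanged to
validation data, preventing leakage; z-scoring is used because the 55
features mix radians, millimetres and dimensionless activations, and unscaled
PCA would be dominated by head position. Frame matching uses a tolerance of
half a frame interval by default, with equidistant ties resolved to the
earlier frame.

All randomness flows through a single base seed: per-participant,
per-restart and per-split seeds are derived deterministically from it, and
two runs with the same configuration and seed produce byte-identical
reports. Model files serialise to JSON for audit and reload.

The test suite exercises the pipeline at deliberately moderate problem sizes
— cohorts of 12–58 participants, mixture fits on a few hundred points,
20-replicate parameter-recovery and end-to-end studies, 500-trial Monte-Carlo
checks of the generator — chosen so the full suite runs in a few minutes
while keeping Monte-Carlo standard errors well inside the asserted
tolerances.

## Known limitations

* **Saturated responder rates degrade the three-cluster geometry.** If
  (nearly) every trial is a clean lateral responder, the feature space
  contains two blobs and no central population. A three-component
  full-covariance mixture fitted by likelihood maximisation must then either
  split one blob or collapse a component, and the smallest-norm component —
  interpreted as "no decision" — captures genuinely lateral trials. In that
  regime decisions remain highly *specific* (agreement with the speaker side
  stays near perfect) but the decision rate is structurally depressed. This
  is a property of forcing three clusters onto two-cluster data, not an
  implementation artefact; an adaptive number of components would be the
  principled fix and is out of scope here.
* The single-frame design misses reactions that finish before, or start
  after, the 2-s extraction point; a widened analysis window would need
  control (no-sound) trials to remain unsupervised.
* The sign-opposition criterion inspects mean coordinates only; a rotated
  solution whose lateral clusters separate along the second axis still
  passes, which is intended (the protocol does not pin the decision axis)
  but means the criterion alone does not guarantee left/right separation on
  the first axis.
* Specificity estimates on small validation splits (e.g. 4–6 decisions in a
  toddler split) carry wide binomial uncertainty; the exact tests reported
  alongside make that explicit.
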