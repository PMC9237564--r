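---
title: "Task-linked intrinsic network synchrony from EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-linked intrinsic network synchrony from EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Under the tri-network model of cognition, three intrinsic connectivity
networks (ICNs) organize task-directed brain activity: the default mode
network (DMN, self-referential processing and memory retrieval), the
central executive network (CEN, working memory and executive control), and
the salience network (SN), which is thought to co-activate with whichever
of the other two the current task demands. A task paradigm of randomly
interleaved 30-s blocks of autobiographical memory recall (AM, driving the
DMN) and 2-back working memory (WM, driving the CEN) probes this
machinery: during AM blocks the DMN dominates early and hands over to the
CEN late in the block, while WM blocks are CEN-dominant throughout.

`icnsync` implements an EEG-only analysis of these dynamics: multichannel
task EEG is preprocessed and converted to per-5-s-window activation
probabilities for the three networks, and the synchrony between a network
pair is summarized by the pairwise cross-entropy (PCE)

$$\mathrm{PCE}_{a\text{-}b} = -\sum_i P_a(i)\,\log P_b(i),$$

summed over the windows of the selected trials (or trial halves). Lower
PCE means the second network's activation probability is high in the
windows that matter for the first — the statistic's floor of zero is
approached as $P_b \to 1$ wherever $P_a > 0$, which is why it is read as
"maximum synchrony". PCE is computed for the DMN-SN and CEN-SN pairs,
during AM and WM trials, over full trials and each half, before and after
an eight-week lifestyle intervention (aerobic running, neurofeedback
mindfulness training, both combined, or no-contact control), and the
group-level battery asks whether intervention and responder status shift
task-appropriate synchrony.

Because no raw recordings ship with the package, a synthetic-cohort
generator is a first-class module: it produces ground-truth latent network
states, multichannel EEG with state-dependent coupling signatures,
behavioral and fitness records, and the subgroup effect structure, so
every downstream stage is testable end to end.

## The statistic and its conventions

* Natural logarithm; $P_b$ is clipped to $[10^{-12}, 1]$ before the log so
  zero probabilities give a finite, bit-reproducible value. The summation
  order is fixed (trials in order, windows within trial) for determinism.
* The sum runs over all windows of all selected trials. Per-trial
  aggregation of window probabilities before the sum would make the
  half-trial variants ill-defined, so it is not the default; a per-window
  mean (`mean_per_window`) is carried alongside every PCE value for
  comparisons across unequal trial counts, and is clearly labeled as a
  convenience, not the primary statistic.
* The per-window probabilities are three *one-vs-rest* activations and are
  deliberately not renormalized to sum to one: the SN is expected to
  co-activate with a task network, which a mutually exclusive softmax
  could not express.

## Preprocessing

The stage order is: band filtering, spectral bad-channel detection, ICA
artifact removal, average referencing, spherical-spline interpolation,
block-aligned 5-s epoching.

* **Filtering.** Six bands — full 1–50, delta 1–4, theta 4–8, alpha 8–13,
  beta 13–30, gamma 30–50 Hz — with a design-order-12 Butterworth applied
  forward and backward (zero phase, effective order 24). The filter is
  realized as second-order sections: a direct-form transfer function of
  this order is numerically singular in double precision for the narrow
  low bands, which is also why the constructor raises an error rather
  than returning an unstable design.
* **Bad channels.** A channel is flagged when its log band power deviates
  from the montage median by more than 3 robust z-units (median/MAD) *and*
  by at least a factor of two in power. The absolute floor matters:
  across a homogeneous montage the MAD can be arbitrarily small, and a
  pure z-rule would flag channels on noise. Segment periodograms are
  aggregated by the median over time so transient artifacts (blinks,
  muscle bursts) do not masquerade as channel failure.
* **ICA.** FastICA (symmetric decorrelation, tanh contrast) with PCA
  whitening and automatic rank reduction. Artifact components are scored
  by transparent heuristics — blinks: dominantly sub-3-Hz source power
  with spatially focal loading; muscle: dominant 30–50 Hz power fraction
  (fractions taken within the 0–50 Hz analysis band) — with all
  thresholds exposed as arguments. One caveat is documented in
  `fast_ica()`: strongly narrowband data contain quadrature source pairs
  whose joint distribution is circularly symmetric, so the unmixing
  rotation inside such a pair is not identifiable and the fixed-point
  iteration need not settle even though identifiable (artifact)
  components have; the pipeline therefore runs ICA in `on_fail = "warn"`
  mode with a capped iteration count, while the strict error contract
  remains the default for callers. The unmixing is estimated once on the
  broadband (1–50 Hz) data — on a strided subsample for speed — and the
  resulting linear cleaning operator is applied to every band, which is
  exact because filtering and cleaning are both linear.
* **Interpolation.** Bad channels are replaced by spherical-spline
  interpolation (stiffness 4, 20-term Legendre series) only when they
  number fewer than 5% of the montage; otherwise the recording is
  *rejected with a distinct status* rather than silently truncated or
  channel-dropped, preserving feature dimensionality downstream.
* **Epoching.** Six non-overlapping 5-s windows per 30-s block, aligned
  to block onset; windows 1–3 are the first half, 4–6 the second.

## Features and classification

Five connectivity families per channel pair: magnitude-squared coherence
(Welch, Hann segments, band-bin average), phase lag index (PLI,
$|\langle \mathrm{sign}\,\Delta\phi\rangle|$ with $\mathrm{sign}(0)=0$),
directed PLI ($\langle H(\Delta\phi)\rangle$, $H(0)=\tfrac12$, so
$\mathrm{dPLI}(x,y)+\mathrm{dPLI}(y,x)=1$), phase-amplitude coupling
(Tort modulation index, 18 phase bins, normalized by $\log 18$), and a
cross-frequency synchronization index (mean resultant vector length
between low-band phase and the low-band-filtered phase of the high-band
amplitude envelope). Phases come from the FFT analytic signal on
band-filtered windows with a 0.25-s edge trim against filter transients.
The estimator choices are stated because the family names alone do not
pin them down; both cross-frequency variants are implemented and
separately selectable since they measure related but distinct couplings.

Features are ranked by one-vs-rest mutual information with the window
state labels, under a fixed equal-frequency discretization (8 bins) so the
estimator is deterministic; the selection object records the training
windows it was computed on, and the default budget is K = 500 at a
32-channel desk scale (the original feature set belonged to a 128-channel
study and is not available). Per network, a ridge-regularized logistic
classifier is trained one-vs-rest (task state for DMN/CEN; an SN-active
flag thresholded at 0.5 for the SN); regularized linear models are the
natural family at these dimensionalities and give calibrated probability
outputs directly.

## The synthetic cohort

The generator's defaults are the study conditions: 15/20/14/20
participants in Control/Running/NFB/Combined, 16 behavioral sessions over
eight weeks, responder fractions matching the reported responder counts in
the neurofeedback arms (11 of 14 NFB, 5 of 20 Combined; the running
responder fraction is not reported and is fixed once at 0.6, inside the
range exercise-response studies report), and pre/post scans of 10
interleaved 30-s blocks. The montage defaults to 32 channels at 256 Hz —
a deliberate desk-scale reduction of the original 128-channel system,
configurable upward.

**EEG model.** Background activity is unit-variance AR(1) noise per
channel. Every channel carries every rhythm (alpha 10 Hz, beta 20 Hz,
gamma 40 Hz, theta 6 Hz plus a theta-gated gamma PAC motif) at constant
power scaled by `sqrt(2*snr)`, with per-channel electrode gains drawn
log-normally — so band spectra are homogeneous across channels and
states, as in real EEG. What a network's activation level gates is the
*coupled fraction* of its members' rhythm: a member channel's rhythm is
$\sqrt{a}\,\sin(\phi_{\mathrm{common}} + j\pi/4) +
\sqrt{1-a}\,\sin(\phi_{\mathrm{own}})$, where all phases follow drifting
random walks and only members share a walk. Activation is therefore
written into the coupling structure (coherence, phase locking, PAC) and
not into band power; this both matches the physiological reading of ICN
activation as transient synchrony and gives the `snr` parameter a real
meaning — as the rhythms sink into the background noise the coupling
evidence genuinely degrades, rather than remaining readable from power.
Latent activation levels carry Gaussian jitter (SD 0.12) so window states
overlap moderately; window-state classification is deliberately not a
ceiling task even at generous snr.

**Artifacts.** Blinks are ~160-ms Gaussian transients at 0.2 Hz on four
designated "frontal" channels; muscle bursts are 1-s high-frequency
episodes on two "edge" channels; dead/noisy channels are optional. The
artifact channels sit off the network signature sets when the montage
allows, so artifact handling can be validated without entangling it with
state decoding.

**Effect structure.** Subgroup effects are injected by pulling SN
activation toward a co-activation ceiling (0.97) in targeted windows,
which is the direction the PCE statistic registers as increased synchrony:

* all labeled non-responders drift toward task-inappropriate DMN-SN
  synchrony in WM windows at the post timepoint (shift 0.35), with
  NFB-group non-responders shifted hardest (0.8) — producing a Session
  main effect within non-responders and the NFB-driven post-hoc contrast;
* responders in the neurofeedback arms carry a *baseline* CEN-SN
  co-activation advantage confined to the second half of WM trials
  (0.35; Combined-group responders 0.8), present at both timepoints —
  producing a Group effect within responders that is concentrated in the
  trial's second half, no Session effect, and baseline predictability of
  NFB response.

The shift magnitudes were fixed at design time to represent the large
reported effect sizes in this literature (partial eta-squared in the
0.3–0.5 range for the corresponding terms) with sufficient power at the
study's subgroup sizes; the cohort-wide non-responder drift is the
generator's account of a Session main effect that a shift confined to
three NFB non-responders could not produce at any plausible magnitude
(it would surface almost entirely as an interaction). Setting every shift
to zero yields a null cohort, which is how the type-I calibration
properties are tested.

**Behavior and fitness.** Responders in the NFB arms draw a positive
underlying slope on at least one of the two neurofeedback metrics
(calm-state percentage, device points); non-responders draw clearly
negative slopes on both (calm slope in [-1.5, -0.25] %/session), keeping
fitted labels faithful to ground truth at the session noise level (SD 3
percentage points). Exercisers who respond draw strictly positive VO2-max
deltas centred near +4 mL/kg/min; non-responders non-positive deltas;
non-exercising groups draw deltas centred at zero. Combined-group
non-responders fail the neurofeedback rule, the exercise rule, or both,
with equal probability. A useful emergent property: because
non-responders both drift toward lower post DMN-SN-WM PCE and draw
non-positive VO2-max deltas, the change in that PCE correlates positively
with fitness across the exercising groups — the direction the fitness
correlation analysis expects — without a dedicated injection.

**Probability-level and EEG-level cohorts.** `generate_cohort()` emits,
per scan, either the window probability series derived directly from the
latent states plus noise (`detail = "probs"`) or a full synthetic EEG
recording (`detail = "eeg"`). The PCE, responder, and statistics stages
consume the identical probability-series interface in both cases. The
replicated statistical properties (type-I calibration across 1,000
cohorts; effect-pattern recovery across 50) run at the probability level:
they characterize the statistics battery, and running EEG synthesis, ICA
and feature extraction thousands of times would add nothing to what the
dedicated EEG-level classifier-recovery checks already establish on full
scans.

## Statistical battery

* VO2-max manipulation check: one-way ANOVA on the delta across the four
  groups plus the four planned Welch t-tests (Running/Combined vs
  Control/NFB) at the Bonferroni threshold 0.0125, with Cohen's d (mean
  difference over pooled SD; the comparisons are independent-samples, so
  a paired-style normalization is not meaningful and is not used).
* Neurofeedback manipulation check: one-way MANOVA (Pillai) over the two
  behavioral slopes.
* PCE panel: per-outcome Group x Session x Responder factorial ANOVA with
  partial eta-squared (Control, which has no responder label, is
  excluded), then Group (between) x Session (within) repeated-measures
  ANOVAs within responders and non-responders separately. The bootstrap
  (default 1,000 replicates, case-resampling participants within group)
  yields percentile confidence intervals for the effect sizes; p-values
  come from the standard RM-ANOVA. Benjamini-Hochberg correction is
  applied per effect term across the outcome family. With only two
  session levels, sphericity machinery is unnecessary.
* Post-hoc pairwise Welch t-tests with BH correction; one-tailed tests
  use a fixed direction (first group in alphabetical pair order lower),
  never a data-driven one, so the type-I rate is preserved.
* Spearman correlations of the DMN-SN-WM PCE change against VO2-max at
  each timepoint, over the exercising groups.
* Response prediction: a linear SVM over baseline (pre-intervention) PCE
  predictors with seeded, stratified 10-fold cross-validation, reporting
  per-fold accuracies and their mean and SD. The default predictor is the
  CEN-SN WM PCE alone — the quantity the headline prediction result is
  reported for — with the two-predictor variant available.

FDR is Benjamini-Hochberg throughout (the generic "FDR correction" is
otherwise underspecified).

## Numerical choices and degenerate inputs

* PCE: natural log, `eps = 1e-12` clip, fixed summation order.
* Filters: SOS cascade, odd-reflection padding of 3x the section count.
* Zero-variance signals raise an undefined-phase error in every
  phase-based estimator; all-zero amplitude raises a degenerate-amplitude
  error in the Tort index.
* Constant group outcomes give statistic 0 / p 1 rather than a crash;
  groups below two observations are skipped with an explicit status in
  pairwise tests; participants missing a session are excluded from the
  RM-ANOVA with a log entry.
* Rank-deficient recordings (duplicated or silent channels) are handled
  by rank reduction inside the whitening step.
* Mutual-information selection uses fixed quantile binning; ties in the
  ranking resolve by feature index, so selection is deterministic.
* One master seed drives everything; per-participant and per-stage child
  seeds are derived by a documented hash so stages are independently
  reproducible and all derived seeds stay below 2^31.

## Problem sizes in the shipped checks

The packaged tests validate classifier recovery on eight-scan sets at 32
channels / 256 Hz / 10 blocks with a reduced channel-pair universe
(within-network pairs plus a cross-network sample), statistical
calibration on 1,000 reduced-size null cohorts (16 participants, 4
blocks), and effect-pattern recovery on 50 study-sized
probability-level cohorts. These sizes are the package's chosen
validation scale; all of them are configuration, not limits.

## What passing tests do and do not show

The generator emulates task-locked latent states, coupling-borne network
signatures, stereotyped artifacts, responder heterogeneity, and the
reported subgroup effect directions. It does not emulate volume
conduction or a forward head model, non-stationary background spectra,
electrode drift, behavioral missingness, or physiological VO2-max
dynamics. Passing the shipped checks therefore demonstrates that the
pipeline recovers known structure of the kinds it models, with calibrated
false-positive behavior — not that the specific published effect sizes
would replicate on new human data, nor that the stand-in window-state
classifier matches the original cross-modal model it replaces.
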