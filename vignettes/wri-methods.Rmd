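---
title: "Quantifying wrist rotation imitation from dual-wrist inertial sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying wrist rotation imitation from dual-wrist inertial sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The task and the measurement model

Wrist rotation imitation (WRI) is a meaningless gross motor imitation task:
a child copies an examiner rotating the hands back and forth about twice a
second. The protocol has three 20 s imitation blocks separated by 10 s rests;
each wrist carries a six-axis inertial sensor (3-axis accelerometer in g,
3-axis gyroscope in deg/s) sampled nominally at 50 Hz. The gyroscope y axis
is aligned with the pronation/supination axis, so the y-channel angular
velocity $\omega(t)$ carries the rotation. `wrikit` turns such recordings —
or simulated ones — into three per-participant metrics and runs the group
statistics and classification benchmark built on them.

The three metrics, each computed per block and aggregated as the maximum
over the three blocks:

* **Total rotation time (TRT)** — seconds of sustained rotation within a
  block, measured as the time the moving-RMS envelope of $\omega$ stays
  above an activity threshold.
* **Rotation amplitude (RoA)** — mean absolute rotation angle between
  adjacent extrema of the integrated angle trace
  $\hat\theta(t)=\int\omega\,dt$:
  $\mathrm{RoA}=\frac{1}{N-1}\sum_{i}\bigl|\hat\theta(P_{i+1})-\hat\theta(P_i)\bigr|$,
  where $P_1,\dots,P_N$ are the detected angle extrema. For a sinusoidal
  rotation of peak angle $\Theta$ this is the peak-to-peak swing $2\Theta$.
* **Symmetry** — a weighted complement of normalised left/right differences,
  $\bigl(1-0.7\,\tfrac{|RoA_l-RoA_r|}{\max(RoA_l,RoA_r)}
         -0.3\,\tfrac{|RoF_l-RoF_r|}{\max(RoF_l,RoF_r)}\bigr)^2\in[0,1]$,
  where the rotation frequency RoF is estimated from extrema counts:
  adjacent extrema are half a cycle apart, so
  $\mathrm{RoF}=(N-1)/\bigl(2\,(t_N-t_1)\bigr)$.

Two definitional points are worth making explicit. First, the "peak points"
between which RoA integrates are extrema of the *angle* trace (equivalently
zero crossings of $\omega$): integrating $\omega$ between adjacent peaks of
$\omega$ itself would give approximately zero for any symmetric oscillation,
while the angle-extrema reading yields the per-half-cycle swing that
"averaged rotation angle" describes. Second, $N$ is the number of detected
extrema — the sum has $N-1$ adjacent-pair terms — not the number of samples.
Each ratio in the symmetry formula is defined as 0 when both of its
arguments are 0, so two motionless wrists are (vacuously) symmetric.

## Conditioning chain

Raw per-block segments pass through three stages, in order:

1. **Shape-preserving cubic interpolation** (PCHIP) onto a uniform 50 Hz
   grid. PCHIP reproduces knots exactly and cannot overshoot monotone data,
   which matters because the angle trace is integrated downstream.
2. **Zero-phase second-order Butterworth low-pass, 10 Hz cut-off**, applied
   forward and backward. Zero-phase application was chosen because metric
   extraction depends on extrema timing; the effective magnitude response is
   the squared one-pass response, which still passes a 2 Hz rotation
   essentially unattenuated (>99.8%) and suppresses a 20 Hz tone below 1%.
   Edges are padded by odd reflection over one filter settling length.
3. **Scalar Kalman smoothing** per channel with a local-level (random-walk
   state) model and gain $K=P/(P+r)$, followed by a fixed-interval (RTS)
   backward pass so the stage is also zero-phase. Defaults:
   $q=10^{-2}\,\mathrm{var}(\text{channel})$, and $r$ estimated from the
   median absolute *second* difference
   ($\hat\sigma=\mathrm{MAD}(\Delta^2 x)/\sqrt{6}$). A first-difference
   estimator was rejected because at 50 Hz the first differences of a 2 Hz
   oscillation are dominated by signal slope rather than noise, which
   inflates $r$ and visibly attenuates a clean rotation; second differences
   of a smooth band-limited oscillation are small, so the estimator tracks
   the noise floor instead. Both parameters are configurable.

On a noiseless simulated 45°/2 Hz session the full chain keeps the
conditioned angular velocity correlated above 0.999 with the analytic
derivative and shifts extrema by less than one sample.

## Extrema detection and the activity rule

Angle extrema are detected on the integrated, bias-corrected angle trace
(the block-mean angular velocity is subtracted before integration, which
removes gyro bias as a linear angle trend and keeps extrema-to-extrema
angle differences identical to direct integrals of the corrected rate).
Candidates are plateau-aware non-strict turning points; a candidate is kept
when its topographic prominence reaches 10° (configurable), and retained
extrema must be at least 0.15 s apart — safe margins for ~2 Hz motion with
tens of degrees of swing. Topographic prominence (height above the higher
of the two surrounding bases) rather than adjacent-swing pruning is used
because it discards low-amplitude noise wiggles in otherwise quiet stretches
without leaving stray terminal extrema.

The TRT activity rule uses a 0.5 s moving-RMS window, threshold
$\max(15\ \mathrm{deg/s},\ 0.2\times$ 95th percentile of the envelope$)$,
and bridges inactive gaps shorter than 0.5 s. The absolute floor keeps
sensor noise (default 8 deg/s) inactive; the relative term adapts to
vigorous rotations. All three constants are configurable.

Degenerate inputs are handled explicitly: fewer than two extrema makes RoA
and RoF 0 (flagged as insufficient motion); a session whose dominant-wrist
blocks all lack motion reports features (0, 0, 0) with a `low_motion` flag.
TRT and RoA are taken from the right wrist by default, since the study
population the task targets is right-handed; `wrist = "max"` switches to
the better wrist per block.

## The session simulator

No recordings are distributed, so the simulator is the package's test bed.
Per wrist, the commanded angle is
$\theta(t)=\Theta\,w(t)\sin(2\pi f t)$ with $f\approx2$ Hz; the envelope
$w(t)$ is 1 until the participant stops sustaining (`sustain_s`) and decays
to 0 over 1 s with a raised cosine — the simplest envelope consistent with
"rotates, then stops". The gyro y channel is the analytic derivative plus a
constant bias and white noise; the accelerometer reports gravity re-projected
through the rotation about the y axis plus white noise (no linear
acceleration term: wrist rotation about a fixed axis is rotation-dominated
and no accelerometer-derived quantity enters the metrics). Rest periods are
noise only. Sessions are bit-reproducible given a seed.

Cohort generation draws per-participant parameters log-normally around
group presets (2 groups x 3 one-year age bands). Defaults: TD sustain
20 s, $\Theta$ 60°, left/right ratios 0.95; ASD sustain 10 s, $\Theta$ 40°,
ratios 0.75; gyro noise 8 deg/s, accelerometer noise 0.02 g, per-session
bias sd 1 deg/s. Sustain draws are capped at the block duration, so the
dispersion of total rotation time depends on both groups' sustain CVs;
the CVs (TD 0.45, ASD 0.8) were calibrated once by Monte-Carlo so that the
simulated Cohen's d on TRT is about -1.6 (ASD - TD) under default noise,
and then frozen. The simulator emulates the statistical structure the
analysis assumes — group differences in sustain, amplitude and left/right
asymmetry with realistic sensor noise — but not tremor, off-axis motion,
voluntary pauses mid-block, or soft-tissue artefacts; passing tests
therefore validate the pipeline's arithmetic and its recovery of known
kinematics, not its behaviour on every pathology of real recordings.

## Calibration utilities

Accelerometer calibration is the classic six-pose least squares: each
static pose contributes its mean acceleration vector, and bias plus
diagonal scale come from the axis-aligned ellipsoid fit
$\sum_i s_i^2(a_i-b_i)^2=1$, linear in its algebraic parameters (cross-axis
terms are out of scope). At least six distinct orientations are required
for identifiability, enforced via the design-matrix rank. Gyroscope noise
is characterised with the overlapping Allan deviation over log-spaced
cluster times from $2/f_s$ to a ninth of the record; white noise shows the
canonical $-1/2$ log-log slope and rate random walk $+1/2$. Calibration is
optional in the pipeline — simulated data are born calibrated — and applied
when a calibration file is supplied, per device.

## Statistics

Because the metrics are bounded and skewed, group comparisons use the
aligned rank transform (ART): for each effect in the 2 (group) x 3 (age
band) design, the response is aligned for that effect (residual from cell
means plus the effect's own unweighted marginal estimate), mid-ranked, and
analysed with a fixed-effects factorial ANOVA (type III sums of squares,
sum-to-zero contrasts); only the aligned effect's F is reported, with
partial $\eta^2=SS_{\text{eff}}/(SS_{\text{eff}}+SS_{\text{err}})$.
The construction is invariant to positive affine transforms of the response
(alignment works on cell means, so nonlinear monotone maps do change it —
an intrinsic property of ART, not an implementation artefact). Under an
i.i.d. null with 15 observations per cell the implementation holds its
nominal 5% type-I error (checked by simulation in the test suite, 1000
replicates). Post-hoc contrasts follow ART-C: re-rank the aligned values of
the two contrasted levels, pooled-variance t test, Bonferroni over the
pairwise family within one factor and one metric; cross-metric correction
is deliberately not applied. Cohen's d is reported on the raw responses
with the ASD-minus-TD sign convention. Correlation screens against clinical
scores use Spearman's rho with no multiplicity adjustment, and cohort
balance is checked with a Pearson chi-square without continuity correction.
Partial (rather than generalized) eta squared is reported and labelled as
such.

## Clinical scales

Gesell developmental age is the pass-weighted mean of milestone ages,
$DA=\sum_i W_iN_i/\sum_i N_i$, over the 24 standard milestones;
week-valued milestones are converted at 4.345 weeks/month because the
schedule mixes weeks and months without a rule. $DQ=100\,DA/CA$, with bands
delay (<76), borderline (76–85), normal (>=86). No basal/ceiling or
partial-credit rules are applied — a straight weighted mean. CARS totals
are the sum of 15 items (half-points admitted, standard practice) with
bands <30 / 30–36 / >36. PEP-3 performance subscales are stored and joined
only; no formula is defined on them.

## Classification benchmark

The three metrics feed five classifiers (KNN, LDA, Gaussian NB, RBF-SVM,
random forest). The data are split 90/10 stratified by group; each
algorithm's hyperparameters come from a grid search scored by 10x repeated
stratified 10-fold cross-validation on the training set, with features
standardized inside each fold using fold-train statistics only. Grids are
small and standard for a three-feature problem (see `default_grid()`).
Gaussian NB implements variance smoothing by adding
`eps x` (largest feature variance) to every class variance, which keeps
features with zero within-class variance usable (total rotation time sits
exactly at the 20 s ceiling for many well-performing children). Evaluation
reports sensitivity/specificity/accuracy (ASD positive) and AUC by the
rank (Mann–Whitney) formulation, which is exactly the all-pairs
probability with ties counted 1/2. Because a single 10% split of ~100
participants is high-variance, the benchmark also reports an accuracy
averaged over 20 fresh splits reusing the chosen hyperparameters; both
numbers are emitted, clearly labelled.

## Problem sizes and reproducibility

The test suite and the acceptance script run everything at the scale the
methods are specified for: cohorts of 108 participants (18 per cell),
1000-replicate null simulations for the type-I error check, 100 random
score sets for the AUC oracle, and single noiseless sessions for metric
recovery. A single master seed drives every stochastic stage through
documented sub-seeding, and repeated runs are bit-identical. Known
limitations: the simulator's envelope is deliberately simple; the Kalman
noise estimator assumes the 10 Hz low-pass has already removed
out-of-band power; and the cohort-specific effect sizes and classifier
accuracies of any real study depend on its population, so the packaged
defaults describe the simulated conditions, not clinical norms.
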