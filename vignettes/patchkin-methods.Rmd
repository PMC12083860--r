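---
title: "Methods: two-stage kinetics analysis of whole-cell voltage-clamp recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage kinetics analysis of whole-cell voltage-clamp recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The analysis problem

A whole-cell voltage-clamp experiment holds a cell at a fixed membrane
potential and steps it through a family of command voltages while recording
the current needed to hold each potential. Each recording is therefore a
small multivariate time series: one sweep (current trace, pA) per step
potential, plus protocol metadata and the cell's membrane capacitance (pF).
Interpreting these recordings — which channel families are present, whether
gating is normal, what the activation threshold and reversal potential are —
is traditionally manual and slow.

`patchkin` automates this in two stages:

1. **Screening**: a weighted k-nearest-neighbour (KNN) detector flags
   recordings that are incompatible with ion-channel behaviour (aberrant
   transients, currents uncorrelated with voltage, low signal-to-noise,
   erratic tail depolarisations) so they never reach downstream analysis.
2. **Classification**: surviving recordings are assigned to one of six
   kinetic categories (typical multi-channel activity; unsustainable outward
   current; absent fast inactivation; slow gating; disordered overlapping
   currents; hyperpolarisation-activated HCN activity) by a three-branch
   neural network that processes the rising, sustaining and falling phases
   of the response separately and fuses the results.

Stage 2 feeds conventional kinetics analyses: peak currents, current
densities (pA/pF), current–voltage (I–V) curves, activation thresholds,
reversal potentials, and group comparisons.

Because high-quality labelled recordings are rarely shareable, the package
includes a conductance-based simulator that generates labelled synthetic
recordings for every category and anomaly type. All tests and the
replication script run on simulated corpora; no external data is required.

# The simulator

## Model

Each simulated cell is a set of Hodgkin–Huxley style conductances. A channel
carries current

$$I(t) = g_{\max}\, m(t)^p\, h(t)^q\, (V(t) - E_{rev}),$$

with first-order gating

$$\frac{dm}{dt} = \frac{m_\infty(V) - m}{\tau_m},\qquad
  m_\infty(V) = \frac{1}{1 + e^{-(V - V_{1/2})/s}},$$

and likewise for the inactivation gate $h$ (negative slope). Time constants
are voltage-independent. The clamp is treated as ideal: the command voltage
is exactly the membrane voltage, so series-resistance artefacts are not
modelled. Capacitive transients are injected phenomenologically at each
voltage edge as $\pm A\,(\Delta V/100\,\mathrm{mV})\,e^{-t/\tau_c}$, and
recording noise is i.i.d. Gaussian per sample.

Under voltage clamp the command voltage is piecewise constant
(holding → step → holding), so the gating ODE has an exact solution on each
segment: $m(t) = m_\infty + (m_0 - m_\infty)e^{-(t-t_0)/\tau}$. The
per-sample exponential-Euler update coincides with this closed form, which
makes the integrator exact by construction — refining the sampling grid
changes nothing, a property the test suite asserts. Gating variables start
at their steady state for the holding potential.

## Units and conventions

Time is in ms, current in pA, voltage in mV, conductance in nS, capacitance
in pF; current density is then directly in pA/pF. Samples are 0-based and
left-aligned: sample $i$ is the value at time $i/\text{rate}$. The default
depolarising protocol holds at −80 mV and steps to
{−40, −20, 0, +20, +40} mV between 50 and 350 ms of a 500 ms sweep; the
hyperpolarising variant steps through {−120 … −40} mV with the same timing
and is used for HCN-dominated cells. These protocol values are package
defaults chosen to be typical of HEK-cell work — sampling rates and sweep
durations are not physical constants and everything is configurable.

## Category presets

The six categories are built from four base conductances — a fast transient
sodium channel (activation $\tau$ 0.8 ms, inactivation $\tau$ 6 ms, so the
inward transient decays to 10% within roughly 15 ms), a fast-inactivating
A-type potassium channel recruited at depolarised potentials, a
non-inactivating delayed-rectifier potassium channel, and an HCN channel
with inverted voltage dependence ($s < 0$, $E_{rev} \approx -30$ mV):

* **I** Na + A-type + delayed rectifier + leak (typical activity).
* **II** as I, but the delayed rectifier conductance runs down as
  $e^{-t/100\,\mathrm{ms}}$ from stimulus onset, so outward current is
  unsustainable. The package's operational criterion — asserted in tests —
  is that for every sweep at ≥ 0 mV the mean evoked current over the last
  50 ms of the stimulus is below half that sweep's outward peak.
* **III** as I without the A-type channel and with the delayed rectifier's
  activation 10× slower (slow-rising current, no fast inactivation).
* **IV** as I with all gating time constants 5× slower (slow gating).
* **V** as I plus an extra potassium population whose activation midpoint is
  re-drawn per sweep within ±25 mV (disordered, overlapping currents).
* **VI** HCN + leak under the hyperpolarising protocol.

The four anomaly types:

* **I (aberrant transients)** every sweep is simulated from a *different*
  category's cell, with per-sweep amplitude scatter and a per-sweep random
  shift of all activation midpoints (−60 … +20 mV). The shift is what makes
  the phenotype faithful: channels appear at low stimuli and vanish at high
  ones, so the amplitude–voltage relation is broken, not merely noisy.
* **II (no current–voltage correlation)** the stimulated region is replaced
  by amplitude-matched low-pass-filtered noise, uncorrelated with the
  command voltage.
* **III (low SNR)** the noise s.d. is set to 0.8× the largest evoked
  deflection, so every sweep's signal-to-noise ratio is below 2 (category I
  defaults give SNR above 10 by two orders of magnitude).
* **IV (erratic tail)** the post-offset tail is replaced by positive
  random-walk bursts scaled to 10–30% of the sweep's evoked peak (never
  below 6 noise s.d.), riding on the tail baseline. Anchoring burst size to
  the evoked current, rather than the noise floor, matches how such
  artefacts present in practice: they are visible against the signal.

Across cells, $g_{\max}$, $V_{1/2}$, $\tau$ and the capacitance receive 10%
multiplicative log-normal jitter, producing within-class variability that
makes classification non-trivial but attainable. One dataset seed is split
deterministically into per-recording seeds, so every corpus is
bit-reproducible.

## What the simulator does not emulate

Stochastic single-channel gating, rundown other than the category-II
construct, series-resistance and space-clamp errors, liquid-junction
potentials, ligand-gated or calcium-dependent kinetics, and temperature
effects. Passing tests therefore demonstrate that the pipeline recovers the
structure this generative model implants; accuracy numbers on synthetic
corpora characterise the method under these controlled conditions, not
performance on any particular laboratory's recordings.

# Stage 1: anomaly detection

## Features

Each recording maps to a fixed-length vector (version `pk-feat-1`),
concatenating per sweep (sweeps in ascending step-potential order):

* the sweep's shape: the jointly z-scored recording decimated to 100
  samples by block mean pooling (scale-invariant);
* seven raw-current statistics: outward and inward baseline-subtracted peak,
  late-stimulus mean (last 50 ms), tail mean and s.d. (measured from 5 ms
  after offset, past the capacitive transient), a smoothed signal-to-noise
  estimate, and the largest positive tail excursion in baseline-noise units;

plus four recording-level consistency statistics: the Spearman correlation
of the late-stimulus mean with the step potential, the absolute Spearman
correlation of evoked amplitude with step potential, and the shape
correlation and log-amplitude-ratio of the two largest sweeps. The SNR
estimate smooths the evoked trace over ~5 ms before taking its peak, so the
maximum of thousands of noise samples cannot masquerade as signal.

## Metric and vote

Features are standardised per dimension with training statistics and
compared by a block-balanced Euclidean metric: a sweep's 100 shape
dimensions jointly carry the squared-distance weight of one statistic, and
the four recording-level dimensions jointly carry the weight of all
per-sweep blocks combined. Without this balancing, distance is dominated by
raw dimensionality and the recording-level evidence — which is precisely
what defines "incompatible with channel behaviour" — is invisible to the
neighbourhood structure. On plain matrices without weight annotations the
detector reduces to standard Euclidean KNN, which is what the oracle
equivalence tests exercise.

Prediction ranks training points by distance (ties by training index),
takes the k nearest (default k = 5, selected by validation grid search over
{1, 3, 5, 7, 9}), and votes. Inverse-distance weighting
($\sum 1/(d+10^{-9})$ per class) is the default; uniform voting implements
the plain majority rule exactly and is verified against an exhaustive
brute-force oracle on a thousand random instances. Class-score ties resolve
to *abnormal* — for a screening step, a false alarm is cheaper than a
contaminated analysis.

A PCA embedding (centred, signs fixed by making each component's
largest-magnitude loading positive) provides the two-dimensional
visualisation of the detector's separation, and a benchmark harness runs
LDA, naive Bayes, random forest, decision tree, extra-trees and gradient
boosting from the standard libraries on the same features for comparison.

# Stage 2: the phase classifier

## Preprocessing

Each recording is z-scored jointly over all sweeps — per-sweep normalisation
would erase the cross-sweep amplitude relations that encode voltage
dependence. The post-onset samples are segmented into rising
[onset, onset + 30 ms), sustaining [onset + 30 ms, offset) and falling
[offset, end) phases; pre-stimulus samples carry no category information in
this model and are excluded. Each phase is cut into non-overlapping 10 ms
windows (remainders dropped to avoid edge artefacts), giving a
windows × samples × sweeps tensor per phase. Both boundary parameters are
configuration values exercised by the grid-search harness.

## Architecture

One branch per phase: per window, a valid 1-D convolution over time with
the sweeps as input channels (32 filters, kernel 7 samples) → ReLU → max
pooling (2) → dense (64) gives a window embedding; the window sequence runs
through a bidirectional LSTM (64 units per direction, concatenated) →
dropout 0.2 → additive attention over windows (weights normalised to sum
to 1) → the attention-weighted sequence (scaled by the window count so a
uniform attention leaves magnitudes unchanged) → global max pooling →
dense logits over the six categories.

The whole-phase probability is a convex combination of the three branch
probabilities under a learned softmax over three phase-weight logits. Of the
several ways to fuse the phase outputs, this one was chosen because it is
interpretable (the weights are readable as phase importances), preserves the
probability simplex by construction, and makes the identity "if all phases
agree with probability ≥ q, the fused confidence is ≥ q" trivially true —
all asserted in tests.

## Training

Branches and phase weights train jointly by Adam (base rate 1e-3, cosine
decay, batch 16, 100 epochs — enough for the slowest-converging branch, the
falling phase, to stabilise across random initialisations) on the sum of
whole-phase and per-phase cross-entropies; the per-phase terms keep each branch individually
predictive so per-phase accuracies are meaningful. The training set is split
8:2 into train and validation strata per class, with a seeded RNG governing
initialisation, the split, shuffling and dropout, so training is
bit-reproducible on one platform in single-threaded mode. Every layer's
backward pass is hand-derived and verified against numerical
differentiation in the test suite (worst relative error below 1e-3; the
occasional larger finite-difference discrepancy is a crossed max-pooling
tie, a genuine subgradient point).

At deployment a prediction is *accepted* only if its confidence (maximum
fused probability) reaches 0.8 and at least two of the three phase labels
agree with the fused label; otherwise it is flagged `REJECTED`. During
evaluation rejection is disabled so test-set metrics cover every recording.

## Evaluation

Reports cover the fused output and each branch separately: accuracy,
per-class precision/recall/F1, macro F1, Cohen's kappa, the multiclass
Matthews correlation coefficient, the confusion matrix, and one-vs-rest
precision–recall (average precision by step integration) and ROC curves
(AUC by the rank statistic, exact under ties). The curve implementations are
cross-checked against an independent reference implementation in the tests.

# Kinetics

Peak measurement shares the classifier's segmentation: the inward peak is
the most negative baseline-subtracted deflection within the rising phase,
the outward peak the most positive anywhere in the stimulus; the baseline is
the mean of the 20 ms before onset, and peaks are clipped at zero toward
their own polarity. I–V curves aggregate per-voltage mean ± s.d. of peak
densities across recordings. The activation threshold is the smallest step
whose absolute mean density reaches 2 pA/pF — small against typical evoked
densities of tens of pA/pF, but above the simulator's noise floor. Reversal
potentials are linearly interpolated at the zero crossing of the *steady*
I–V curve — the signed late-stimulus mean *without* baseline subtraction,
since subtracting the holding current would make the evoked current vanish
at the holding potential and pin a spurious zero there; polarity-clipped
peak curves cannot cross zero and are equally unsuitable. The estimate is
only meaningful where the channel conducts around its reversal (as in any
experimental reversal measurement). With 20 mV step spacing this recovers
single-channel reversal potentials with a median error under 2 mV, verified
by parameter-recovery tests on channels open across the scan range. Group comparisons delegate to Welch's
t-test (two groups) or one-way ANOVA with Tukey HSD (more), with the
conventional star mapping (*, **, ***, **** at 0.05, 0.01, 0.001, 0.0001).

# Problem sizes and numerical choices

The replication suite uses the corpus sizes of the study design: 240
training and 144 test recordings for detection (three independent seeds;
reported values are medians, so the bar must hold in at least two of three),
and 139 training / 124 test recordings over six near-balanced categories
for classification. Per-category counts within the classification split are
an even allocation (24+23×5 / 21×4+20×2), since only the totals are fixed
by the design. Classifier corpora are generated at 1 kHz (1 sample/ms) —
500 samples per sweep fully resolve the slowest and fastest preset kinetics
while keeping a full training run around a minute on one CPU; the
detection corpora use the default 10 kHz. Probability floors of 1e-12 guard
the cross-entropy; softmax computations subtract row maxima; the forget-gate
bias initialises at 1 (standard LSTM practice); weights use Glorot-uniform
initialisation.

# Known limitations

* The HDF5 container and CSV are the exchange formats; vendor binary
  formats (e.g. ABF) must be converted externally before import.
* Synthetic anomaly phenotypes are operational definitions — stated above
  and in the reference pages — of qualitative descriptions; real anomalous
  recordings are more varied.
* The classifier assumes the acquisition protocol matches training
  (timing, rate, sweep count are checked; a mismatch raises an error rather
  than silently resampling).
* Training determinism is per-platform (BLAS reduction order may differ
  across builds); the replication bars, not bitwise weights, are the
  cross-platform contract.
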