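---
title: "From single-lead ECG to MI localization: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From single-lead ECG to MI localization: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcgmi)
```

## The problem

Wearable ECG monitors typically record a single lead (lead I), which is
a poor basis for diagnosing and localizing myocardial infarction (MI):
clinicians localize infarcts by comparing deflections across many leads.
Vectorcardiography (VCG) captures the heart's electrical activity as a
3-D vector on three orthogonal Frank leads (Vx, Vy, Vz) with far fewer
electrodes than the 12-lead ECG, and the three Frank leads carry most of
the spatial information an MI classifier needs.

`vcgmi` implements a four-stage pipeline that makes single-lead
recordings usable for 12-class MI localization (11 infarct sites plus
healthy control):

1. **Preprocessing** — resample to 500 Hz, zero-phase band-pass
   0.5–150 Hz.
2. **VCG synthesis** — a patient-specific recurrent network maps a
   sliding window of lead-I samples to the synchronous Frank X/Y/Z
   samples.
3. **Feature extraction** — heartbeats are segmented between R peaks,
   period-normalized to 400 samples, min–max scaled, and represented by
   16 least-squares B-spline coefficients per lead; together with the
   time factor $\alpha$ and three amplitude factors $\beta$ this gives a
   52-dimensional per-beat vector.
4. **Classification** — a SMOTE-balanced multilayer perceptron
   (52–300–275–12, ReLU hidden units, softmax output, cross-entropy
   loss) assigns each beat to one of the 12 classes.

## The synthesis model

For window length $L$ the training pairs couple
$s_t = \{x_{t-L+1},\dots,x_t\}$ (lead-I history) with
$y_t = (y_t^{(1)}, y_t^{(2)}, y_t^{(3)})$ (Frank X, Y, Z at time $t$).
Each window is presented to a two-layer recurrent network of LSTM units
(30 per layer) as a sequence of scalars; the cell follows the standard
gate equations

$$f_t = \sigma(W_f x_t + U_f h_{t-1} + b_f), \quad
  i_t = \sigma(W_i x_t + U_i h_{t-1} + b_i),$$
$$c_t = f_t \circ c_{t-1} + i_t \circ \tanh(W_c x_t + U_c h_{t-1} + b_c),$$
$$o_t = \sigma(W_o x_t + U_o h_{t-1} + b_o), \quad
  h_t = o_t \circ \tanh(c_t),$$

and the final hidden state is linearly projected to the three targets.
Mean squared error is minimized by Adam over mini-batches of windows.

Interpretation choices that the published procedure leaves open,
decided here once:

* **"Time step of 1"** is read as stride-1 sliding windows; each window
  is an independent many-to-one training example with hidden state reset
  between windows.
* **Optimizer**: Adam from the first epoch (a two-phase SGD-then-Adam
  schedule is under-determined), learning rate $10^{-3}$ by default,
  configurable.
* **Standardization**: inputs and targets are z-scored per record before
  training and predictions un-standardized afterwards; this is purely a
  conditioning device and fidelity metrics (RMSE) are reported in native
  units (mV).
* **Window cap**: `max_train_windows` evenly subsamples the stride-1
  window set when a record provides more windows than a training run
  needs. The mapping is stationary along the record, so this is compute
  scaling, not a change of the learning problem. Default 20000.

The feedforward baseline (`baseline_mlp_synthesizer`) flattens the
window into a 150-vector and uses two ReLU hidden layers of 150 units;
it shares the windowing, loss, and derive contract.

Synthesis fidelity is measured per lead by RMSE and by the *uncentered*
correlation
$\mathrm{CC} = \sum_i V_i \hat V_i \big/ \sqrt{\sum_i V_i^2 \sum_i \hat V_i^2}$,
which is scale-invariant but deliberately not shift-invariant (a
baseline offset in a derived lead is a real error and should be
penalized).

## Beat representation

R peaks are detected with the Pan–Tompkins algorithm (5–15 Hz band-pass,
five-point derivative, squaring, 150 ms moving-window integration,
adaptive dual thresholds, 200 ms refractory period, search-back).  The
published procedure does not fix the detector's internal constants; the classic
published ones are used and exposed in `detect_r_peaks(params = )`.
Fiducials are detected once on a single reference channel (derived
$\hat V_x$ by default, configurable) and shared across leads, so the
three per-lead feature blocks of one heartbeat are time-aligned.
"Individually processed" leads are read as per-lead normalization and
fitting, not per-lead fiducials.

Each beat (R-to-R, physiological length 0.2–3 s; others rejected and
counted) is interpolated by a cubic spline onto 400 evenly spaced
points, recording $\alpha_i = N_i/400$, then min–max scaled to $[0,1]$
with $\beta$ = amplitude range.  The normalized time axis is taken as
$t_j = j/400$, $j = 1,\dots,400$, i.e. $t \in [0.0025, 1]$ — the only
reading under which the spline domain endpoints 0.0025 and 1 coincide
with the data support.  This is an assumption, recorded here, not an
established intent of the procedure it implements.

## The spline basis

The knot vector is clamped: $p+1$ knots at 0.0025 and at 1, with
interior knots at knot averages
$\zeta_k = (\tau_{k+1} + \dots + \tau_{k+p})/p$ of an arithmetic
sequence $\tau_{p+1} = 0.0025, \dots, \tau_m = 1$, $m = n + p + 1$.
Basis functions follow the Cox–de Boor recursion with the $0/0 = 0$
convention; at the right endpoint the last knot span is treated as
closed so the partition of unity holds on the whole domain.  Degree
$p = 3$ (cubic) is a package choice — no degree is prescribed by the
procedure, but cubic matches the cubic interpolation used for beat
normalization — and is configurable.  $n = 15$ (16
coefficients per lead) is the default trade-off; $n = 23$ is supported
for finer fits, and the least-squares residual is non-increasing in $n$.
Fits are solved by QR decomposition of the design matrix, not normal
equations; an independent normal-equations solve on a `splineDesign`
basis serves as the test oracle.

## Classifier and evaluation

SMOTE brings every minority class up to the majority count by
interpolating between a minority sample and one of its $k = 5$ nearest
same-class neighbors. It is applied **inside each training fold only**.
A global application before splitting would leak synthetic points (which
interpolate real ones) into test folds; the per-fold reading is the
package's documented deviation from the looser phrasing "before
training".  Feature standardization is likewise fitted on training folds
only.  Cross-validation folds are stratified per class and assigned
after sorting rows into a canonical content order, which makes the whole
procedure invariant to permutations of the input rows.

Metrics follow the one-vs-rest conventions: per class,
$\mathrm{ACC} = (TP+TN)/\text{total}$, $\mathrm{SEN} = TP/(TP+FN)$,
$\mathrm{SPE} = TN/(FP+TN)$; overall accuracy is micro (trace/total),
and overall sensitivity/specificity are **unweighted macro averages** of
the per-class values — the definition was left open and the macro
reading is the one that reproduces the reference tables' overall rows
from their per-class values.  Display rounding is half-up to two
decimals; computations keep full precision.  The bundled reference
confusion matrices (`inst/extdata/confusion_*.tsv`) act as golden values
for these definitions; one overall cell of the three-lead table is
internally inconsistent by 0.01 (its matrix yields 99.1449% micro
accuracy, reported there as 99.15), and the tests assert the honest
recomputation to printed precision.

## What the synthetic generator emulates — and what it does not

All tests run on seeded synthetic records from `generate_record()`: a
3-axis dipole trajectory built from five Gaussian kernels per axis
(P, Q, R, S, T waves at fixed phase fractions of the RR interval), with
every lead an exact linear projection of the same dipole (rows: lead I =
x-axis rotated 15° in the xy-plane; Frank rows = identity), uniform RR
jitter, sinusoidal baseline wander, and white noise.  Defaults: 500 Hz,
mean RR 0.8 s (the nominal 400-sample beat), 5% RR jitter, 0.02 mV
noise, 0.1 mV wander at 0.3 Hz — values a physiologist would call
unremarkable for resting ECG.  Class-conditional morphology is a fixed
lookup table of amplitude offsets (deepened Q, flattened/inverted T,
tall posterior R) on the axis subsets each MI localization projects
onto.

This emulates exactly the structure the pipeline relies on — shared
dipole source (inter-lead correlation), quasi-periodicity (intra-lead
correlation), detectable R peaks, class-dependent morphology — and
nothing more.  It does not model ectopy, conduction abnormalities,
electrode artifacts, heart-rate drift, or the within-class variability
of real patients.  A green end-to-end test therefore establishes that
the pipeline's stages compose correctly and can recover structure that
is present by construction; it does not establish clinical performance,
which requires real recordings (e.g. the PTB diagnostic database) and
full-scale training (300 epochs per record; out of scope for the test
suite, whose configurations are scaled down and say so).

## Numerical choices

* **Band-pass realization**: the 0.5–150 Hz filter is applied in the
  frequency domain as the squared-magnitude response of a 4th-order
  Butterworth (high-pass and low-pass cascaded), with 4 s mirror
  padding.  This is the exact zero-phase response that forward–backward
  IIR filtering approximates, without its startup transients; R-peak
  positions shift by at most 2 samples.
* **Resampling** uses cubic-spline interpolation; a record already at
  the target rate passes through untouched.
* **Recurrent core** is compiled (RcppArmadillo) with the four gate
  blocks stacked into single GEMMs; an R-level `lstm_step()` defines the
  reference semantics and the compiled path is tested against it to
  1e-10, with BPTT gradients checked numerically to 1e-4.
* **Ties** at the classifier argmax break to the lowest class index.
* **Degenerate beats** (constant over a lead) cannot be min–max scaled
  and are rejected with a counted reason, as are beats outside 0.2–3 s.
* **Edge effects**: the first and last 0.5 s of a filtered record are
  flagged and excluded from beat segmentation.

## Known limitations

* Training is CPU-only and patient-specific; no generic cross-patient
  transformation is provided.
* The WFDB reader supports the single-`.dat`, format-16 layout this
  package writes (sufficient for round-trip tests); it is not a general
  WFDB implementation.
* SMOTE with very small classes (fewer than $k+1$ members) lowers $k$
  per class; singleton classes are an error rather than duplicated.
* Real-data (PTB) experiments are supported through the same interfaces
  but are not part of the test surface.
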