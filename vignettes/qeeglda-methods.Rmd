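---
title: "Spectral parameterization and regularized LDA for dementia EEG: methods"
author: "qeeglda authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral parameterization and regularized LDA for dementia EEG: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(qeeglda)
```

This vignette is the package's own account of its science: the spectral
model and its assumptions, what the synthetic cohort generator emulates
(and what it deliberately does not), the parameters that matter, and the
numerical decisions taken where the design was genuinely open.

## 1. The analysis in one page

A resting 22-channel EEG recording is reduced to six numbers per channel
and those numbers are used to separate diagnostic groups:

1. **Preprocessing** — resample to 256 Hz, band-pass 0.5–50 Hz with
   least-squares linear-phase FIR filters applied zero-phase, reject
   artifactual 1-s epochs, re-concatenate the survivors.
2. **Spectra** — segment into 2-s epochs with 1-s overlap, rectangular
   window, FFT each epoch, average: Welch's estimate on a 100-point
   0.5–50 Hz grid (0.5 Hz resolution), per channel.
3. **Spectral fit** — fit
   $P(f) = b + S f^{-k} + A \exp\{-(f-c)^2/(2w^2)\}$
   to each channel's average spectrum over 0.5–30 Hz by bounded
   nonlinear least squares; report $R^2$.
4. **Features** — 6 parameters × 22 channels = 132 predictors per
   subject; Box–Cox normalization; optional correlation screening
   (reject $|r| < 0.15$ against the class labels).
5. **Classifier** — binary LDA with the pooled within-class covariance
   replaced by its analytic shrinkage estimate
   $\hat\Sigma = (1-\lambda) S + \lambda \nu I$.
6. **Evaluation** — stratified 10-fold cross-validation with the
   transform and the screen fitted per training fold, repeated 20 times
   with re-randomized folds; mean cv-accuracy and mean AUC with SEMs;
   vertically averaged ROC curves. Four contrasts are evaluated:
   HC vs AD, HC vs VaD, AD vs VaD, HC vs pooled dementia.

## 2. The spectral model

The model decomposes a resting spectrum into an aperiodic 1/f component
(scale $S$, exponent $k$), a single Gaussian alpha peak (amplitude $A$,
center $c$, dispersion $w$) and a frequency-independent floor $b$. Units:
power parameters in µV² per 0.5-Hz bin, $c$ and $w$ in Hz. Bounds used by
both generator and fitter: $S, A, b \ge 0$; $k \in [0, 5]$;
$c \in [6, 14]$ Hz; $w \in [0.3, 5]$ Hz.

Assumptions worth making explicit:

* **One oscillatory peak.** Theta or beta oscillations are not modeled
  separately; theta power loads on $S$ and $k$, beta on $b$. This limits
  what the features can express about contrasts that hinge on an
  independent theta component.
* **Linear power space.** The fit minimizes squared error in power, not
  log-power, so $R^2$ is the fraction of the spectrum's variance
  captured. A `log_space = TRUE` option exists; it reweights the fit
  toward high frequencies.
* **Weak identifiability at small $k$.** When the 1/f slope is shallow,
  $S f^{-k}$ is nearly flat and only combinations of $(S, k, b)$ are
  identified; fitted $k$ and $b$ are therefore correlated across
  subjects even when their true values are independent. This is a
  property of the model class, not an optimizer defect, and is the
  reason the package ships a `param_correlations()` redundancy audit.

**Fitting.** Bounded Levenberg–Marquardt over the 60 points of the
0.5–30 Hz band. Starting values from the data: $b_0$ = minimum power in
25–30 Hz; $k_0$ = negative slope of the log-log regression on 1–30 Hz
after subtracting $b_0$; $S_0$ = power at 1 Hz minus $b_0$; $c_0, A_0$ =
location/height of the residual maximum in 7–13 Hz; $w_0 = 1.5$ Hz. If
the first attempt leaves $R^2 < 0.999$, up to 4 jittered restarts run
under a fixed internal seed and the best-$R^2$ solution is kept. Fits
never throw on poor spectra; they return `converged = FALSE` with the
best attempt, so a single bad channel cannot abort a cohort run.

## 3. The synthetic cohort generator

No clinical recordings ship with the package; the generator defines the
study conditions instead. Its central design decision is to **invert the
analysis model**: subjects are drawn with known parameter vectors, and
time series are colored noise whose expected Welch spectrum *is* the
model curve (random-phase inverse FFT over 0.5–50 Hz). Parameter
recovery is then a well-posed end-to-end test of the entire pipeline.

**Group profiles.** HC is the base: $S = 15$, $k = 1.2$, $b = 1$,
$c = 10$ Hz, $w = 1.5$ Hz, with alpha amplitude 18 µV² posteriorly,
10 µV² centrally, 6 µV² frontally. At `effect_scale = 1`:

* AD: $S \times 1.3$ globally, posterior $A \times 0.7$, posterior
  $c - 1$ Hz;
* VaD: $S \times 1.8$ globally, $A \times 0.8$ everywhere, posterior
  $c - 1$ Hz.

Directions follow the clinical literature: both dementias raise
low-frequency power and lose alpha; VaD's low-frequency rise is
stronger; AD's alpha loss is posterior-dominant; and the slowing of the
posterior dominant rhythm is common to both dementias — which is why the
AD-vs-VaD contrast is structurally the hardest and the HC-vs-dementia
contrast the easiest, matching the ordering such cohorts show in
practice. All deviations scale linearly with `effect_scale`, and at 0
the three groups are exchangeable — the basis of the null-calibration
tests.

**Between-subject variability.** Parameters jitter normally around the
profile (SDs: $S$ 8, $k$ 0.3, $A$ 6, $c$ 1.2 Hz, $w$ 0.4, $b$ 0.5),
clipped at the physical bounds. The jitter mixes a subject-level
component shared by all channels with an independent per-channel
component (across-channel correlation 0.7). Both choices are realism
choices: clinical qEEG varies between subjects by amounts comparable to
the group effects, and that variability is largely global — a subject's
skull conductivity, vigilance and individual alpha level shift the whole
head coherently. The shared component matters statistically: with
independent per-channel jitter a 132-feature classifier would average
the noise away and every contrast would saturate near AUC 1.0, which
emulates no clinical cohort. An optional `kb_cor` couples the $k$ and
$b$ jitter for studying parameter-redundancy recovery.

**Artifacts.** With probability `artifact_rate` per second (default
0.02) a 0.25-s Gaussian-windowed 4-Hz transient with ≥ 500 µV peak is
added on all channels with random polarity — the kind of high-amplitude
event amplitude thresholding removes. Ocular artifact morphology (and
hence ICA) is deliberately out of scope; the generator's artifacts are
threshold-removable by construction.

**What passing tests do and do not show.** The generator draws
stationary, Gaussian, linearly mixed data whose spectra lie exactly in
the fitted model class. Real EEG is nonstationary (vigilance drifts,
eyes-open/closed alternation), contains non-Gaussian artifacts that
survive thresholding, and has spectra the model only approximates.
Pipeline correctness, leakage-freedom, calibration and
parameter-recovery results transfer to real data; absolute AUC levels do
not.

**Direct-spectra mode.** For cohort-scale runs the generator can skip
time-series synthesis and draw each subject's Welch-averaged spectrum
directly: the model curve times per-bin Gamma noise with shape equal to
the effective number of independent epochs ($n/1.5$ for 50% overlap with
rectangular windows), matching the first two moments of an averaged
periodogram. The time-series path and this shortcut agree in
expectation; the time-series path remains the one exercised by the
recovery tests.

## 4. Preprocessing decisions

* **Filters.** The band-pass is a 1536-order least-squares linear-phase
  FIR high-pass at 0.5 Hz cascaded with a 512-order low-pass at 50 Hz.
  No least-squares FIR designer exists in the R package stack used, so
  the design (closed-form band-integral normal equations for type-I
  filters, piecewise-linear desired response) is implemented in
  `fir_ls()`. Two numerical choices: transition bands are specified
  explicitly (linear ramps 0.25→0.5 Hz and 50→57.5 Hz) rather than left
  as don't-care, which keeps the normal equations well-conditioned at
  generous orders; and the high-pass taps are mean-corrected so the DC
  response is exactly zero. Filters are applied zero-phase by
  compensating the linear-phase group delay; measured responses: ≤ 1%
  error at 10 Hz, ≥ 20 dB attenuation at 60 Hz.
* **Resampling** uses polyphase band-limited interpolation
  (`signal::resample`) with 10 sidelobes per branch (passband droop
  < 0.2%); 128 Hz doubles, 500 Hz converts by 64/125.
* **Artifact rejection** scans non-overlapping 1-s epochs with three
  criteria: maximum absolute amplitude > 100 µV; broadband power
  z-score > 4 across epochs; spatial-deviation (sSTD) z-score > 3. The
  sSTD index is implemented as the standard deviation of per-channel
  log₁₀ power across the 22 channels — an interpretation chosen here;
  the index's original definition admits variants. Thresholds are
  configurable; the defaults are typical clinical-qEEG values and the
  synthetic tests pin their behavior. Surviving epochs are concatenated
  before 2-s segmentation, mirroring reconstruction of continuous data.
  Note that with ~300+ epochs, z-score criteria reject a fraction of a
  percent of genuinely clean epochs by construction; cohort runs
  standardize to the first 334 epochs to keep the averaged epoch count
  identical across subjects.
* **Power convention.** Epoch spectra are scaled so the summed power
  over all positive-frequency bins equals the epoch's variance
  (Parseval); each of the 100 retained bins is total power per 0.5-Hz
  bin, not density, so band sums are band power in µV².
* **Mastoids** M1/M2 are analysis channels like the other 20.

## 5. Features, transform, screening

The 132-column predictor matrix is laid out channel-major
(`Fp1_S, Fp1_k, …, M2_b`). Box–Cox $\lambda$ is estimated per column by
maximizing the profile log-likelihood; $\lambda = 0$ is the natural log.
Columns are shifted positive when needed (shift = 10⁻³·SD − min of
training values, recorded); rows outside the training range are clamped
at half the smallest shifted training value so the power transform stays
defined — all three quantities (λ, shift, clamp) derive from training
rows only.

Screening computes the point-biserial correlation $r$ of each column
with the 0/1 labels on training rows, with the two-tailed p-value from
$t = r\sqrt{(n-2)/(1-r^2)}$. The default rule rejects columns with
$|r| < 0.15$; a `"conjunction"` option additionally requires
$p \le 0.01$ for a column to be kept. The two-threshold phrasing of this
screen is ambiguous in the literature this follows (does rejection
require both a small and a non-significant correlation?); the magnitude
rule is the default because at $n \approx 200$ the $p$-criterion is
implied by the $r$-criterion almost everywhere, and both rules are
recorded in the screening report.

**Leakage policy.** The transform and the screen are fitted inside each
training fold by default. A `boxcox = "global"` mode (one transform on
all rows before splitting) reproduces the common-but-leaky variant of
this design for comparison; it is off by default.

## 6. The regularized discriminant

Class means are estimated per class; rows are centered by their own
class mean; the pooled centered sample is shrunk once:
$\hat\Sigma = (1-\lambda) S + \lambda \nu I$ with $\nu =
\mathrm{tr}(S)/p$ and the closed-form Ledoit–Wolf intensity
$\lambda = \min(b^2, d^2)/d^2$, where $d^2 = \|S - \nu I\|_F^2$ and
$b^2 = n^{-2}\sum_t \|x_t x_t' - S\|_F^2$. Properties the tests pin:
$\lambda \in [0,1]$; every eigenvalue of $\hat\Sigma$ lies between the
corresponding eigenvalue of $S$ and $\nu$ (so $\hat\Sigma$ is positive
definite whenever $\nu > 0$, including $p > n$); $\lambda \to 0$ as
$n \to \infty$ when the truth is far from spherical; and the estimator
agrees with an independent reference implementation to double
precision. One behavior worth knowing: when the true covariance *is*
spherical, optimal shrinkage is large (the target equals the truth), so
$\lambda$ near 1 on near-spherical data is correct, not a failure.

The weight vector solves $\hat\Sigma w = \mu_1 - \mu_0$ (linear solve,
no explicit inverse); the threshold is the midpoint
$w'(\mu_0+\mu_1)/2$ — equal priors, appropriate for the balanced
designs this pipeline targets. With $\lambda = 0$ the discriminant
direction coincides with classical pooled-covariance LDA (pinned against
`MASS::lda`).

## 7. Cross-validation and reporting

* **Folds.** 228 is not divisible by 10; stratified folds of 22–23 are
  used (the alternative reading — fixed fold size 22 with a discarded
  remainder — is not used because it silently drops subjects).
  Stratification by class is on by default to prevent class-empty
  training folds at small n.
* **Repeats.** "Bootstrap" here means 20 repetitions of the full CV with
  re-randomized fold assignment — robustness to the permutation of
  subjects — not resampling with replacement (a true resampling mode
  exists in the fold splitter's seed interface but is not the default
  reporting path).
* **AUC.** Each repeat's AUC comes from its pooled held-out scores via a
  tie-aware threshold sweep whose trapezoid area equals the Mann–Whitney
  $U/(n_0 n_1)$ exactly. ROC curves for plotting are vertically averaged
  on a 101-point FPR grid with SEM bands; per-fold mean TPR/FPR
  operating points are reported alongside.
* **Positive classes.** Patients in HC-vs-patient contrasts; VaD in
  AD vs VaD.
* **Determinism.** One master seed fans out to per-stage seeds through a
  label-hash scheme (`derive_seed`), so any stage can be reproduced in
  isolation and two runs with the same config are identical.

## 8. Problem sizes used by the test suite

The suite exercises the study design sizes where the quantity under test
depends on them: 114 subjects per group (228-row contrasts, 342-subject
three-group cohorts), 334 two-second epochs per subject, 132 predictors,
10 folds, 20 repeats. Unit tests of individual operations use the
smallest sizes that expose the property (e.g. 6-subject groups for fold
mechanics, 50 subjects for noisy parameter recovery, 1000 draws for
generator calibration). Direct-spectra mode supplies cohort-scale inputs
to the classifier tests; the time-series path is exercised end-to-end in
the recovery and agreement tests.

## 9. Known limitations

* No EDF reader: cohort I/O uses the documented CSV layouts. Real-data
  use requires converting EDF to the signal CSV format (one comment
  header line, then time × channels).
* No ICA and no realistic ocular/muscle artifact morphology; the
  rejection stage only addresses threshold-detectable transients.
* Recordings are treated as stationary; eyes-open/closed alternation
  within a session is not modeled.
* The spectral model has a single alpha peak; contrasts driven by an
  independent theta component are outside its expressiveness.
* Age/gender covariates are not simulated; group balance stands in for
  matching.
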