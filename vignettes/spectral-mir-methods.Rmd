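---
title: "Directed coupling between interacting brains: the spectral MIR pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed coupling between interacting brains: the spectral MIR pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In fNIRS hyperscanning, two interacting people are recorded simultaneously
and the question is not merely whether their cortical hemodynamics are
correlated but **who drives whom**. The setting `dyadmir` targets is a
dyadic imitation protocol: one participant (the *Model*) performs an
instructed movement, the other (the *Imitator*) copies it, so the ground
truth direction of influence is known by design. The obstacles are severe:
epochs are short (a 20 s task interval is ~204 samples at ~10 Hz), the
inter-personal delay is one or two samples, and systemic physiology — most
prominently ~0.1 Hz Mayer waves — is shared between participants and acts
as a confounder that mimics coupling.

## Model and measures

Each analysis unit is a `dyad_epoch`: the region's channels of both
participants, Model block first, $X = [X_M\; X_I]$, z-normalized per
channel. A vector autoregression of order $p$ (selected per epoch by MDL,
$p \le 2$ so a 1–2 sample delay is representable without overfitting 204
samples) is fitted by least squares and rewritten in innovations/companion
state-space form with transfer function
$H(\omega) = I + C(I - A e^{-i\omega})^{-1} K e^{-i\omega}$ and spectral
factorization $S_X(\omega) = H \Sigma_W H^*$.

The total linear interdependence at each normalized angular frequency is
the Geweke log-determinant measure
$$f_{M;I}(\omega) = \log\frac{|S_M(\omega)|\,|S_I(\omega)|}{|S_X(\omega)|},$$
which factorizes exactly into two directed terms and an instantaneous
term, $f_{M;I} = f_{M\to I} + f_{I\to M} + f_{M\cdot I}$ — the
frequency-domain decomposition of the mutual information rate of the two
processes (in nats). Each directed term is formed after orthogonalizing
the innovations for that direction (left-multiplication by the
block-triangular factor of $\Sigma_W$): without this normalization the
three-way identity fails whenever the innovation covariance has cross-block
correlation. `mir_decompose()` computes the instantaneous term from its own
closed form and verifies the identity numerically at every frequency (it
errors beyond `1e-8`); directed terms are clamped at zero below `-1e-6`.

The signed causal spectrum is $C(\omega) = f_{M\to I} - f_{I\to M}$, and
the epoch's scalar statistic is its band integral
$$C_{M\to I} = \frac{1}{4\pi}\int_{\omega_1}^{\omega_2} \tilde C(\omega)\,
d\omega$$
over 0.008–0.08 Hz by default — below motion-related frequencies and below
the Mayer band. Only in-band grid samples enter the trapezoid; edge values
are constant-extended rather than interpolated with out-of-band points, so
the noisy near-DC estimates cannot leak into the band value.

## Significance and the direction decision

Per-frequency significance uses phase-randomization surrogates: each
channel keeps its amplitude spectrum while all phases (hence all
cross-channel lead/lag structure) are randomized, independently per
channel; the observed directed spectra are compared against the mean of a
10-member surrogate ensemble, pointwise. In the band integral,
$\tilde C(\omega)$ keeps $C(\omega)$ at frequencies where either directed
term is significant and is zero elsewhere (`mask_convention =
"frequency"`). The alternative of masking each directed term separately is
available (`"per_term"`), but when the two masks disagree at a frequency it
injects one-sided mass — the full magnitude of a single directed term
rather than the difference — which inflates the null distribution of the
band value several-fold; keeping the difference intact lets the strongly
correlated estimation noise of the two directions cancel, which is the
point of using a signed difference in the first place.

The decision calibrates against short-distance channels (SDCs), which see
scalp and systemic physiology but no cortical signal. $C_{\text{short}}$
is the per-dyad mean of the same masked band statistic computed on SDC
epochs; the rule is
*Model→Imitator* if $C > C_{\text{short}} + \epsilon$,
*Imitator→Model* if $C < C_{\text{short}} - \epsilon$, else *none*, with
$\epsilon = 10^{-4}$. Two remarks. First, the rule is applied literally:
a positive $C$ far below $C_{\text{short}} - \epsilon$ is classified
Imitator→Model. Second, the log-determinant measures grow with block
dimension, so a 3-vs-3 SDC block is not on the scale of a low-dimensional
region statistic; by default the SDC baseline is computed from bivariate
Model-SDC$_i$/Imitator-SDC$_i$ pairs and averaged over pairs and trials
(`pairing = "pairwise"`), which both matches scales and averages more
estimation noise out of the calibration constant. The single-block variant
is `pairing = "block"`.

## Filtering and why the pipeline can skip it

Band-pass filtering (5th-order Butterworth, 0.008–0.2 Hz, zero-phase by
default, forward mode available) is implemented for real recordings, which
carry drifts, cardiac (~1 Hz) and respiratory (~0.25 Hz) power that the
short-epoch VAR cannot absorb. The filter is realized as an analytically
designed cascade of second-order sections: at ~10 Hz sampling this band
occupies ~2% of the Nyquist range and a single 10th-order polynomial
realization is numerically unusable (its roots cluster at $z = 1$), while
the biquad cascade matches the closed-form Butterworth magnitude
(`bandpass_gain()`) to better than 0.01 dB.

Filtering this aggressively before fitting a VAR, however, is itself a
known failure mode of Granger-causal inference: the filtered process is
nearly deterministic sample-to-sample, the fitted companion poles approach
the unit circle, innovation covariances approach singularity, and the
log-determinant measures become numerically enormous and sign-unstable.
On simulated dyads this is dramatic — with pre-filtering, task-direction
accuracy drops to chance and the no-coupling decision essentially never
fires, while the identical pipeline without the filter recovers the
planted direction reliably. The pipeline therefore exposes
`filter$mode = "off"`, and the synthetic validation study runs unfiltered:
the simulator emits no out-of-band artifacts, and restriction to the band
of interest is achieved spectrally by the band integral, which is the
measure's native mechanism. For real recordings the filter remains the
default, and results should be read with the caveat above in mind.

## The synthetic dyad study

`simulate_dyad()` builds a full session: per trial, 60 s rest then a 20 s
task video interval, hand and foot conditions pseudo-randomized, ten
trials each. The Model's region channel carries an HRF-convolved task
boxcar (difference-of-gamma kernel, unit peak, 6 s peak latency); the
Imitator's carries the same *pre-HRF* drive delayed by `coupling_lag`
samples (default 2, ~200 ms; the foot condition adds one sample by
default, echoing the longer observed latency of foot responses) and scaled
by `coupling_gain`; both then receive an independent AR(1) hemodynamic
background, a sinusoidal ~0.1 Hz confounder with the *same phase* in every
channel of both participants (the designed spurious-coupling stressor),
and white measurement noise. SDC channels carry only confounder plus
noise. Baseline analysis windows are placed end-aligned inside each rest
interval, ending 1 s before the next video, so they are clear of the
previous response's undershoot.

Default amplitudes (task response 3, noise 0.5, background 0.02,
confounder 0.05, one channel per participant per region) put the study in
a *clean validation regime*, and this is deliberate. The decision
statistic has an intrinsic noise floor: on pure white-noise epochs of 204
samples the masked band value falls inside the $\pm\epsilon$ no-causality
window for ~90% of epochs with one channel per participant, but only
~40–55% with two or three — at this epoch length and $\epsilon$, the
no-coupling decision is only meaningful for low-dimensional blocks, and
nuisance components have to sit well below the noise floor of the
statistic for the calibration to work. Passing the study therefore
demonstrates that the machinery is correct and that the direction of a
genuine 2-sample-lagged coupling is recoverable under a shared-phase
confounder; it does *not* claim that real fNIRS data yields accuracies of
this magnitude — real recordings have far stronger in-band physiology,
and published accuracies in comparable real protocols are in the 60–70%
range for task intervals. Raising `background_sd`,
`confounder_amplitude`, or `n_channels_region` degrades accuracy smoothly
and can be used to explore harsher regimes.

At the default study scale (5 dyads × 10 trials × 2 conditions: 100 task
and 100 baseline epochs, each with a 10-surrogate ensemble, plus the
pairwise SDC calibration) the full run takes on the order of half a minute
on one core.

## Numerical choices and degenerate inputs

* Covariance log-determinants use Cholesky factorizations of the
  Hermitian blocks; innovation covariances are floored by a relative ridge
  `1e-8 · tr(Σ)/d` before any determinant, since short epochs can yield
  numerically singular residual covariances on which the measures diverge.
* Stability gate: a fitted epoch whose companion spectral radius is ≥ 1 is
  refitted with a small ridge (`1e-6`) and excluded if still unstable;
  excluded epochs are reported, and the SDC mean simply omits them.
* OLS rank checking uses a `1e-12` relative tolerance: heavily oversampled
  band-limited signals make lagged regressors near-collinear without being
  rank-deficient; exactly duplicated channels still error.
* MDL: $\log\det\hat\Sigma(p) + p\,d^2\log(n)/n$ with $n = L - p$; ties go
  to the smaller order.
* Phase randomization: even-length series keep the Nyquist-bin magnitude
  with phase 0; the DC bin is untouched, so means are preserved. The
  master seed spawns per-surrogate and per-channel substreams
  deterministically, and the entire simulate→analyze→report chain is
  byte-reproducible from one seed.
* Frequency grid: 513 uniform points on $[0, f_s/2]$ by default; the
  three-way identity, Hermitianity, and positive semidefiniteness of
  $S_X(\omega)$ are enforced or checked at every point.
* Zero-variance channels are rejected with the channel named; missing
  values are rejected outright — causal estimates are lag-sensitive and
  imputation would manufacture or destroy lead/lag structure.

## Known limitations

* Linear-Gaussian measures only: the decomposition captures linear
  dependence; nonlinear coupling is visible only through its linear
  signature.
* The literal decision rule can output Imitator→Model for positive but
  sub-baseline values; this is faithful to the calibration logic but worth
  remembering when reading per-epoch outputs.
* With multichannel regions at 204-sample epochs the no-coupling decision
  saturates its noise floor (see above); group-level averages of the
  directed spectra remain informative there, per-epoch "none" decisions do
  not.
* The simulator's confounder is a pure shared-phase tone and its noise is
  white; real systemic physiology is broadband and patient-specific, which
  is precisely why real-data accuracies are lower than this study's.
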