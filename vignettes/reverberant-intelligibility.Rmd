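---
title: "Models and methods: simulating speech intelligibility in reverberant noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What this package simulates

`revspeech` runs a complete speech-intelligibility-in-reverberation
experiment in silico. Two monaural mechanisms are at its core:

* **Temporal smearing of the target.** Reverberation flattens the envelope
  of speech; intelligibility drops as the reverberation time (RT) of the
  room grows.
* **Dip listening (masking release).** A temporally modulated masker lets
  listeners glimpse speech in its gaps; reverberation applied to the
  masker fills those gaps and removes the benefit. Hearing-impaired (HI)
  listeners typically start with a smaller benefit than normal-hearing
  (NH) listeners.

The pipeline separates these mechanisms by applying reverberation to the
speech only, the noise only, or both, crossed with stationary and
speech-modulated maskers, and analyses intelligibility on the full
psychometric function rather than at one SNR.

# Room acoustics

## Model

Rooms are rectangular with one absorption fraction per octave band
(125-4000 Hz) shared by all six surfaces. The early response is an exact
image-source sum: an image reached after $e$ wall reflections and travel
distance $d$ contributes $\beta^e/d$ at its fractional delay, with
$\beta = \sqrt{1-\alpha}$ per band, injected as a Hann-windowed sinc.
Beyond a mixing time (direct delay + 20 ms by default) the late field is a
seeded Gaussian tail whose per-band energy envelope follows the
image-model continuum
$$e_b(t) = \frac{4\pi c}{V}\exp\!\big(-c\,t\,[-\ln(1-\alpha_b)]/\bar\ell\big),$$
with $\bar\ell = 4V/S$ the mean free path — i.e. an Eyring decay with no
free parameter. Band responses are recombined through an
amplitude-complementary zero-phase octave filterbank, and everything below
20 Hz is removed: the all-positive reflection sum otherwise accumulates an
inaudible DC component (an artefact also present in commercial room
simulators) that corrupts energy and modulation measures.

**Why a hybrid and not a pure image model?** A purely specular shoebox
image model contains axial image chains along the long room dimension that
hit few walls per metre and decay far more slowly than a diffuse field.
They fatten the late tail, stretch the broadband decay, and bias the
direct-to-reverberant ratio (DRR) 2-3 dB low relative to scattering-based
ray tracing. Replacing the post-mixing-time field with Eyring-decay
diffuse statistics reproduces the reference DRR values of the five study
rooms to within a fraction of a decibel without any tuning constant. The
early reflections — which carry the perceptually relevant structure — stay
exact.

## Metrics and conventions

* **T30**: twice the time the backward-integrated (Schroeder) energy takes
  to fall from −5 dB to −35 dB. Broadband T30 on a multi-band decay is
  dominated by the slowest (lowest) band and therefore reads higher than
  the nominal per-room RT labels; per-band T30s are reported alongside,
  and the acceptance checks rely on DRR values and RT *ordering*, which
  are stable under this convention.
* **DRR**: energy in [direct arrival − 0.5 ms, + 2.5 ms] over the rest,
  in dB. The 2.5 ms window is a common convention and configurable, since
  the reference software's convention is unstated.
* **Air absorption** is off by default (small room, bands ≤ 4 kHz) and
  switchable; the reference DRRs are met without it.
* Default sample rate 16 kHz (bands stop at 4 kHz); configurable.
* RIRs are energy-normalized before convolution so reverberation never
  changes broadband level, making level calibration independent of RT.

```{r}
library(revspeech)
r <- normalize_energy(simulate_rir(virtual_room(0.8), seed = 1))
room_metrics(r)[c("rt_broadband", "drr")]
```

The absorption tables for the near-anechoic (nominal 0.15 s) and most
reverberant (1.5 s) rooms come from a typographically fragile source; both
decode exactly as the base mineral-wool row divided by 0.3 and 4.615
respectively, and are treated as such.

# Stimuli

* **Synthetic speech tokens.** The real matrix corpus is copyrighted, so
  sentences are emulated by consonant-vowel-like noise bursts: a syllabic
  3-5 Hz envelope over speech-shaped noise (flat to 500 Hz, −8 dB/octave
  above). They carry the spectro-temporal statistics the masker recipes
  need, nothing more; a green test says the *pipeline* behaves, not that
  the tokens are intelligible speech.
* **Modulated masker.** 288 source sentences are split into two
  144-sentence halves; each half is concatenated and passed through a
  3-channel noise vocoder (channel edges equally spaced on an ERB scale
  over 100 Hz - 8 kHz, envelope = magnitude of the analytic signal
  low-passed at 60 Hz, imposed on band-limited noise carriers), and the
  two one-voice streams are summed. Noise carriers are assumed (the
  reference leaves the carrier type unstated).
* **Stationary masker.** The concatenated sentences with their phase
  spectrum randomized: identical long-term spectrum, no modulation.
* **Spectral matching.** Third-octave levels are the testable surrogate
  for excitation-pattern matching: a linear-phase FIR brings a signal's
  long-term third-octave spectrum within ~1 dB/band of a reference over
  100-8000 Hz.
* **Modulation spectrum.** Envelope (analytic magnitude) divided by its
  mean, DC removed, power integrated in octave bands centred 1-16 Hz.
  Reverberation monotonically drains these bands for modulated signals.
* **Trial assembly.** The masker excerpt is one second longer than the
  (reverberated) target, starts 300-700 ms before it (uniform), is gated
  with 10 ms raised-cosine ramps, and is levelled to realize the requested
  SNR as a broadband RMS ratio over the target's extent *after*
  reverberation. Presentation level is digital: 0 dBFS RMS maps to 100 dB
  SPL, so the 50 dB SPL target is an RMS of 10^(−50/20) relative to full
  scale.

# The synthetic cohort

Audiograms are drawn to satisfy the inclusion criteria: NH thresholds at
most 20 dB HL (125-4000 Hz) and 25 dB HL (6-8 kHz) with a 4-frequency
average hearing loss (4FAHL; 0.5/1/2/4 kHz) near 12.6 ± 3.3 dB HL; HI
listeners have sloping mild-to-moderate losses with 4FAHL drawn from
N(45.2, 11.3²) truncated to [25, 70] dB HL. HI listeners receive NAL-RP
linear gains (three-frequency-average rule plus the profound-loss X-term;
the severe-loss spectral tilt table is omitted because the cohort never
reaches H2000 ≥ 95 dB HL), clipped non-negative and capped at 40 dB.

Each listener carries latent psychometric truth per condition. The word
score on a sentence is Binomial(5, ψ) — word-level independence is
assumed, matching the fitting model. The latent threshold is

* a per-group baseline (NH −7 dB, HI −4.5 dB; widths 8 and 10 dB) plus a
  per-listener offset (SD 1.5 dB),
* plus a smearing penalty `smear[group] * sqrt(rt_speech − 0.15)` when
  reverberation is on the speech,
* minus a dip-listening benefit `dip_benefit[group]` for modulated
  maskers, fading linearly to zero as the *masker* RT goes from 0.15 to
  1.5 s.

Each listener's smearing and dip-benefit coefficients are the group value
times a mean-preserving lognormal multiplier (SD 0.3 on the log scale):
listeners demonstrably differ in their susceptibility to reverberation and
in their use of masker gaps, and without this heterogeneity a simulated
cohort is unrealistically informative — even trivial group-trajectory
differences produce decisive interaction Bayes factors that no real
cohort of this size would yield.

**Calibration of the defaults.** The stated world is defined on the scale
the study measured: similar RAU-domain smearing penalties for the two
groups at the optimal SNR (the group-by-RT interaction is null there), an
NH dip benefit near 20 RAU and an HI benefit near 9 RAU at the
benefit-maximizing SNR. Because the groups sit at different operating
points of their psychometric functions, equal RAU effects require
group-specific dB-domain coefficients; `smear = c(NH 2.1, HI 3)` and
`dip_benefit = c(NH 1.5, HI 0.8)` were calibrated once against those
magnitudes and then frozen. The square-root growth of the penalty with RT
reproduces the roughly 1:2 ratio between the RT = 0.5 s and RT = 1.5 s
penalties. Per-condition jitter defaults to zero so that latent truth is
deterministic given the listener — the binomial sampling supplies all
trial noise.

What the generator does **not** emulate: signal-driven confusions (scores
come from latent truth, not from decoding audio), word-level dependence
within a sentence, training effects across sessions, loudness discomfort
(only a config-level gain cap), and per-listener SNR-grid adjustment
(a fixed −16..0 dB grid is used).

# Psychometric fitting and derived statistics

The fitted function is the logistic form
$$\psi(x) = \gamma + \frac{1-\gamma-\lambda}{1+e^{-2\ln(19)(x-m)/w}},$$
with guess rate γ fixed at 0.1 (closed set, 10 alternatives per slot),
lapse rate λ box-constrained to [0, 0.05], and (m, w, λ) estimated by
maximum binomial likelihood with a 7 × 2 multistart grid over (m, w)
(L-BFGS-B, likelihood tolerance 1e-8 on the scaled deviance). The source
material describes the sigmoid as a cumulative Gaussian but prints the
logistic equation; the printed equation is implemented as the reference
(`shape = "logistic"`), with a Gaussian-CDF variant behind a flag. The
`converged` flag is honest: a fit must beat the best constant-rate model
by 2 log-likelihood units, so floor-only or ceiling-only data are flagged
unreliable rather than silently returned.

* **RAU**: the continuous-proportion rationalized arcsine transform
  $R = (146/\pi)\,2\arcsin\sqrt{p} - 23$ is applied to fitted curves
  (endpoints −23 and 123, midpoint 50); the integer-count form is
  available for raw scores.
* **Group curves** average the four parameters across listeners, then
  convert the resulting curve to RAU (never averaging RAU values).
* **Optimal SNR**: the grid SNR maximizing the number of *fitted* listener
  scores strictly inside (15%, 95%), ties toward the lower SNR. Fitted
  rather than raw scores are counted (the source is ambiguous); a
  raw-score variant is a one-liner via `rau_score()`.
* **Dip benefit**: RAU(ψ_mod) − RAU(ψ_stat) at a stated SNR. The
  benefit-maximizing SNR is found per group as the grid argmax of the mean
  benefit — it is cohort-specific and never hard-coded.
* **SRT**: closed-form inversion of ψ at 50%, defined only when
  γ < 0.5 < 1 − λ.

# Bayes factors

Paired and two-sample t-tests use the JZS default prior: a Cauchy with
scale ½ on the standardized effect, computed by one-dimensional quadrature
(relative error below 1e-6) and verified in the tests against an
independent integral over the noncentral-t density.

The repeated-measures ANOVA comparisons are Rouder-style g-prior model
comparisons built directly rather than delegated: orthonormal sum-to-zero
contrast blocks for each term, a random subject-intercept block, Jeffreys
prior on σ², inverse-gamma(½, r²/2) priors on each block's g (Cauchy scale
r = ½ for fixed terms, 1 for the subject block). The marginal likelihood
given g has a closed form via the Woodbury identity; the g's are
integrated by Laplace approximation on log g, with optional
importance-sampling refinement that reports a relative Monte-Carlo error.
The null model for a target interaction contains all lower-order terms
and same-order interactions not containing it; the full model adds the
target. A BIC surrogate (maximum-likelihood `lme4` fits,
BF ≈ exp(ΔBIC/2)) is provided for bulk simulation and flagged as such in
the result. Exact numerical parity with any external Bayesian ANOVA
package is not claimed; calibration (null and effect detection rates) and
limit behaviour are what the tests pin down. Whether the original
analysis placed priors on random slopes is unknown; no random slopes are
modelled here, which is a documented limitation.

Evidence categories use the conventional cuts: BF > 10 strong, > 3
moderate, 1/3-3 inconclusive, < 1/3 moderate absence, < 1/10 strong
absence.

# Sequential design analysis

`sbf_maxn()` implements the SBF+maxN design: accrue listeners (one per
group per look) from a Gaussian cell-mean effect model, recompute the
interaction BF each look, stop at BF ≥ 3 or ≤ 1/3 or at the per-group
maximum. Sequential accrual (listeners are kept across looks) is assumed,
as is standard. The cell means and SDs that parameterized the original
power analysis come from an external publication and are not reproduced
here; `sbf_example_effect_model()` ships a documented example whose
qualitative outcome pattern (mostly confirming the null, a small
inconclusive mass, mean total N in the mid-thirties) matches the reported
analysis, but the printed probabilities are deliberately not automated
targets.

# Numerical choices and degenerate inputs

* All filtering is zero-phase FFT masking with raised-cosine transitions
  on zero-padded buffers (no IIR state, fully reproducible).
* Every stochastic routine takes a seed and restores the caller's RNG
  state; identical inputs and seeds give bit-identical outputs.
* Degenerate cases fail loudly: coincident source/receiver, silent RIRs
  or signals, absorption outside (0, 1], maskers shorter than target + 1 s,
  missing design cells (named in the error), zero-variance responses.
* A Schroeder curve that never reaches −35 dB — or that only crosses it in
  the final 10% of the impulse response, where backward integration of any
  truncated signal plunges artificially — yields an estimate flagged
  `insufficient_decay` instead of a silent extrapolation.
* FFT lengths are padded (or, for masker concatenations, trimmed by a few
  milliseconds) to 2-3-5-smooth values: R's mixed-radix FFT degrades to
  near-quadratic cost on lengths with large prime factors.

# Known limitations

* Monaural only; no binaural cues, by scope.
* The broadband T30 of a multi-band decay exceeds the nominal RT labels
  (band weighting); per-band values are the comparable quantities.
* Synthetic tokens are not speech; intelligibility prediction from the
  waveforms (STI-style) is out of scope.
* The Bayesian ANOVA prior structure approximates, not replicates, the
  original point-and-click software.
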