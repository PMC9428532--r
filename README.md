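# revspeech

Speech intelligibility in reverberant noise, simulated end to end.

Reverberation hurts speech understanding in noise through two monaural
mechanisms: it temporally smears the target speech, and it fills the gaps
of fluctuating maskers, removing the *dip listening* benefit. Studies that
compare normal-hearing (NH) and hearing-impaired (HI) listeners on these
mechanisms are expensive — dozens of listeners, seventy conditions, hours
of testing — and their statistics (psychometric-function fitting,
rationalized arcsine units, Bayesian ANOVAs, sequential sampling designs)
involve many moving parts. `revspeech` implements that entire machinery as
a tested R package so the full study can be run in silico on synthetic
data, stage by stage:

* **room** — shoebox-room impulse responses by a hybrid image-source /
  Eyring-diffuse-tail model with octave-band absorption; Schroeder decay,
  T30 and direct-to-reverberant ratio (DRR).
* **stimuli** — synthetic matrix-style speech tokens; a two-voice vocoded
  speech-modulated masker (3 channels, 60 Hz envelope cut-off); a
  phase-randomized spectrum-matched stationary masker; envelope modulation
  spectra (octave bands 1–16 Hz); reverberant mixing at exact SNR.
* **cohort** — NH/HI audiograms meeting the study's inclusion criteria,
  NAL-RP linear gains, latent psychometric truth per condition, binomial
  word scoring.
* **psychofit** — maximum-likelihood fits of
  ψ(x) = γ + (1−γ−λ)/(1+e^(−2·ln19·(x−m)/w)) with γ = 0.1 and
  λ ∈ [0, 0.05]; RAU conversion; optimal-SNR selection; dip-listening
  benefit; SRT.
* **bayes** — JZS t-test Bayes factors (quadrature) and Rouder-style
  g-prior mixed-ANOVA interaction BFs (Cauchy scale ½), with a BIC
  surrogate for bulk simulation.
* **design** — SBF+maxN sequential Bayes-factor design analysis.
* **experiment** — Table-style condition bookkeeping (14 combinations,
  70 condition×SNR cells, 140 min of testing), sentence-list construction
  (50 words used exactly once per 10-sentence list), and `run_replication()`
  which chains everything into one seeded, reproducible report.

## Worked example

```r
library(revspeech)

# the study's virtual room (5 x 9 x 2.7 m) at the nominal RT = 0.8 s setting
r <- normalize_energy(simulate_rir(virtual_room(0.8), seed = 1))
room_metrics(r)[c("rt_broadband", "drr")]
#> $rt_broadband
#> [1] 0.847
#> $drr
#> [1] -9.05
```

The DRR of −9.05 dB sits within 0.1 dB of the reference value for this
room (−8.97 dB). The broadband T30 reads above the nominal 0.8 s label
because the low-frequency band decays slowest and dominates the late
broadband decay — per-band T30s (`room_metrics(r)$rt_per_band`) are the
comparable quantities.

```r
rep1 <- run_replication(n_per_group = 16, seed = 1)
print(rep1)
#> synthetic replication: 16 listeners/group, 14 combos, 70 cells
#> optimal SNRs: speech -4, noise -4, both -4 dB; dip-max NH -8, HI -4 dB
#>   H1           BF10 = 9.063      (moderate_alt) at -4 dB
#>   H2           BF10 = 0.5272     (inconclusive) at -4 dB
#>   H2_dipmax    BF10 = 0.5272     (inconclusive) at -4 dB
#>   H3_1         BF10 = 0.2365     (moderate_null) at -4 dB
#>   H3_1_dipmax  BF10 = 0.2365     (moderate_null) at -4 dB
#>   H3_2_a       BF10 = 3.096      (moderate_alt) at -4 dB
#>   H3_2_b       BF10 = 8.259      (moderate_alt) at -4 dB
```

Reading the report: each hypothesis is an interaction Bayes factor
computed on RAU-converted fitted scores at the SNR named in the line
(H1: does reverberation on the *speech* affect the groups differently;
H2: does reverberation on the *noise* reduce dip listening differently;
H3-1: does reverberation on *both* affect the groups differently;
H3-2-a/b: is the dip-listening reduction present within each group).
BF10 > 3 is moderate evidence for the interaction, < 1/3 moderate
evidence against, 1/3–3 inconclusive. In this synthetic cohort the
combined effect of reverberation is the same for both groups (H3-1
moderate null), while the dip-listening structure is visible within
groups. The dip benefits themselves (`rep1$dip_benefit`) show the
signature pattern: at the benefit-maximizing SNR the NH group gains
17.7 RAU from masker gaps and the HI group 13.8 RAU at their respective
best SNRs, and both collapse to ≈ 0 (−2.5 / −0.5 RAU) when the masker is
smeared by the most reverberant room.

```r
plot_group_curves(rep1, "speech_only")   # RAU group curves vs SNR
```

## Command-line entry points

```sh
Rscript inst/cli/room.R simulate --rt-target 0.8 --out rir.wav
Rscript inst/cli/room.R metrics rir.wav
Rscript inst/cli/replicate.R run --seed 7 --out results/
```

See `vignettes/reverberant-intelligibility.Rmd` for the models, their
assumptions, the calibration of the synthetic cohort, and known
limitations.
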