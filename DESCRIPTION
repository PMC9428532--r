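Package: revspeech
Title: Speech Intelligibility in Reverberant Noise: Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("revspeech", "maintainers", email = "revspeech@example.org",
           role = c("aut", "cre"))
Description: An in-silico replication toolkit for speech-intelligibility-in-noise
    experiments under reverberation. Simulates shoebox-room impulse responses
    (hybrid image-source / diffuse-tail model) with octave-band absorption and
    computes reverberation time and direct-to-reverberant ratio; builds vocoded
    speech-modulated and phase-randomized stationary maskers with spectral
    matching and envelope modulation spectra; generates synthetic normal-hearing
    and hearing-impaired listener cohorts (audiograms, NAL-RP gains, latent
    psychometric parameters) and binomial word-scoring trial data; fits logistic
    psychometric functions by maximum likelihood with a bounded lapse rate and
    derives rationalized-arcsine-unit statistics (dip-listening benefit, optimal
    signal-to-noise ratio, speech reception threshold); computes default-prior
    Bayes factors (JZS paired t-tests, mixed-design repeated-measures ANOVA
    model comparisons) and runs sequential Bayes-factor design analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lme4,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
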