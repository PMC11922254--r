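Package: ncmephys
Title: Context-Dependent Auditory Response Analysis for Songbird Forebrain Recordings
Version: 0.1.0
Authors@R:
    person("ncmephys", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies context-dependent auditory responses in awake-behaving
    songbird extracellular recordings (caudomedial nidopallium, NCM).
    Provides per-trial spike-rate metrics (baseline-normalized Z-scores,
    response strength, d-prime stimulus selectivity, stimulus-specific
    adaptation ratios, offset responses), broad/narrow-spiking unit
    classification from mean waveforms, Welch power-spectral-density
    permutation statistics for local field potentials, Wilcoxon
    signed-rank context comparisons with Holm-Bonferroni correction, and a
    synthetic-session generator emulating playback experiments (bird's own
    song, reversed song, conspecific song, white noise) across solitary,
    social and directed contexts, so the full pipeline is testable without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
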