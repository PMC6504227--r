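Package: epiphys
Title: State-Dependent Interictal Spike and Hippocampal Theta Analysis for
    Rodent Gene-Restoration Studies
Version: 0.1.0
Authors@R:
    person("Avery", "Quinn", email = "avery.quinn@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative analysis of chronic video-EEG/LFP
    recordings and behavioral cohorts from rodent gene-restoration designs.
    Detects high-amplitude interictal spikes in a hippocampal depth channel
    with artifact rejection, segments wake and sleep from EMG quieting,
    computes state- and genotype-dependent event rates and fold changes,
    estimates time-resolved Morlet wavelet amplitude spectra with
    theta/delta ratio tracking and within-subject normalized amplitude
    change (bootstrap confidence intervals and sign-flip permutation
    inference), and runs the behavioral statistical battery (type-III
    two-factor ANOVA with Bonferroni pairwise comparisons, mixed
    repeated-measures ANOVA, MANOVA, t tests, Wilcoxon rank-sum, Cohen's d,
    activity suppression ratios). Includes a seeded synthetic-data
    generator emulating state-dependent Poisson spike trains, theta/delta
    oscillations on a 1/f background, and behavioral cohorts, so every
    stage is testable end to end without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
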