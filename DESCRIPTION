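Package: bitrack
Title: Simulation and Analysis of Bimanual Wrist-Tracking Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how two hands share a redundant continuous
    tracking task under visual (shared-cursor) and mechanical (virtual-spring
    or rigid-bar) coupling. Provides the multisine target model and coupling
    physics, a seeded synthetic cohort simulator with surface-EMG synthesis
    and isometric torque calibration, EMG envelope extraction and
    EMG-to-torque calibration, per-trial effort and performance metrics
    (normalized arc length, reciprocal activation, co-contraction,
    imbalances, RMS tracking error, Spearman hand correlation), and the
    matching inferential layer: aligned-rank-transform factorial ANOVA,
    random-intercept mixed-effects slope models with Satterthwaite degrees
    of freedom, Wilcoxon and Mann-Whitney pairwise families, and Hommel or
    Benjamini-Hochberg multiplicity control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    lmerTest,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
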