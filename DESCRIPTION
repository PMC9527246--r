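Package: schemasim
Title: Simulation and Analysis of Schema-Congruent Memory Consolidation fMRI Experiments
Version: 0.1.0
Authors@R:
    person("Schemasim", "Developers", email = "schemasim@example.org", role = c("aut", "cre"))
Description: Tools to design, simulate and analyse object-scene schema memory
    experiments with task and resting-state fMRI. Generates counterbalanced
    stimulus lists and encoding/retrieval schedules under scene-adjacency
    constraints; scores encoding judgments and cued-retrieval responses into
    coarse/detailed/forgotten memory outcomes with delay-local exclusions;
    simulates cohorts with known ground truth (trial outcome probabilities,
    multi-voxel trial patterns built from shared context/scene/item components,
    HRF-convolved BOLD runs, and pre/post rest series with behaviour-linked
    inter-region coupling); estimates single-trial activation patterns by
    least-squares-single (LSS) regression with motion and spike nuisance
    modelling; computes cross-run-restricted Fisher-z pattern similarities
    under context and scene-granularity pairing schemes; derives post-encoding
    connectivity change via aCompCor-style denoising and band-pass filtering;
    and fits linear mixed-effects models with estimated marginal means,
    pairwise contrasts, heteroskedasticity-aware refitting, and Morey
    within-subject error bars.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    nlme,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
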