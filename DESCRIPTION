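Package: reafference
Title: Corollary-Discharge Modulation of Lateral-Line Sensory Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how corollary discharge (efference copy)
    restructures self-generated sensory feedback in the fish lateral line.
    Implements a discrete-time two-state (sensitive/insensitive) stochastic
    sensor with stimulus gain, cholinergic inhibition of the spontaneous
    release term, and probabilistic regeneration; exact expected-count
    oracles and deterministic inhibition calibration against the observed
    spontaneous suppression ratio; circular spike-train statistics (phase
    quantiles, vector strength, gain, peristimulus time histograms,
    interspike intervals); labeling of evoked/spontaneous and swim-coupled
    spikes with evoked and spontaneous inhibition ratios, adaptation
    indices, k-means response-type clustering and an interaction
    regression; swim-normalized response time courses; and simulations of
    heterogeneous sensor populations with interspike-interval structure
    analysis. A synthetic-experiment generator emulates the recording
    protocol so the full analysis pipeline runs without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
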