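Package: strokecoh
Title: Resting-State EEG Coherence Networks for Stroke Motor-Recovery
    Prognosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Builds sensorimotor coherence networks from multichannel
    resting-state EEG and relates them to upper-limb motor recovery after
    a neural-guided stroke intervention.  Provides Welch magnitude-squared
    coherence over a 10-20 sensorimotor montage with lesion-side
    canonicalization and five-network summaries; Fugl-Meyer (FMA-UE)
    outcome management with LOCF imputation, Tukey-fence screening and
    MCID-based recovery labels; tie-corrected Friedman and
    signed-rank tests, exact permutation t-tests with Hedges' g and FDR,
    and permutation-null Spearman screening; and PLS1 regression with VIP
    biomarker selection and leave-one-out cross-validated prognosis.
    A synthetic-data module generates EEG with known pairwise coherence
    and cohorts with a known coherence-to-outcome model so the whole
    pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
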