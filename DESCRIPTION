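Package: hierphys
Title: Dominance-Hierarchy Scoring and Prefrontal Unit Analysis for Social Competition Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for social-competition experiments in group-housed
    mice combined with chronic extracellular recording in medial prefrontal
    cortex. Scores dominance hierarchies from tube-test round robins, warm-spot
    occupancy, and pairwise food-competition trials; classifies sorted units
    into narrow- and broad-spiking types from averaged-waveform features;
    categorizes units as competition-, rank-, both- or non-related from
    per-trial firing-rate contrasts; builds longitudinal delta z-score series
    across an intervention window; and quantifies neural-behavioral coupling
    with lagged cross-correlation and a circular-shift permutation null. A
    synthetic-data generator with known ground truth supports closed-loop
    testing of every stage.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    mclust,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
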