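Package: lamtacs
Title: Layer-Specific Analysis of Visual-Evoked Laminar LFPs During
    Transcranial Alternating-Current Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for laminar multichannel recordings of
    flash-evoked local field potentials acquired during low-frequency
    transcranial alternating-current stimulation (tACS). Covers
    stimulation-artifact removal by second-order blind identification
    with sinusoid subtraction, biophysical estimation of the stimulation
    voltage and electric-field depth profiles, current source density and
    layer assignment, phase-dependent circular statistics of evoked
    components with permutation nulls, cluster-based permutation
    comparison of conditions, multi-unit spike detection and firing-rate
    analysis, and a reduced single-compartment driving-force
    demonstrator. Includes a synthetic laminar-session generator with
    known ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    arrow,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
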