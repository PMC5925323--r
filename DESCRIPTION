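Package: boldcbf
Title: Dynamic BOLD-CBF Coupling Analysis for Dual-Echo pCASL
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for resting-state dynamic coupling between
    spontaneous BOLD and cerebral blood flow (CBF) fluctuations measured
    simultaneously with dual-echo pseudo-continuous arterial spin labeling
    (pCASL). Provides temporal filtering and demodulation to separate the
    BOLD-weighted and perfusion-weighted components of the interleaved
    control/label timeseries, voxelwise zero-lag and lag-optimized coupling
    estimation with sinc upsampling, Fisher-z group statistics with
    Benjamini-Hochberg false discovery rate control, baseline perfusion
    quantification with a single-compartment kinetic model, quality-control
    metrics (RSFA, DVARS, motion RMS exclusion), and a synthetic dual-echo
    pCASL generator with known ground-truth coupling, lag, and perfusion for
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
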