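Package: epspmap
Title: Quantification of Optogenetically Evoked EPSPs Across Cortical Layers and Cell Types
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for optogenetic circuit-mapping experiments in
    brain slices: stimulus-aligned trial averaging of whole-cell membrane
    potential recordings, EPSP feature extraction (baseline, peak amplitude,
    20-50% rise slope), cortical layer assignment from subpial depth,
    per-slice normalization of synaptic input strength to reference-layer
    excitatory neurons, exact rank-based group statistics, and summary-table
    and depth-profile reporting. Includes a generative simulator of complete
    cohorts (dual-exponential synaptic waveforms on Ornstein-Uhlenbeck
    membrane noise, slice-level opsin-expression scaling, pharmacology and
    stability conditions) so the full pipeline can be exercised and validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
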