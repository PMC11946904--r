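Package: gabaglioma
Title: GABAergic Neuron-to-Glioma Synapse Analytics for Diffuse Midline Glioma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analyses of GABAergic neuron-to-glioma signalling in
    H3K27M-altered diffuse midline glioma: bin-matched control-set module
    scoring of GABAergic synapse gene signatures in single-cell expression
    data, lineage/stemness scoring of malignant cells, reversal-potential
    regression and Nernst-equation inference of intracellular chloride from
    GABA current-voltage data, evoked postsynaptic current kinetics (10-90%
    rise time, monoexponential decay, synaptic latency), optical-fractionator
    stereology with the Gundersen coefficient of error, 3-D synaptic puncta
    colocalization, and pooled proliferation indices. Ships seeded synthetic
    generators for every input so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    minpack.lm,
    uwot,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
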