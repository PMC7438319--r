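Package: synapdens
Title: Synapse Density Estimation from Fluorescent Puncta and Volume Electron Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating excitatory synapse densities by combining
    two microscopy modalities. Detects, classifies and measures fluorescent
    postsynaptic puncta (PSD95/SAP102-style two-channel fields) in 2D
    spinning-disk images; counts and sizes synapses in 3D labeled volumes
    using an unbiased stereological counting frame with tissue-shrinkage
    correction and synaptic apposition surface (SAS) area measurement;
    calibrates a conversion factor that maps 2D puncta densities
    (puncta/100 square micrometers) to 3D synapse densities
    (synapses/cubic micrometer); and extrapolates minimum excitatory
    synapse densities across brain regions. Includes synthetic-data
    generators that emulate both microscopes with known ground truth, so
    every pipeline stage can be validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    randomForest,
    car
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
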