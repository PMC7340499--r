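Package: ca1quant
Title: Quantification of Hippocampal CA1 Microcircuitry Under Cellular Heterotopia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable quantification stack for studies of hippocampal CA1
    microcircuitry in models of cellular heterotopia. Provides morphometric
    classification of complex versus simple (calbindin-predictive) pyramidal
    cells from SWC reconstructions via branch-based length- and node-ratio
    indices (LRI/ORI), first-prominent-bifurcation distance and Sholl
    profiles; supervised k-means and PCA-based clustering of morphological
    and intrinsic-physiology feature tables; extraction of intrinsic
    electrophysiological properties from current-clamp sweeps with recording
    quality control; synaptic-puncta detection, proximity filtering and an
    innervation-bias statistic; gamma-band local-field-potential spectral
    analysis and FFT cross-correlation with millisecond lag estimation
    between deep and superficial channels; somatic census bookkeeping with
    two depth conventions; and seeded synthetic-data generators with known
    ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
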