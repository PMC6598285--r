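Package: plexquant
Title: Reporter-Ion Quantitation and Differential Expression for 4-Plex
    Isobaric Labelling Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spectrum-to-protein quantitation for iTRAQ 4-plex reporter-ion
    data: isotope cross-over correction via non-negative least squares,
    spectrum qualification, summed-intensity ratio normalization,
    zero-denominator sentinel handling, intensity-filtered pairwise median
    protein ratios and a PSM-count/significance quantitation gate.
    Downstream tools call differentially expressed proteins by fold-change
    thresholds, summarise them as Venn-region and COG-category counts,
    build z-scored condition profiles with hierarchical clustering,
    run hypergeometric pathway enrichment, and compute fermentation
    end-product stoichiometry (endogenous ethanol, ethanol:acetate molar
    ratios, weight percentages). A synthetic-data generator with planted
    ground truth makes the whole pipeline testable without raw mass
    spectrometry data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
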