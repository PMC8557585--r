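Package: vascuquant
Title: Quantification of Thyroid Nodule Vascularization from Monochrome SMI
    Sonograms and CD34 Immunohistochemistry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify thyroid-nodule vascularization from two
    complementary modalities and to compare them statistically.  From
    monochrome superb-microvascular-imaging (SMI) Doppler sonograms the
    package computes node-to-parenchyma vascularization quotients (mean
    gray value and flow-positive area fraction per region of interest);
    from brightfield CD34 immunohistochemistry micrographs it computes
    Fast-Red-positive area fractions via Beer-Lambert optical-density
    stain unmixing in calibrated sampling rectangles.  A statistics layer
    provides exact small-sample Wilcoxon rank-sum tests, exact and
    permutation Spearman correlations, and rank-based partial
    correlations.  Synthetic sonogram, histology and cohort generators
    with known ground truth make the whole pipeline testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
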