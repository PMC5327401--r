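Package: IrisPheno
Title: Quantitative Iris Pigmentation Phenotyping and Eye-Colour Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated quantitative phenotyping of human eye colour from
    digital eye photographs, together with the statistical-genetics battery
    used to exploit it. The imaging pipeline locates the iris annulus
    (Canny edges followed by a centre-constrained circular Hough transform),
    classifies every iris pixel in HSV space with a quadratic-kernel support
    vector machine into non-pigmented, pheomelanin-like and eumelanin-like
    areas, and reports the three areal proportions alongside legacy colour
    quantifiers (mean hue/saturation, melanin index and colour score,
    CIE-L*a*b* means, PIE score, T-index). Downstream tools quantify
    category separation via Hellinger distances, test per-SNP association
    by partial correlation, scan SNP pairs for epistasis with nested-model
    F-tests, and evaluate cross-validated genotype-based prediction of the
    quantitative phenotypes. Ground-truthed synthetic eye images and
    simulated genotype-phenotype cohorts make the full pipeline testable
    without access to restricted study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    EBImage,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    vcfR,
    optparse,
    yaml
biocViews: Visualization, Classification, SNP, GeneticVariability
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
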