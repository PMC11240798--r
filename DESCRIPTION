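Package: surrocor
Title: Skin-Surface Surrogate Analysis of Respiratory Motion from 4DCT Contours
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating skin-surface regions as surrogates of
    internal respiratory motion from ten-phase 4DCT skin contours. Radial
    beams cast from a least-squares central craniocaudal axis measure
    per-beam skin excursion across respiratory phases; per-beam Pearson
    correlation with the craniocaudal trajectory of an internal tracking
    structure yields skin-to-target correlation maps. Beams are aggregated
    into nine anatomical torso regions bounded by parasternal angular
    bands, the xipho-sternal line and the subcostal plane. Additional
    components quantify subcutaneous, visceral and total adipose tissue on
    a single axial CT slice at L4 by Hounsfield-unit thresholding, and run
    a cohort statistical battery (Friedman with Dunn-Bonferroni post hoc,
    Mann-Whitney U with effect size r, Spearman correlation matrices,
    independent-samples t-test with Cohen's d). A synthetic breathing-torso
    phantom with analytically known magnitude, correlation and adipose
    ground truth supports validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
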