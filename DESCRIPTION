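Package: casemap
Title: Single-Case Deviation Mapping and Multivariate Classification for
    Structural Neuroimaging Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Places single subjects within reference cohorts of structural
    brain images and scalar phenotypes. Implements voxel-wise and per-measure
    z-deviation mapping of rare cases against two reference groups, a
    resemblance rule classifying each case as similar to one group or the
    other, family-level probabilistic deviation maps, region-of-interest
    volumetrics with global gray-matter adjustment, and a multivariate
    pattern-classification stage (linear support vector machine under
    leave-one-out cross-validation with recursive feature elimination and
    fold-wise case probabilities). Includes a seeded synthetic-cohort
    generator emulating smoothed modulated gray-matter maps with planted
    regional effects, so the full pipeline can be exercised and validated
    without access to clinical scans.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    e1071,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
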