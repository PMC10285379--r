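Package: hblupr
Title: Single-Step Genomic Evaluation (HBLUP) with Blending, Tuning and
    GRM Scale-Factor Hyper-Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-step genetic evaluation (HBLUP/ssGBLUP):
    pedigree numerator relationship matrices via the tabular method,
    allele-frequency-scaled genomic relationship matrices G(alpha),
    blending and tuning adjustments, assembly of the combined H matrix,
    restricted maximum likelihood variance-component estimation with the
    direct Average Information algorithm, best linear unbiased prediction
    of genetic values, a forward-in-time population simulator with
    half-sib and full-sib mating designs, and cross-validated grid search
    over the (tune, theta, alpha) hyper-parameter space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
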