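Package: morphogrowth
Title: Deformation-Based Morphometry of Perisylvian Cortical Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the opercula converge over the insula to
    close the Sylvian fissure in the fetal brain. Provides a synthetic phantom
    generator with analytically known diffeomorphic growth deformations,
    affine and diffeomorphic (stationary-velocity log-demons) image
    registration, Jacobian-determinant growth maps normalized for global
    volume change, displacement magnitude and arrow maps, multiclass Dice
    validation of registrations, and a layered percentile fold-change
    contrast of regional gene expression between opercular and insular
    cortex. Both analysis arms are orchestrated by a reproducible,
    manifest-writing pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
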