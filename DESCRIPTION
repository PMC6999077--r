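Package: retoct
Title: Multicontrast Optical Coherence Tomography Analysis of the Mouse Retina
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of multicontrast (reflectivity,
    angiographic, and polarization-sensitive) optical coherence tomography
    volumes of the rodent retina. Provides a synthetic dual-polarization
    phantom generator with complete ground truth, axial motion correction
    and retinal flattening, layer segmentation with peripapillary annulus
    thickness morphometry and regression-pretest ANCOVA/ANOVA cohort
    statistics, complex-difference angiography with vessel density and
    Weber contrast quantification, phase retardation mapping with screening
    for ectopic depolarizing deposits, hyper-reflective focus detection,
    and brightfield histomorphometry of immunostained plaque load.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    jsonlite,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
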