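Package: flowradiomics
Title: Radiomics Characterization of Aortic 4D Flow MRI Velocity Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative flow-profile phenotyping for time-resolved
    three-directional (4D flow) phase-contrast MRI of the aorta. Cross-sections
    are placed along the vessel centerline and resampled at 1 mm by trilinear
    multiplanar reconstruction; five scalar flow parameter maps (throughflow,
    wall parallelity degree, flow angle, local normalized helicity and
    normal-component vorticity) are computed per plane and timeframe,
    normalized to fixed integer ranges and summarized by a 411-feature
    radiomics signature (first-order, GLCM, GLRLM, GLSZM, GLDM, NGTDM and 2D
    shape families). Features are screened by inter-scanner and inter-observer
    intraclass correlation and the reproducible set feeds a logistic-regression
    flow-profile classifier. An analytic flow phantom (parabolic, plug,
    helical, jet and vortex profiles with scanner- and observer-dependent
    perturbations) supports end-to-end validation without MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    RNifti,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
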