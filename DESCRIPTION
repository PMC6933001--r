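Package: praxismap
Title: Voxel-Based Lesion-Symptom Mapping from CT with Case-Control Lesion Delineation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for mapping the neural correlates of limb apraxia (and other
    continuous behavioural deficits) from clinical CT in stroke cohorts. Implements
    automated lesion delineation by voxelwise Crawford-Howell case-control t
    statistics against a control scan set, the CT preprocessing chain it requires
    (background cluster removal, 12-parameter affine registration, an invertible
    CSF/parenchyma contrast transform, brain and ventricle masking, isotropic
    reslicing, Gaussian smoothing), and mass-univariate voxel-based lesion-symptom
    mapping (VLSM) of continuous praxis scores with covariates, a minimum
    lesion-count voxel filter, Benjamini-Hochberg FDR control and cluster/peak
    reporting. A synthetic-cohort generator with exact ground truth makes every
    stage verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
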