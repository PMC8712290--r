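Package: svcaref
Title: Supervised Clustering Reference Region Extraction for Dynamic TSPO PET
Version: 0.1.0
Authors@R: person("svcaref", "maintainers", email = "svcaref@example.org",
    role = c("aut", "cre"))
Description: Implements the supervised clustering algorithm (SVCA) for
    extracting a pseudo-reference region from dynamic TSPO PET scans.
    Kinetic classes (low-binding grey matter, white matter, blood,
    high-binding grey matter) are built from frame-wise z-normalized
    time-activity curves of a training cohort, optionally stratified by
    TSPO binding genotype.  Each voxel of a new scan is then decomposed
    against the classes by non-negative least squares, and voxels whose
    low-binding grey matter weight fraction exceeds a threshold are
    averaged into a reference time-activity curve.  Includes quality
    control checks, a minimal Logan reference-region DVR, a ground-truthed
    compartment-model phantom simulator, NIfTI-1 input/output and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    digest,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
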