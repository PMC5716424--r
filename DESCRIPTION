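Package: ctstitch
Title: Stitching Double Partial CT Acquisitions by Line-Profile Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs a complete, non-deformed 3D planning CT of an
    oversized patient from two partial acquisitions, one covering the
    uncompressed left side and one the uncompressed right side. The lateral
    overlap between the two scans is estimated by root-mean-square matching
    of 1D intensity line profiles drawn through the spine, small
    anterior-posterior and superior-inferior shifts are resolved by an
    exhaustive neighbourhood search, and the volumes are fused by a
    subtraction-and-merge scheme that discards possibly deformed edge
    columns before merging. Includes a synthetic CT phantom generator with
    known ground-truth offsets for validation, readers and writers for
    NIfTI, MetaImage and DICOM series, and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    stats,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
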