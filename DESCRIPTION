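Package: radcad
Title: Headless Toolkit for Developing and Validating Radiology CAD Software
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale workbench for computer-assisted detection (CAD)
    software development and validation. Reads single-frame DICOM series into
    geometry-complete volumes, writes and reads ITK MetaImage (MHD + raw)
    volume pairs, and generates deterministic synthetic DICOM series with
    planted spherical lesions. Provides a deterministic multiplanar
    reconstruction (MPR) kernel for orthogonal and oblique sections with
    trilinear or nearest-neighbour sampling and window/level display mapping.
    Implements a versioned clinical-case database with voxel and 2D geometric
    labels, schema-validated attributes, append-only revisions, content
    fingerprinting with integrity warnings, and anonymised case
    export/import. A sequential job manager prepares sandboxed plug-in inputs
    (raw volume plus plain-text metadata, never DICOM), executes plug-ins,
    parses lesion-candidate results, and collects structured radiologist
    feedback (known TP / missed TP / FP / pending plus false-negative marks).
    A JSON-document store with domain-based access control and a thin
    command-line interface tie the pieces together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    digest,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
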