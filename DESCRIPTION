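Package: omeDeposit
Title: Assemble 5D Microscopy Hypercubes from Plane Directories and
    Deposit Them as Annotated OME-TIFF Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Transforms directory trees of 2D microscopy planes, named by a
    position/timepoint/channel/z-section convention, into five-dimensional
    (T, C, Z, Y, X) hypercube images; extracts experiment metadata
    (description, tags, key-value pairs, tables) from semi-structured text
    logs through a pluggable parser contract; and deposits images and
    annotations through a data-broker abstraction whose local sink writes
    OME-TIFF files with embedded OME-XML, HDF5 table attachments and a
    machine-readable annotation manifest. Includes a deterministic fixture
    generator so the whole pipeline is testable without external data, and
    a command-line entry point for scripted uploads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    tools,
    utils,
    stats,
    tiff,
    png,
    xml2,
    rhdf5,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
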