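Package: scopekit
Title: Simulation-First Control Core for Bespoke Microscope Acquisition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless re-implementation of the computational core of a
    bespoke-microscope acquisition platform, exercisable entirely in
    simulation. Devices expose control "handlers" aggregated in a depot;
    nested translation stages are coordinated into a single macro XYZ
    position; experiments (channels x Z-stack x time-lapse) compile to
    hardware-style action tables of digital levels and analogue values and
    replay on a virtual clock; images are cut from a stored multi-channel
    sample volume by stage position and blurred by defocus; mosaics are
    acquired in an expanding spiral and persisted with an XYZ sidecar;
    datasets are written in a '.dv' dialect of the MRC2014 format; and a
    blur/binarise/circular-Hough pipeline detects nucleus-like objects in
    mosaic tiles and marks their stage positions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
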