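Package: trpmicro
Title: Tryptophan Microenvironment Analysis from Multi-Dimensional
    Fluorescence and Continuum Electrostatics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the local microenvironments of
    tryptophan residues in multi-tryptophan proteins by combining
    steady-state emission spectroscopy, PARAFAC decomposition of total
    synchronous fluorescence (TSFS) cubes re-laid onto trilinear
    excitation-emission (t-EEM) grids, multi-channel time-correlated
    single photon counting (TCSPC) lifetime fitting with instrument
    response reconvolution, and per-residue structural and electrostatic
    descriptors (solvent accessibility, packing density, and the change
    of electrostatic potential along the indole long axis) read from
    OpenDX potential grids.  A synthetic-data module generates
    fluorophore banks, TSFS cubes, decay histograms, toy structures and
    screened-Coulomb potential grids with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
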