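Package: ndimg
Title: Emission-Anisotropy, FCS and Laurdan GP Analysis for Membrane
    Nanodomain Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative imaging of membrane-protein
    nanoclustering. Turns dual-channel polarized TIRF image stacks into
    G-factor-calibrated fluorescence emission anisotropy maps and ROI
    statistics, analyses photobleaching homoFRET curves and whole-cell
    spreading kinetics, fits triplet + two-component diffusion models to
    fluorescence correlation spectroscopy data, computes Laurdan
    generalized-polarization membrane-order maps, segments punctate
    adhesion structures and spatially correlates them with anisotropy.
    A synthetic-scene generator with full ground truth makes every
    analysis stage testable without raw microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
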