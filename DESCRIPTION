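Package: bundletrac
Title: Semi-Automatic Tracing of Actin Filament Bundles in Cryo-Electron Tomograms
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracing hundreds of roughly parallel filaments (an
    actin bundle, as found in hair-cell stereocilia) through noisy,
    anisotropic 3D cryo-electron tomography density maps. Implements
    bundle-axis detection by 2D cross-correlation of cross-sections,
    longitudinal averaging along the local bundle direction, seed-based
    filament tracing with one-peak and seven-peak Gaussian matched-filter
    kernels, a local quadratic polynomial kernel-regression denoiser with an
    anisotropic weight kernel, the cross-distance accuracy metric between
    filament models, and a synthetic bundle-phantom generator with known
    ground truth for end-to-end validation. Reads and writes MRC2014 density
    volumes and CSV / Chimera CMM marker models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    xml2,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
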