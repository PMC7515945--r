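Package: cliMargin
Title: Cerenkov Luminescence Imaging Analysis for Surgical Margin Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for ex-vivo Cerenkov luminescence imaging (CLI)
    of excised tumour specimens with beta-emitting radiotracers such as
    Ga-68-PSMA. Provides isotope and Cerenkov physics primitives (beta decay
    spectra, Frank-Tamm photon yield, radioactive decay, depth-dependent
    optical attenuation), a ground-truthed synthetic specimen-image generator
    with photon-counting camera noise, the deterministic image-processing
    chain (pixel binning, gamma-strike suppression, background subtraction,
    radiance calibration), ROI-based radiance quantification with decay and
    injected-activity correction, tumour-to-background ratios, a
    filtered/unfiltered hotspot-persistence classifier for positive surgical
    margins, and staff radiation-dosimetry bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
Collate:
    'cliMargin-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'utils-filters.R'
    'physics.R'
    'phantom.R'
    'imaging.R'
    'quantify.R'
    'margin.R'
    'benchmarks.R'
    'dosimetry.R'
    'io.R'
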