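Package: guvquant
Title: Quantitative Fluorescence Analysis of GUV Membrane-Protein Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for giant unilamellar vesicle (GUV) fluorescence
    experiments on membrane-binding proteins such as ezrin: intensity-profile
    extraction with explicit background-subtraction rules, conversion of
    fluorescence to protein surface density via a lipid-dye (HPC*) calibration,
    Langmuir (hyperbolic) binding-isotherm fits, membrane nanotube radius
    estimation from tension, force or fluorescence, curvature sorting-ratio
    statistics, GUV-GUV tethering energetics per molecular bond from the
    contact-angle force balance, FRAP photobleaching correction and
    mobile-fraction fitting, and contingency statistics on nanotube assembly
    classes. Includes a synthetic-data generator that renders confocal-like
    two-channel scenes and tabular datasets from known ground truth so every
    stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'assembly-stats.R'
    'binding.R'
    'frap.R'
    'guvquant-package.R'
    'image-quant.R'
    'synthetic.R'
    'io.R'
    'sorting.R'
    'surface-density.R'
    'tethering.R'
    'utils.R'
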