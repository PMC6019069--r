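Package: depthgauge
Title: Circuit, Imaging and Behavioral Analysis of a Ratio-Chromatic
    Depth Gauge in Marine Larvae
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for studying how ciliary (UV-sensitive)
    and rhabdomeric (phototactic) photoreceptor circuits interact to set
    the vertical swimming direction of marine zooplankton larvae.
    Provides connectome utilities (loading synapse-count matrices,
    grouping by cell class, enumerating short directed synaptic bridge
    paths between circuits, ciliary membrane morphometrics), radiometric
    and stimulus-design helpers (photon flux, stimulation geometry,
    duty-cycle wavelength mixtures, absorbance-spectrum peaks),
    calcium-imaging trace analysis (delta-F/F0 with fixed or
    time-dependent baselines, pixelwise Pearson correlation maps,
    biphasic response classification), vertical-column behavior analysis
    (particle tracking, binned vertical displacement, action spectra,
    balance-point estimation, corrected multiple comparisons), and
    seeded synthetic-data generators with exposed ground truth for every
    input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tiff,
    EBImage,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'behavior.R'
    'calcium.R'
    'connectome.R'
    'depthgauge-package.R'
    'stimulus.R'
    'synthetic.R'
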