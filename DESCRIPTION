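Package: atpsDroplets
Title: Dehydration-Driven PEG/Dextran Droplet Formation in Microchannels
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Phase-field simulation and droplet morphometrics for
    dehydration-driven water-in-water droplet formation in aqueous
    two-phase (PEG/dextran) microfluidics. Implements a modified
    Cahn-Hilliard model on a quasi-1D channel grid with a time-ramped
    polymer interaction parameter and wall-affinity boundary relaxation,
    an empirical PEG/dextran binodal with dehydration dilution lines, a
    diffusion-limited dehydration timing model calibrated on channel-size
    series, and a segmentation/statistics pipeline (equivalent diameters,
    coefficient of variation, linear density, throughput, encapsulation
    efficiency) applied to simulated order-parameter fields and
    ground-truthed synthetic fluorescence-like channel images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, grDevices, graphics, Rcpp, EBImage,
    jsonlite, yaml, tiff
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
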