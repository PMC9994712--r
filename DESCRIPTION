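Package: phascreen
Title: High-Throughput Screening of Bacterial Polyhydroxyalkanoate Production
Version: 0.1.0
Authors@R:
    person("phascreen", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for microplate-based screening of bacterial
    polyhydroxyalkanoate (PHA) production. Covers Biolog PM1 phenotype
    microarray thresholding with no-carbon background subtraction, 96-well
    growth-curve metrics (maximum specific growth rate, time of maximum
    growth, area under the curve, model error) with box-plot outlier
    flagging, whole-cell FTIR spectral processing (amide I normalization,
    linear baseline correction, individual-baseline band integration, the
    carbonyl-to-amide-I CA1 ratio, carbonyl peak localization and scl/mcl
    PHA classification), acetyl-CoA-equivalent carbon-to-nitrogen medium
    design, and GC-FID external-standard PHA quantification. Ships a
    deterministic synthetic-data generator (Gaussian-band spectra, logistic
    growth, formazan kinetics) so every stage is testable without
    instrument files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    mgcv,
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
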