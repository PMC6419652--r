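Package: orgpet
Title: Amplitude-Based Optimal Respiratory Gating Simulation and PET Radiomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates respiratory-motion-degraded PET acquisitions of hot
    lesions on a digital phantom, implements amplitude-based optimal
    respiratory gating (the narrowest amplitude window containing a
    prescribed duty cycle of acquired data), delineates metabolic tumor
    volumes by SUVmax isocontouring, computes first-order and
    GLCM/GLRLM/GLSZM texture features from discretized volumes of interest,
    and provides the paired-comparison and survival layer (Wilcoxon
    signed-rank, standard-scaled univariate Cox models, Kaplan-Meier with
    maximally selected log-rank cutoffs) used to relate image features to
    overall survival.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
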