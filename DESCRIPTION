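Package: ecglead
Title: Single-Lead to Twelve-Lead ECG Reconstruction and Classification Feasibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the standard 12-lead electrocardiogram
    from a single lead I recording and for testing whether the reconstructed
    leads carry diagnostic information. Implements a one-dimensional
    conditional generative adversarial network (U-Net generator with skip
    connections, convolutional discriminator, adversarial plus L1 objective)
    that maps 2.5 s lead I segments to each remaining lead, Einthoven-triangle
    derivation of the limb leads from any two measured or generated limb
    leads, a 1D residual-network six-class classifier (normal, atrial
    fibrillation, complete left/right bundle branch block, left/right
    ventricular hypertrophy) used as a feasibility probe, and an evaluation
    protocol comparing real and reconstructed lead sets by precision, recall,
    F1, confusion matrices, mean squared error and discrete Frechet distance.
    Includes a class-conditioned synthetic 12-lead ECG simulator (dipole
    projection with Gaussian wave morphology) for fully reproducible
    desk-scale experiments, plus readers and writers for WFDB (PTB-XL layout)
    and a plain CSV fixture format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
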