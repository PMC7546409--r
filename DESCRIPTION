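Package: vtasteer
Title: Volume of Tissue Activated Modelling for Directional Deep Brain
    Stimulation in the Globus Pallidus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the volume of tissue activated (VTA) around a
    directional eight-contact deep brain stimulation lead implanted in the
    globus pallidus. Provides a synthetic voxel phantom of the pallidum
    (GPi, GPe, medial medullary lamina, internal capsule, optic tract and
    surrounding tissues), a parametric segmented-lead model, a
    heterogeneous quasi-static volume-conductor solver with
    electrode-tissue-interface impedance and current scaling, a
    double-cable myelinated axon model driven by interpolated
    extracellular potentials, direct bounding of action-potential
    initiation sites into a VTA with a four-way pallidal partition, and an
    orchestrated sweep over monopolar and bipolar contact configurations,
    vertical contact spacings and stimulus amplitudes.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
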