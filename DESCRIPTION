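Package: sercatraj
Title: Trajectory Analysis of Lipid Binding-Site Dynamics in the Calcium Pump SERCA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing molecular-dynamics trajectories of membrane
    transport proteins, built around the comparison of lipid-bound and
    lipid-free simulations of the SERCA calcium pump in its protonated E2
    state. Provides a light structure/trajectory data model with an atom
    selection mini-language; per-frame distance series with threshold and
    hydrogen-bond occupancies and density histograms; Kabsch superposition,
    per-segment RMSD profiles and leader/medoid conformational clustering;
    Cartesian principal component analysis with one-Gaussian essential-space
    classification and inner-product collinearity between trajectories;
    breadth-first detection of hydrogen-bonded water wires with event and
    lifetime statistics; and seeded synthetic-trajectory generators with
    planted ground truth so every stage is verifiable by parameter recovery
    without running molecular dynamics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
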