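Package: channelgauge
Title: Structural Analysis of Ion-Channel Simulation Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Geometric and conformational analysis of ion-channel
    molecular-dynamics ensembles, aimed at tetrameric potassium channels
    such as hERG/Kv11.1.  Provides largest-inscribed-sphere pore-radius
    profiles along the channel axis, Kabsch superposition with per-domain
    RMSD and monomer-averaged RMSF, average-linkage conformational
    clustering with Davies-Bouldin and explained-variance model selection,
    hydrogen-bond based helix assignment and helix propensity, center-of-mass
    domain hinge angles, Shrake-Rupley solvent accessibility of linear
    trafficking motifs, accelerated-MD dual-boost parameterisation with
    exponential reweighting, and synthetic channel-like trajectory
    generators that emit ground-truth manifests for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
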