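Package: poregate
Title: Ion-Channel Permeation, Conducting-Regime and Conformational
    Landscape Analysis at Desk Scale
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for voltage-driven ion permeation through a
    membrane channel pore, built around a Brownian-dynamics synthetic data
    generator. Detects complete pore-crossing events with a hysteresis state
    machine, accumulates the signed transported charge q_tot(t), estimates
    current and conductance by linear regression with diffusion-coefficient
    renormalization, classifies conducting regimes (stable low, open-like,
    bistable) via single- and two-segment change-point regression, screens
    conformers by a conductance threshold, and provides conformational
    analytics (Kabsch superposition and RMSD, beta-barrel ellipticity,
    charged-residue z statistics, PCA landscapes with cross-condition
    overlap, RMSD-based agglomerative clustering with medoid
    representatives, sequence apparent charge). Also implements the
    dual-boost accelerated-MD bias potential and a multi-walker
    cluster-restart exploration scheduler exercised on analytic toy
    landscapes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
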