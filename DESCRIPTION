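Package: cgphase
Title: Residue-Level Coarse-Grained Modelling of Biomolecular Phase Separation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A one-bead-per-residue coarse-grained model for proteins
    (disordered and folded) and RNA, aimed at liquid-liquid phase
    separation and solubility. Provides topology construction with
    elastic-network restraints for folded domains and surface-exposure
    scaling of interaction strengths, the full potential-energy function
    (harmonic bonds and angles, 10-5 short-range pair potential,
    screened Debye-Hueckel electrostatics), a deterministic BAOAB
    Langevin integrator, mixed-phase saturation-concentration (csat)
    estimation from multi-chain trajectories, and an energy-rescoring
    parameter-optimization protocol with RANSAC linear fits linking
    condensate potential energy to log10 csat. Ships the COCOMO and
    COCOMO2 parameter presets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
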