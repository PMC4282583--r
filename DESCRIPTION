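Package: puckerdyn
Title: Pseudorotation, NMR Relaxation and Torsion-Parameter Calibration for
    Five-Membered Ring Sidechain Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis and calibration toolkit for the structure and dynamics of
    proline and hydroxyproline five-membered rings. Provides Westhof-Sundaralingam
    pseudorotation analysis (phase P and amplitude chi_m) with endo/exo
    classification, generalized Karplus (Haasnoot 8C/8D) three-bond proton
    coupling prediction with trajectory averaging and two-state least-squares
    fitting, the two-site-jump dipolar 13C T1 relaxation model with forward and
    inverse solvers for overall and internal correlation times, P2 bond-vector
    autocorrelation and Lipari-Szabo model-free fitting, torsion-energy terms and
    QM-profile merit fitting by simulated annealing, Nelder-Mead fitting with a
    restart-factor initial-vertex scheme, single-trajectory reweighting, and the
    ln-linear timescale-matching calibration of torsion force constants. A seeded
    synthetic two-state ring-dynamics simulator stands in for molecular dynamics
    and experiment in tests and worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    minpack.lm,
    lhs,
    jsonlite
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
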