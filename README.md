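# puckerdyn

Structure **and** timescale analysis for proline / hydroxyproline ring
dynamics, and the calibration machinery that tunes a torsion force constant
until simulated dynamics match NMR-measured timescales.

The pyrrolidine ring of a proline residue exchanges continuously between two
pucker states, C&gamma;-endo and C&gamma;-exo. Motionally averaged NMR
observables (³J couplings, NOE distances) constrain the *populations* of the
two states but say nothing about how *fast* they exchange; ¹³C spin-lattice
relaxation times do. `puckerdyn` is for spectroscopists and force-field
developers who want to run that full chain:

* **Pseudorotation geometry** — endocyclic torsions &chi;1–&chi;5,
  Westhof–Sundaralingam phase/amplitude
  (tan P = [(&chi;4+&chi;1)−(&chi;3+&chi;5)] / [2&chi;2(sin36°+sin72°)],
  &chi;m = &chi;2/cos P, +180° when &chi;2 < 0), endo/exo classification,
  rigid-fragment superposition and C–H jump angles.
* **Couplings** — Haasnoot 8C/8D generalized Karplus prediction of the ten
  ring ³J(HH) values, trajectory averaging, the rms<sub>Jp</sub> merit, a
  bounded multistart two-state fit returning (P<sub>exo</sub>,
  P<sub>endo</sub>, &chi;m, x<sub>endo</sub>), and r⁻⁶ NOE distances.
* **Relaxation** — the two-site-jump dipolar T1 model
  R1 = N·K·[S²·g(&tau;c) + (1−S²)·g(&tau;′)], 1/&tau;′ = 1/&tau;c + 1/&tau;e,
  S² = 1 − 3x(1−x)sin²&Delta;&theta;, with forward evaluation, fast-branch
  inversion of T1 for &tau;c and &tau;e, a CSA diagnostic and Arrhenius fits.
* **Trajectory analysis** — FFT-based P2 autocorrelation with jackknife
  errors, Lipari–Szabo fits C(t) = S² + (1−S²)e^(−t/&tau;e), hysteresis
  transition counting, state populations, overall-motion removal.
* **Calibration** — torsion terms (cosine / Ryckaert–Bellemans), a
  Boltzmann-weighted merit &Phi; against QM torsion scans with simulated
  annealing, Nelder–Mead with the restart-factor initial-vertex scheme,
  (V, &gamma;) grid scans, single-trajectory reweighting with ESS
  diagnostics, and the ln-linear timescale matching V3 = a·ln &tau;e + b.
* **Synthetic dynamics** — a seeded two-state Markov-jump simulator (with
  libration and isotropic tumbling) that provides ground truth for every
  estimator; presets mirror the studied peptide systems.

See `vignettes/ring-dynamics-methods.Rmd` for the model details, conventions
and design decisions.

## Worked example

The GPGG timescale chain — backbone T1 to &tau;c, populations and jump angle
to S², ring-carbon T1 to &tau;e, calibration line to the matched force
constant:

```r
library(puckerdyn)

ctx_ch  <- spectrometer_context(n_h = 1, dsigma_ppm = -43)  # backbone CH
ctx_ch2 <- spectrometer_context(n_h = 2, dsigma_ppm = -30)  # ring CH2

tau_c <- invert_t1_tauc(ctx_ch, 995)                 # T1 = 995 ms
s2    <- order_parameter(0.543, 82.56)               # x_endo, jump angle
tau_e <- invert_t1_taue(ctx_ch2, 898, tau_c, 0.543, 82.56)
v3    <- predict(calibration_line(1.9272, -2.1881), 29.7)
cat(round(tau_c, 1), round(s2, 3), round(tau_e, 1), round(v3, 4), "\n")
#> 48.3 0.268 29.6 4.3473
```

`tau_c` (48.3 ps) is the overall tumbling time of the tetrapeptide, `s2` the
jump-model order parameter of the ring C&gamma;–H bonds, `tau_e` (29.6 ps)
the ring-interconversion correlation time, and `v3` (4.35 kJ/mol) the
&chi;2 torsion force constant whose simulated timescale matches that
experiment. The same chain is packaged as a recipe:

```r
run_recipe("gpgg-timescale")   # JSON-serialisable report of every stage
```

Pucker analysis of a conformer:

```r
chi <- ideal_ring_torsions(185, 40.3)   # or endocyclic_torsions(read_ring_atoms("x.pdb", 2))
pseudorotation(chi)
#> Pucker: P = 185.000 deg, chi_m = 40.300 deg (endo)
```

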