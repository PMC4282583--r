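---
title: "Methods: pseudorotation, ring-jump relaxation and timescale-matched torsion calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pseudorotation, ring-jump relaxation and timescale-matched torsion calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puckerdyn)
```

# The scientific problem

The pyrrolidine ring of proline (and 4-hydroxyproline) interconverts
continuously between two pucker states, C&gamma;-endo and C&gamma;-exo.
Classical force fields reproduce the motionally *averaged* NMR observables of
this ring reasonably well while getting the *timescale* of the interconversion
badly wrong, because nothing in a conventional parameterisation constrains how
fast conformers exchange.  `puckerdyn` implements the full analysis chain that
makes the timescale measurable and tunable:

1. **Ring geometry.**  Endocyclic torsions &chi;1–&chi;5 and the
   Westhof–Sundaralingam pseudorotation coordinates (phase *P*, amplitude
   &chi;m), with endo/exo classification.
2. **Couplings.**  Generalized Karplus (Haasnoot 8C/8D) prediction of the ten
   ring ³J(HH) couplings, trajectory averaging, the rms~Jp~ figure of merit
   and a two-state least-squares fit of experimental couplings that yields the
   endo population x~endo~.
3. **Relaxation.**  A two-site-jump dipolar ¹³C T1 model that inverts measured
   T1 values into the overall tumbling time &tau;c (from backbone CH carbons)
   and the internal interconversion time &tau;e (from the ring CH2 carbon),
   plus the jump-model order parameter
   S² = 1 − 3·x·(1−x)·sin²&Delta;&theta;.
4. **Trajectory analysis.**  P2 bond-vector autocorrelation functions,
   Lipari–Szabo model-free fits, torsional transition counting with
   hysteresis, and state populations.
5. **Calibration.**  Torsion-energy terms, a Boltzmann-weighted merit &Phi;
   against QM torsion scans (simulated annealing), Nelder–Mead fitting with a
   restart-factor initial-vertex scheme, (V, &gamma;) grid scans,
   single-trajectory reweighting, and the ln-linear timescale-matching
   calibration V = a·ln &tau;e + b that selects the torsion barrier whose
   simulated timescale matches experiment.
6. **Synthetic dynamics.**  A seeded two-state Markov-jump simulator with
   libration and isotropic tumbling that stands in for explicit-solvent MD in
   every test.

# Pseudorotation conventions

Torsions are IUPAC-signed, in degrees, wrapped to (−180, 180], with &chi;2
spanning C&alpha;–C&beta;–C&gamma;–C&delta;.  The cosine model is
&chi;~j~ = &chi;m·cos(P + 144°·(j − 2)), so &chi;2 is the zero-phase torsion.
The phase is computed as

tan *P* = [(&chi;4 + &chi;1) − (&chi;3 + &chi;5)] / [2·&chi;2·(sin 36° + sin 72°)],

adding 180° when &chi;2 < 0.  Internally both the phase and the amplitude are
evaluated through `atan2` on the pair (&chi;m cos *P*, &chi;m sin *P*), which
realises the same branch rule while remaining defined at &chi;2 = 0 and
numerically exact for model torsions (the round trip
`pseudorotation(ideal_ring_torsions(P, chi_m))` holds to 1e−9 across the
cycle).  The amplitude equals the maximum torsion the cosine model attains.
Classification is half-open: *P* &isin; [90°, 270°) is endo (typical
P~endo~ &asymp; 178–185°), the rest exo (P~exo~ &asymp; 11–14°); only
degenerate inputs land exactly on the boundary.

`ideal_ring_coords()` builds Cartesian five-membered rings whose torsions
follow the cosine model with 1.53 Å bonds, closing the ring by penalised
quasi-Newton refinement.  It is a geometric fixture for round-trip and
proton-placement tests, not a molecular-mechanics minimiser; residual torsion
error is below 0.1°.

# Karplus couplings

The Haasnoot generalisation of the Karplus curve,

J = P1·cos²&phi; + P2·cos&phi; + P3 + &Sigma;~i~ &lambda;~i~·[P4 + P5·cos²(&xi;~i~&phi; + P6·|&lambda;~i~|)],

is evaluated with the published fragment-class coefficient sets: 8C for
–CH2X–CH2Y– fragments (the &beta;&gamma; and &gamma;&delta; couplings) and 8D
for –CHXY–CH2Z– fragments (the &alpha;&beta; couplings).  Group
electronegativities use the Huggins scale with the &beta;-substituent
correction &lambda; = &lambda;~&alpha;~ − P7·&Sigma;&lambda;~&beta;~.  The
proton–proton dihedrals are obtained from the parent endocyclic torsion by
fixed tetrahedral offsets (0/±120°); the default offset table was fixed once
against an explicit three-dimensional proton construction and agrees with it
to within a few degrees around the pucker cycle.  Offsets, substituent tables
and orientation signs are all configurable, since different labs wire this
fragment bookkeeping slightly differently.

The two-state fit `two_state_jfit()` minimises rms~Jp~ =
&radic;(mean (J~calc~ − J~exp~)²) over (P~exo~, P~endo~, &chi;m, x~endo~) with
one shared amplitude, bounded L-BFGS-B from 32 Latin-hypercube starts
(P~exo~ &isin; [−40°, 70°], P~endo~ &isin; [120°, 260°], &chi;m &isin;
[25°, 55°], x~endo~ &isin; [0, 1]).  When the optimum collapses to a single
state, the empty state's phase is undetermined and the fit is flagged.
NOE-style distances use strict r⁻⁶ averaging against a 2.4 Å
H&alpha;–H&beta;3 reference, appropriate for small fast-tumbling peptides.

# The relaxation model

For a protonated carbon relaxed by the C–H dipolar interaction,

R1 = N·K·[S²·g(&tau;c) + (1 − S²)·g(&tau;&prime;)],&emsp;
K = (&mu;0/4&pi;)²·&hbar;²&gamma;H²&gamma;C²/(10·r~CH~⁶),

g(&tau;) = j(&omega;H−&omega;C) + 3·j(&omega;C) + 6·j(&omega;H+&omega;C),&emsp;
j(&omega;,&tau;) = &tau;/(1+&omega;²&tau;²),&emsp;
1/&tau;&prime; = 1/&tau;c + 1/&tau;e,

with CODATA constants, r~CH~ = 1.09 Å and Larmor frequencies taken directly
from the instrument (600.13/150.90 MHz at 14.1 T).  This Ernst-style
two-site-jump form was pinned numerically: one set of constants must satisfy
all five published T1 &harr; &tau; pairings simultaneously (995 ms &harr;
48.2 ps; 310 ms &harr; 246 ps; 614 ms &harr; 82.8 ps; 898 ms &rarr; 29.7 ps;
386 ms &rarr; 32 ps), which it does to better than 2%.  A wrong
spectral-density convention (a missing factor, the wrong linear combination)
breaks at least one pairing by far more.

Inversions are bracketed root solves to 1e−4 ps.  &tau;c inversion uses the
fast-motion branch only (&tau; below the T1 minimum): every peptide in this
regime satisfies &omega;H&tau; < 1, and the slow branch is rejected
explicitly.  The &tau;e inversion is monotone between the motionally averaged
(&tau;e &rarr; 0) and rigid (&tau;e &rarr; &infin;) limits, so the root is
unique; unattainable targets raise an error reporting the attainable R1
range.  The axially symmetric CSA rate (2/15)(&omega;C&Delta;&sigma;)²j(&omega;C,&tau;)
is reported as a diagnostic only — at −43 ppm and 48 ps it is about 1% of the
dipolar rate, so folding it into the inversions would shift &tau; by less
than the measurement uncertainty.  Populations are treated as temperature
independent when combining coupling-derived x~endo~ with variable-temperature
T1 series; `arrhenius_fit()` then extracts E~a~ and &tau;⁰ from ln &tau;
versus 1/T.

# Trajectory analysis choices

The P2 autocorrelation C(t) = &lang;P2(û(s)·û(s+t))&rang; uses all
overlapping time origins, evaluated through the tensor identity
(u·u&prime;)² = &Sigma;(u~a~u~b~)(u&prime;~a~u&prime;~b~) and FFTs, so a
10⁶-frame series costs seconds.  Uncertainties come from a delete-one-block
jackknife over 10 contiguous segments.  The Lipari–Szabo fit
C(t) = S² + (1−S²)e^(−t/&tau;e) is a Levenberg–Marquardt fit on a
configurable window (default 20 ns) with S² clipped to [0, 1]; flat curves
return S² = 1 with &tau;e flagged unidentifiable.

A torsional "transition" is deliberately an estimator with a declared rule:
frames are assigned to states by the sign of &chi;2 with hysteresis cores
|&chi;2| &ge; 10°, and no transition is registered until the opposite core is
entered.  This makes the count invariant to libration of amplitude smaller
than the band.  Counting uses a 1 ps stride by default; both the core width
and stride are configurable because published counts are estimator-dependent.
Population estimates use the same assignment with band frames inheriting the
last state.

Overall motion is removed by superposing each frame on a reference frame
(the midpoint of the run by default) over the four bonded backbone atoms of
the rigid C–N–C&alpha;–C fragment, using a closed-form proper-rotation
(Kabsch) superposition.  The same superposition defines the jump angle
&Delta;&theta;: conformers are overlaid on that fragment and the angle
between their C&gamma;–H directions is read off.

# The synthetic generator

`simulate_states()` realises a two-state Markov jump process with
*exact* stationary distribution and exchange time: sojourns are geometric
with leaving probabilities p(e&rarr;o) = x~exo~(1−e^(−dt/&tau;~ex~)) and
p(o&rarr;e) = x~endo~(1−e^(−dt/&tau;~ex~)), so the relaxation time of the
state autocorrelation is &tau;~ex~ at any step size, and the internal
correlation time reported to users equals &tau;~ex~ (the two-site-jump
identity).  Torsions are the ideal pucker torsions of the current state plus
Gaussian libration (default 5°).  Bond vectors jump by exactly
&Delta;&theta; between two body-fixed orientations; overall tumbling is
small-step isotropic rotational diffusion with per-step angle
&radic;(dt/&tau;c) about uniform random axes, which gives
&lang;P2&rang;-decay e^(−t/&tau;c) (verified against the free-diffusion
limit).  Step-size guards (dt &le; &tau;~ex~/10, dt &le; &tau;c/50) keep the
discretisation honest.  When tumbling is on, a rigid reference vector
subject to the same rotations is emitted as the backbone analogue, because
the experimental chain also determines &tau;c from a backbone carbon and
only then solves for &tau;e.

What the simulator emulates: two-state exchange kinetics, libration,
jump-geometry and tumbling, with known ground truth for every estimator in
the package.  What it does not emulate: explicit solvent, force-field
energetics, backbone conformational exchange, anisotropic tumbling, or
correlated libration between torsions.  Passing tests therefore demonstrate
estimator correctness and internal consistency of the analysis chain — not
that any particular force field reproduces real proline dynamics.  The
published MD-table quantities (rms~Jp~ columns, transition counts,
populations from hundreds of nanoseconds of explicit-solvent MD) are
represented only by these simulator analogues.

# Calibration choices

The cosine torsion term uses the AMBER normalisation
E = &Sigma;(V~n~/2)(1 + cos(n&theta; − &gamma;~n~)), fixed by the requirement
that a pure V3 term with &gamma;3 = 0 has a barrier of exactly V3 at
&chi;2 = 0 (the transition state of the ring interconversion).
Ryckaert–Bellemans terms use &psi; = &theta; − 180°.

The QM merit &Phi; is the Boltzmann-weighted root-mean-square deviation
between a QM torsion scan and baseline-plus-candidate-term energies, with
weights &prop; exp(−&beta;E~QM~), &beta; = 1.0 mol/kcal; torsion terms stay
in kJ/mol with conversion at the &Phi; boundary, and the offset k0 is
optimised in closed form, making &Phi; invariant to constant shifts.
Annealing uses geometric cooling over 200 temperatures with 50 proposals
each (the source method states no schedule; this one converges well inside a
second on 31-point profiles) followed by a bounded quasi-Newton polish.
Phases default to the AMBER convention for this torsion class
(&gamma;1 = &gamma;2 = 180°, &gamma;3 = 0°) and are held fixed: on a ±75°
scan window, freeing the phases makes the three-term cosine basis nearly
degenerate with the free offset, and no optimiser can then pin a planted V3
to ±0.2 kJ/mol under realistic noise.  Discrete 0/180° flips remain
available via `free_gamma = TRUE`.

`simplex_fit()` is a from-scratch Nelder–Mead whose initial simplex perturbs
vertex j multiplicatively, x~j~ &rarr; x~j~ + c·x~j~; sweeping the restart
factor c probes different basins, positivity is enforced by projection, and
c = 0 is rejected as degenerate.  The MD engine inside simplex steps is a
pluggable backend (closed-form two-state couplings or the simulator); real
MD backends are out of scope.  Reweighting implements Boltzmann frame
weights with the effective sample size (&Sigma;w)²/&Sigma;w² as the overlap
diagnostic; a collectivity-style acceptance screen can be plugged in on top,
with ESS/n as the default surrogate.

The timescale calibration `timescale_calibration()` is an ordinary least
squares fit of V against ln &tau;, with `calibration_line()` available to
evaluate a published line directly.  Evaluating the published proline line
(slope 1.9272, intercept −2.1881) at &tau;e = 29.7 ps gives
V3 = 4.3473 kJ/mol; the hydroxyproline line (3.6404, −10.555) at 82.6 ps
gives 5.5138 kJ/mol.

# Problem sizes and numerical tolerances

Statistical tests run at the sizes a desk-scale study supports: 10⁶-step
state series for stationarity, exchange-time and transition-rate checks
(frames strided to &tau;~ex~/10 where near-independent samples are wanted),
2×10⁵–10⁶-step vector series for ACF and Lipari–Szabo recovery, 20–25
replicates for noise-recovery studies, and 31-point scan profiles for the
annealing fits.  Root solves are converged to 1e−4 ps, round-trip identities
hold to 1e−6 relative (1e−9 for pure geometry), and statistical assertions
use 3&sigma; bounds from the generator's own closed forms.

# Known limitations

* The 8D secondary Karplus coefficients are transcribed from secondary
  reproductions of the original table; absolute coupling scales should be
  re-verified against primary data before quantitative use on new systems.
* Published coupling-fit residuals depend on the exact proton-dihedral
  bookkeeping of the original fitting code, which is not restated anywhere;
  bit-reproduction of those residuals is not expected.
* Only five-membered rings are supported (no Cremer–Pople generalisation),
  overall tumbling is isotropic, and the relaxation model omits
  cross-correlation and NOE-factor effects.
* The CSA convention yields a ~1% fractional contribution at the study
  field; this differs slightly from the "<1%" bookkeeping of the source
  data and is surfaced as a diagnostic rather than forced.
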