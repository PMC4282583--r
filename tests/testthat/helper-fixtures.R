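# Shared geometric fixtures built in code.

# planar regular pentagon with 1.53 Angstrom sides, in the xy plane
planar_pentagon <- function(bond = 1.53) {
  r <- bond / (2 * sin(pi / 5))
  ang <- 2 * pi * (0:4) / 5
  cbind(r * cos(ang), r * sin(ang), 0)
}

rotation_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rotation_axis <- function(axis, deg) {
  k <- axis / sqrt(sum(axis^2)); a <- deg * pi / 180
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# two-conformer ideal couplings mixed at x_endo: the closed-form two-state
# coupling average used as generating truth in fit tests
two_state_couplings <- function(p_exo, p_endo, chi_m, x_endo) {
  je <- conformer_couplings(ideal_ring_torsions(p_endo, chi_m))$values
  jx <- conformer_couplings(ideal_ring_torsions(p_exo, chi_m))$values
  coupling_set(x_endo * je + (1 - x_endo) * jx)
}
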