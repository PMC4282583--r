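# Generalized Karplus prediction, trajectory averaging, the rms_Jp merit,
# the two-state coupling fit and NOE r^-6 averaging.

test_that("haasnoot_j matches a direct evaluation of the coefficient polynomial", {
  # independent hand evaluation of J = P1 cos^2 + P2 cos + P3 +
  # sum lam (P4 + P5 cos^2(xi phi + P6 |lam|)) for the 8C set
  pat <- substituent_pattern("8C", dchi = c(0.34, 0.281), xi = c(1, -1))
  p <- c(7.76, -1.10, 1.40, 0.56, -2.47, 16.9)
  for (phi in c(0, 60, 180)) {
    pr <- phi * pi / 180
    byhand <- p[1] * cos(pr)^2 + p[2] * cos(pr) + p[3] +
      0.34  * (p[4] + p[5] * cos(+pr + p[6] * 0.34  * pi / 180)^2) +
      0.281 * (p[4] + p[5] * cos(-pr + p[6] * 0.281 * pi / 180)^2)
    expect_equal(haasnoot_j(phi, pat), byhand, tolerance = 1e-6)
  }
})

test_that("Karplus curves are periodic with a minimum near 90 degrees", {
  pats <- pro_ring_patterns()
  grid <- seq(0, 359.5, by = 0.5)
  for (nm in c("ab2", "b2g2", "g3d3")) {
    pat <- pats[[nm]]
    expect_equal(haasnoot_j(grid, pat), haasnoot_j(grid + 360, pat),
                 tolerance = 1e-12)
    expect_lt(haasnoot_j(90, pat), haasnoot_j(0, pat))
    expect_lt(haasnoot_j(90, pat), haasnoot_j(180, pat))
    # bounded, with a trans maximum in the usual 8-16 Hz window
    v <- haasnoot_j(grid, pat)
    expect_gte(min(v), 0); expect_lte(max(v), 16); expect_gte(max(v), 8)
  }
})

test_that("offset model agrees with explicit proton geometry across the cycle", {
  offs <- pro_ring_offsets()
  for (P in seq(0, 324, by = 36)) {
    ring <- add_ring_protons(ideal_ring_coords(P, 40))
    x <- ring$coords; e <- ring$extra
    geo <- c(
      ab2  = dihedral(e$HA, x[2, ], x[3, ], e$HB2),
      ab3  = dihedral(e$HA, x[2, ], x[3, ], e$HB3),
      b2g2 = dihedral(e$HB2, x[3, ], x[4, ], e$HG2),
      b2g3 = dihedral(e$HB2, x[3, ], x[4, ], e$HG3),
      b3g2 = dihedral(e$HB3, x[3, ], x[4, ], e$HG2),
      b3g3 = dihedral(e$HB3, x[3, ], x[4, ], e$HG3),
      g2d2 = dihedral(e$HG2, x[4, ], x[5, ], e$HD2),
      g2d3 = dihedral(e$HG2, x[4, ], x[5, ], e$HD3),
      g3d2 = dihedral(e$HG3, x[4, ], x[5, ], e$HD2),
      g3d3 = dihedral(e$HG3, x[4, ], x[5, ], e$HD3))
    model <- ring_proton_dihedrals(endocyclic_torsions(ring), offs)
    expect_lt(max(abs(wrap_angle(geo[names(model)] - model))), 8)
  }
})

test_that("offset configuration behaves as specified", {
  t <- ideal_ring_torsions(100, 40)
  offs0 <- pro_ring_offsets(); offs0$offset <- 0
  expect_equal(unname(ring_proton_dihedrals(t, offs0)),
               unname(as.numeric(t)[offs0$parent]))
  # chi3 = 0 at this phase, so a zero-offset gamma-delta pair is zero too
  t2 <- ideal_ring_torsions(90 - 144, 40)   # makes chi3 = chi_m cos(90) = 0
  expect_equal(unname(ring_proton_dihedrals(t2, offs0)["g2d2"]), 0,
               tolerance = 1e-9)
})

test_that("trajectory averaging is the weighted arithmetic mean of frames", {
  t1 <- as.numeric(ideal_ring_torsions(14, 40))
  t2 <- as.numeric(ideal_ring_torsions(185, 40))
  one <- average_couplings(matrix(t1, 1))
  expect_equal(one$values, conformer_couplings(ring_torsions(t1))$values,
               tolerance = 1e-12)
  both <- average_couplings(rbind(t1, t2))
  expect_equal(both$values,
               0.5 * conformer_couplings(ring_torsions(t1))$values +
                 0.5 * conformer_couplings(ring_torsions(t2))$values,
               tolerance = 1e-12)
  # linearity in frame weights; uniform weights equal the plain mean
  w <- average_couplings(rbind(t1, t2), weights = c(2, 2))
  expect_equal(w$values, both$values, tolerance = 1e-12)
  expect_error(average_couplings(matrix(numeric(0), 0, 5)), "empty")
})

test_that("two-state simulator averages approach the x-weighted closed form", {
  p <- synthetic_params(x_endo = 0.55, tau_ex = 30, chi_m = 40,
                        p_endo = 185, p_exo = 14, libration_sd = 0,
                        dt = 1, n_steps = 5e4, seed = 21)
  sim <- simulate_states(p)
  avg <- average_couplings(sim$torsions)
  x_hat <- mean(sim$states == 1L)
  closed <- two_state_couplings(14, 185, 40, x_hat)
  expect_lt(rms_jp(avg, closed), 1e-10)   # sigma = 0: frames are the two states
  closed_x <- two_state_couplings(14, 185, 40, 0.55)
  expect_lt(rms_jp(avg, closed_x), 0.1)   # Monte-Carlo error in x only
})

test_that("rms_jp is the root-mean-square residual over shared labels", {
  je <- two_state_couplings(14, 185, 40, 0.6)
  expect_equal(rms_jp(je, je), 0)
  shifted <- coupling_set(je$values + 1)
  expect_equal(rms_jp(shifted, je), 1, tolerance = 1e-12)
  res <- c(0.3, -0.4, 0.5, rep(0, 7))
  perturbed <- coupling_set(je$values + res)
  expect_equal(rms_jp(perturbed, je), sqrt(0.5 / 10), tolerance = 1e-12)
  bad <- coupling_set(c(zz = 1))
  expect_error(rms_jp(bad, je), "shared")
})

test_that("two_state_jfit recovers the generating parameters without noise", {
  truth <- two_state_couplings(14, 185, 40.3, 0.611)
  fit <- two_state_jfit(truth)
  expect_equal(unname(coef(fit)), c(14, 185, 40.3, 0.611), tolerance = 1e-2)
  expect_lt(fit$rms, 1e-3)
})

test_that("a single-state truth drives x_endo to the bound and is flagged", {
  truth <- conformer_couplings(ideal_ring_torsions(185, 40.3))
  fit <- two_state_jfit(coupling_set(truth$values))
  expect_equal(fit$x_endo, 1, tolerance = 1e-3)
  expect_false(fit$x_endo_identifiable)
})

test_that("x_endo recovery under 0.1 Hz noise stays within 3 percent", {
  truth <- two_state_couplings(14, 185, 40.3, 0.611)
  set.seed(77)
  xs <- replicate(25, {
    noisy <- stats::setNames(pmax(0, truth$values + stats::rnorm(10, 0, 0.1)),
                             names(truth$values))
    coef(two_state_jfit(coupling_set(noisy), n_starts = 8))[["x_endo"]]
  })
  expect_true(all(abs(xs - 0.611) < 0.03 * 1))    # within +-0.03 absolute
  expect_lt(abs(mean(xs) - 0.611), 0.01)          # unbiased at this noise
})

test_that("NOE r^-6 averaging reduces to statics and matches hand arithmetic", {
  base <- rbind(c(0, 0, 0), c(2.4, 0, 0), c(0, 3, 0))
  static <- list(base, base)
  d <- noe_distances(static, pairs = list(ref = c(1, 2), far = c(1, 3)),
                     ref_pair = c(1, 2))
  expect_equal(unname(d["ref"]), 2.4, tolerance = 1e-12)
  expect_equal(unname(d["far"]), 3.0, tolerance = 1e-12)
  # alternating 2 / 4 Angstrom: effective r = (mean r^-6)^(-1/6), scaled
  alt <- list(rbind(c(0, 0, 0), c(2.4, 0, 0), c(2, 0, 1e-9)),
              rbind(c(0, 0, 0), c(2.4, 0, 0), c(4, 0, 1e-9)))
  d2 <- noe_distances(alt, pairs = list(p = c(1, 3)), ref_pair = c(1, 2))
  # with the reference static at its own calibration distance, the scaling
  # cancels and r_p = (mean r^-6)^(-1/6) ~ 2.244 Angstrom
  expect_equal(unname(d2["p"]), mean(c(2^-6, 4^-6))^(-1 / 6),
               tolerance = 1e-6)
  # frame order and per-frame rigid motion do not matter
  d3 <- noe_distances(rev(alt), pairs = list(p = c(1, 3)), ref_pair = c(1, 2))
  expect_equal(d3, d2, tolerance = 1e-12)
})
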