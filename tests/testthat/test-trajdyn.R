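# Time-series analysis: P2 autocorrelation, Lipari-Szabo fitting, transition
# counting with hysteresis, populations and overall-motion removal.

test_that("P2 ACF of degenerate series behaves as expected", {
  const <- matrix(rep(c(0, 0, 1), each = 50), ncol = 3)
  ac <- acf_p2(vector_series(const, dt = 1), max_lag = 10)
  expect_equal(ac$c, rep(1, 11), tolerance = 1e-12)
  set.seed(10)
  z <- matrix(stats::rnorm(3 * 20000), ncol = 3)
  z <- z / sqrt(rowSums(z^2))
  ac2 <- acf_p2(vector_series(z, dt = 1), max_lag = 20)
  expect_equal(ac2$c[1], 1, tolerance = 1e-12)
  expect_lt(max(abs(ac2$c[-1])), 0.05)     # isotropy
  expect_error(acf_p2(vector_series(z, 1), max_lag = 3e4), "duration")
})

test_that("simulator ACF matches the analytic two-state curve", {
  p <- synthetic_params(x_endo = 0.543, tau_ex = 29.7, dtheta = 82.56,
                        tau_c = 0, dt = 1, n_steps = 2e5, seed = 1)
  vs <- simulate_ch_vectors(p)
  ac <- acf_p2(vs, max_lag = 150, se = "jackknife")
  an <- two_state_acf(ac$lag_ps, p)
  expect_lt(max(abs(ac$c - an) / pmax(ac$se, 1e-12)), 3)
})

test_that("Lipari-Szabo fit inverts its own analytic curve exactly", {
  lags <- 0:500
  curve <- structure(list(lag_ps = lags,
                          c = 0.29 + (1 - 0.29) * exp(-lags / 28.7),
                          dt = 1), class = "acf_curve")
  fit <- lipari_szabo_fit(curve, window = 500)
  expect_equal(fit$s2, 0.29, tolerance = 1e-9)
  expect_equal(fit$tau_e, 28.7, tolerance = 1e-7)
})

test_that("a flat curve yields S2 = 1 with tau_e flagged unidentifiable", {
  flat <- structure(list(lag_ps = 0:100, c = rep(1, 101), dt = 1),
                    class = "acf_curve")
  fit <- lipari_szabo_fit(flat, window = 100)
  expect_equal(fit$s2, 1)
  expect_false(fit$tau_e_identifiable)
})

test_that("Lipari-Szabo recovery from simulated curves is accurate", {
  p <- synthetic_params(x_endo = 0.543, tau_ex = 29.7, dtheta = 82.56,
                        tau_c = 0, dt = 1, n_steps = 1e6, seed = 2)
  ac <- acf_p2(simulate_ch_vectors(p), max_lag = 200)
  fit <- lipari_szabo_fit(ac, window = 200)
  s2_true <- order_parameter(p$x_endo, p$dtheta)
  expect_lt(abs(fit$s2 - s2_true), 0.02)
  expect_lt(abs(fit$tau_e - p$tau_ex) / p$tau_ex, 0.10)
})

test_that("transition counting crosses once for a monotone sweep", {
  sweep1 <- seq(-40, 40, length.out = 201)
  tc <- transition_count(sweep1, dt = 1, core = 10, stride = 1)
  expect_equal(tc$n_transitions, 1)
})

test_that("hysteresis suppresses chatter inside one core region", {
  set.seed(11)
  noisy <- -40 + stats::rnorm(5000, 0, 8)   # wanders, stays endo-side
  tc <- transition_count(noisy, dt = 1, core = 10)
  expect_equal(tc$n_transitions, 0)
  # and libration smaller than the band never creates counts even when
  # centred at the band edge minus the amplitude
  lib <- -15 + 4 * sin(seq(0, 100 * pi, length.out = 5000))
  expect_equal(transition_count(lib, dt = 1, core = 10)$n_transitions, 0)
})

test_that("transition rate matches the Markov-chain closed form", {
  p <- synthetic_params(x_endo = 0.55, tau_ex = 30, dt = 0.25,
                        n_steps = 2e6, seed = 12, libration_sd = 4)
  sim <- simulate_states(p)
  tc <- transition_count(sim$chi2, dt = p$dt, core = 10, stride = p$dt)
  rate_theory <- 2 * 0.55 * 0.45 / 30 * 1000   # per ns
  n_expect <- rate_theory * tc$duration_ns
  expect_lt(abs(tc$n_transitions - n_expect), 3 * sqrt(n_expect))
})

test_that("state populations recover the stationary distribution", {
  expect_equal(state_populations(rep(-40, 100)), 1)
  expect_equal(state_populations(rep(c(-40, 40), each = 50)), 0.5)
  # dt at the coarsest allowed stride (tau_ex / 10) keeps successive frames
  # close to independent, so the n = 1e6 estimate resolves 0.005
  p <- synthetic_params(x_endo = 0.567, tau_ex = 30, dt = 3,
                        n_steps = 1e6, seed = 13)
  sim <- simulate_states(p)
  expect_lt(abs(state_populations(sim$chi2) - 0.567), 0.005)
})

test_that("populations and jump angle compose to the fitted order parameter", {
  p <- synthetic_params(x_endo = 0.543, tau_ex = 29.7, dtheta = 82.56,
                        tau_c = 0, dt = 1, n_steps = 5e5, seed = 14)
  vs <- simulate_ch_vectors(p)
  sim_states <- attr(vs, "states")
  x_hat <- mean(sim_states == 1L)
  s2_comp <- order_parameter(x_hat, p$dtheta)
  fit <- lipari_szabo_fit(acf_p2(vs, max_lag = 200), window = 200)
  expect_lt(abs(s2_comp - fit$s2), 0.03)
})

test_that("overall-motion removal restores a rigidly moved trajectory", {
  base <- rbind(ideal_ring_coords(14, 39)$coords, c(3, 1, 0.5))
  set.seed(15)
  frames <- lapply(1:20, function(i) {
    ax <- stats::rnorm(3)
    sweep(base %*% t(rotation_axis(ax, stats::runif(1, 0, 180))), 2,
          stats::rnorm(3, 0, 5), "+")
  })
  out <- remove_overall_motion(frames, anchor = 1:4)
  expect_lt(max(out$anchor_rmsd), 1e-9)
  ref <- out$frames[[out$reference]]
  for (f in out$frames) expect_equal(f, ref, tolerance = 1e-8)
})

test_that("motion removal leaves the C-H ACF flat when only tumbling acts", {
  # frames: a rigid fragment tumbling with no internal motion; after
  # superposition on the anchors the bond vector is constant in time
  base <- rbind(ideal_ring_coords(14, 39)$coords, c(2, 2, 2))
  set.seed(16)
  R <- diag(3)
  frames <- lapply(1:500, function(i) {
    R <<- rotation_axis(stats::rnorm(3), 4) %*% R
    base %*% t(R)
  })
  out <- remove_overall_motion(frames, anchor = 1:4)
  u <- t(vapply(out$frames, function(f) {
    v <- f[6, ] - f[4, ]; v / sqrt(sum(v^2))
  }, numeric(3)))
  ac <- acf_p2(vector_series(u, dt = 1), max_lag = 100)
  expect_equal(ac$c, rep(1, 101), tolerance = 1e-9)
})
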