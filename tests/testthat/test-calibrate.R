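# Torsion-energy conventions, QM merit fitting, simplex with restart-factor
# initial vertices, grid scans, reweighting and the timescale calibration.

test_that("a pure V3 term has period 120 and barrier V3 at theta = 0", {
  term <- torsion_term("cosine_series", v = c(0, 0, 5), gamma = c(180, 180, 0))
  grid <- seq(-180, 180, by = 0.5)
  e <- torsion_energy(grid, term)
  expect_equal(torsion_energy(0, term) - min(e), 5, tolerance = 1e-9)
  expect_equal(torsion_energy(grid, term), torsion_energy(grid + 120, term),
               tolerance = 1e-9)
  # minima where cos(3 theta) = -1
  expect_equal(torsion_energy(60, term), 0, tolerance = 1e-12)
  # V1/V2 with gamma = 180 vanish at theta = 0, preserving the barrier = V3
  full <- torsion_term("cosine_series", v = c(1.1, 0.9, 5),
                       gamma = c(180, 180, 0))
  expect_equal(torsion_energy(0, full), 5, tolerance = 1e-12)
})

test_that("Ryckaert-Bellemans energies follow the psi = theta - 180 convention", {
  rb <- torsion_term("ryckaert_bellemans",
                     c_coef = c(0.6527, 0, 12.46832, 0, 0, 0))
  expect_equal(torsion_energy(180, rb), 0.6527 + 12.46832, tolerance = 1e-12)
  expect_equal(torsion_energy(90, rb), 0.6527, tolerance = 1e-12)  # cos(psi)=0
  expect_error(torsion_energy(0, structure(list(form = "x"), class = "list")),
               "unknown")
})

test_that("Phi vanishes when the model matches and absorbs constant offsets", {
  term <- torsion_term("cosine_series", v = c(0, 0, 4), gamma = c(180, 180, 0))
  prof <- synth_qm_profile(term, noise_sd = 0, seed = 3)
  m <- qm_merit_phi(prof, term)
  expect_equal(m$phi, 0, tolerance = 1e-9)
  shifted <- qm_profile(prof$angle_deg, prof$e_qm + 3.7, prof$e_mm_base)
  m2 <- qm_merit_phi(shifted, term)
  expect_equal(m2$phi, 0, tolerance = 1e-9)
  expect_equal(m2$k0, m$k0 + 3.7, tolerance = 1e-9)
  # with k0 pinned at the wrong offset the merit no longer vanishes
  expect_gt(qm_merit_phi(shifted, term, k0 = 0)$phi, 1)
})

test_that("annealing recovers a planted V3 and reruns bit-identically", {
  truth <- torsion_term("cosine_series", v = c(0, 0, 5), gamma = c(180, 180, 0))
  prof <- synth_qm_profile(truth, noise_sd = 0.05, seed = 31)
  fit <- anneal_torsion_fit(prof, seed = 4)
  expect_lt(abs(fit$term$v[3] - 5), 0.2)
  # V1/V2 perturb the scan window an order of magnitude more weakly than V3,
  # so at this noise their estimates scatter around zero at the ~1 kJ/mol
  # scale; they must stay small relative to the planted barrier
  expect_lt(fit$term$v[1], 1.2); expect_lt(fit$term$v[2], 1.2)
  fit2 <- anneal_torsion_fit(prof, seed = 4)
  expect_identical(fit$term$v, fit2$term$v)
  # all-zero profile drives every V to zero
  zero <- qm_profile(seq(-75, 75, 5), rep(0, 31), rep(0, 31))
  fit0 <- anneal_torsion_fit(zero, seed = 4)
  expect_lt(max(fit0$term$v), 1e-6)
})

test_that("a larger planted barrier is recovered tightly without noise", {
  truth <- torsion_term("cosine_series", v = c(0, 0, 6.61951),
                        gamma = c(180, 180, 0))
  prof <- synth_qm_profile(truth, noise_sd = 0, seed = 32)
  fit <- anneal_torsion_fit(prof, seed = 4)
  expect_lt(abs(fit$term$v[3] - 6.61951), 0.1)
  expect_lt(max(fit$term$v[1:2]), 0.01)   # without noise V1, V2 vanish
})

test_that("simplex converges on a quadratic and rejects a degenerate start", {
  back <- function(x) sum((x - c(1.2, 0.8, 2.0))^2)
  fit <- simplex_fit(back, c(0.5, 0.5, 0.5), c = 0.5)
  expect_equal(fit$par, c(1.2, 0.8, 2.0), tolerance = 1e-3)
  expect_true(fit$converged)
  expect_true(all(diff(fit$trace) <= 1e-12))   # monotone best-so-far
  expect_error(simplex_fit(back, c(1, 1, 1), c = 0), "degenerate")
})

test_that("simplex drives a coupling-merit backend to the generating truth", {
  target <- two_state_couplings(14, 185, 40.3, 0.611)
  backend <- function(x)  # x = (x_endo,) positive scalar parameter
    rms_jp(two_state_couplings(14, 185, 40.3, min(x[1], 1)), target)
  fit <- simplex_fit(backend, x0 = 0.3, c = 0.5, tol = 1e-12)
  expect_equal(unname(fit$par[1]), 0.611, tolerance = 1e-4)
})

test_that("grid scan enumerates and orders the merit surface", {
  back <- function(v, g) (v - 3)^2 + (g - 10)^2 / 100
  sc <- grid_scan(back, 1:5, seq(-50, 50, by = 10))
  expect_equal(nrow(sc), 5 * 11)
  expect_equal(sc$v[1], 3); expect_equal(sc$gamma[1], 10)
  expect_true(!is.unsorted(sc$merit))
  one <- grid_scan(back, 3, 10)
  expect_equal(one$merit, back(3, 10))
  expect_error(grid_scan(back, numeric(0), 1), "empty")
})

test_that("reweighting to an identical term returns the plain mean, ESS = n", {
  set.seed(33)
  chi <- stats::runif(500, -60, 60)
  term <- torsion_term("cosine_series", v = c(0, 0, 2), gamma = c(180, 180, 0))
  obs <- cos(chi * pi / 180)
  rw <- reweighted_average(chi, term, term, obs)
  expect_equal(rw$mean, mean(obs), tolerance = 1e-12)
  expect_equal(rw$ess, 500, tolerance = 1e-9)
})

test_that("two-state reweighting matches the closed-form Boltzmann shift", {
  # libration-free series: chi2 takes exactly two values, so the reweighted
  # population has an exact two-level Boltzmann closed form
  p <- synthetic_params(x_endo = 0.55, tau_ex = 30, libration_sd = 0,
                        dt = 1, n_steps = 2e5, seed = 34)
  sim <- simulate_states(p)
  old <- torsion_term("cosine_series", v = c(0, 0, 2), gamma = c(180, 180, 0))
  new <- torsion_term("cosine_series", v = c(0, 0, 2), gamma = c(180, 180, 40))
  rw <- reweighted_average(sim$chi2, old, new,
                           observable = function(chi) as.numeric(chi < 0))
  beta <- 1000 / (8.314462618 * 298.15)
  chi_e <- unique(sim$chi2[sim$states == 1L])
  chi_x <- unique(sim$chi2[sim$states == 2L])
  de <- function(chi) torsion_energy(chi, new) - torsion_energy(chi, old)
  x0 <- mean(sim$states == 1L)
  w_e <- x0 * exp(-beta * de(chi_e))
  w_x <- (1 - x0) * exp(-beta * de(chi_x))
  expect_equal(rw$mean, w_e / (w_e + w_x), tolerance = 1e-9)
  expect_lte(rw$ess, rw$n)
})

test_that("extreme barrier changes collapse the effective sample size", {
  set.seed(35)
  chi <- c(stats::rnorm(1000, -40, 4), stats::rnorm(5, 40, 4))
  old <- torsion_term("cosine_series", v = c(0, 0, 0), gamma = c(180, 180, 0))
  # the new term puts the bulk of the frames (around -40 deg) high in
  # energy, crushing their weights
  new <- torsion_term("cosine_series", v = c(0, 0, 200),
                      gamma = c(180, 180, -60))
  expect_warning(
    rw <- reweighted_average(chi, old, new, observable = abs(chi)),
    "low overlap")
  expect_lt(rw$ess, 0.1 * rw$n)
})

test_that("timescale calibration inverts exact exponential pairs", {
  a <- 1.9272; b <- -2.1881
  v <- seq(2, 7, by = 0.5)
  tau <- exp((v - b) / a)
  cal <- timescale_calibration(v, tau)
  expect_equal(cal$slope, a, tolerance = 1e-9)
  expect_equal(cal$intercept, b, tolerance = 1e-9)
  expect_equal(cal$r2, 1, tolerance = 1e-12)
  expect_error(timescale_calibration(c(1, 2), c(5, 5)), "degenerate")
  # equivariance: scaling all tau by s shifts V* by a ln(s)
  cal2 <- timescale_calibration(v, tau * 3)
  expect_equal(predict(cal2, 3 * 29.7) - predict(cal, 29.7), 0,
               tolerance = 1e-9)
  m <- timescale_match(v, tau, target_tau_ps = 29.7)
  expect_equal(m$v_star, a * log(29.7) + b, tolerance = 1e-9)
})

test_that("published calibration lines evaluate to the selected barriers", {
  expect_equal(predict(calibration_line(1.9272, -2.1881), 29.7), 4.3474,
               tolerance = 1e-3)
  expect_equal(predict(calibration_line(3.6404, -10.555), 82.6), 5.5138,
               tolerance = 1e-3)
})

test_that("log transition rate falls linearly with the barrier height", {
  # simulator analogue of the ln(N) vs V3 linearity: exchange time grows
  # Arrhenius-like with the barrier, so ln(rate) vs V3 is linear with
  # negative slope
  v3 <- c(1, 2, 3, 4)
  beta <- 1000 / (8.314462618 * 298.15)
  rates <- vapply(seq_along(v3), function(i) {
    tau <- 5 * exp(beta * v3[i])         # Arrhenius exchange time, ps
    p <- synthetic_params(x_endo = 0.55, tau_ex = tau, dt = tau / 20,
                          n_steps = 2e5, seed = 40 + i)
    sim <- simulate_states(p)
    transition_count(sim$chi2, dt = p$dt, core = 10,
                     stride = p$dt)$rate_per_ns
  }, numeric(1))
  fit <- stats::lm(log(rates) ~ v3)
  expect_lt(stats::coef(fit)[2], 0)
  expect_gt(summary(fit)$r.squared, 0.98)
})
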