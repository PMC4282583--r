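# Seeded synthetic two-state ring-dynamics generator: Markov-jump state
# series with libration, C-H bond-vector trajectories with optional overall
# isotropic tumbling, forward-model T1 datasets and pseudo-QM torsion
# profiles.  Stands in for explicit-solvent MD and for experiment in tests
# and worked examples.

#' Synthetic two-state dynamics parameters
#'
#' Defines a two-site endo/exo exchange: stationary endo population `x_endo`,
#' exchange correlation time `tau_ex` (the relaxation time of the two-state
#' Markov process, equal to the internal correlation time tau_e of the
#' two-site jump model), ring geometry (P_endo, P_exo, chi_m), per-torsion
#' Gaussian libration, C-H jump angle and optional isotropic tumbling.
#'
#' @param x_endo stationary endo population.
#' @param tau_ex exchange correlation time, ps (1 / (k_eo + k_oe)).
#' @param chi_m pucker amplitude, degrees.
#' @param p_endo,p_exo pucker phases of the two states, degrees.
#' @param libration_sd Gaussian libration of each torsion, degrees.
#' @param dtheta C-H jump angle between the two states, degrees.
#' @param tau_c overall tumbling correlation time, ps (0 disables tumbling).
#' @param dt time step, ps (must satisfy dt <= tau_ex / 10, and
#'   dt <= tau_c / 50 when tumbling is on).
#' @param n_steps number of frames.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return object of class `synthetic_params`.
#' @export
synthetic_params <- function(x_endo = 0.543, tau_ex = 29.7, chi_m = 40,
                             p_endo = 180, p_exo = 14, libration_sd = 5,
                             dtheta = 82.56, tau_c = 0, dt = 1,
                             n_steps = 1e5, seed = 1L) {
  stopifnot(x_endo > 0, x_endo < 1, tau_ex > 0, dt > 0, n_steps >= 2)
  if (dt > tau_ex / 10)
    stop("dt too coarse: require dt <= tau_ex / 10")
  if (tau_c > 0 && dt > tau_c / 50)
    stop("dt too coarse for tumbling: require dt <= tau_c / 50")
  structure(list(x_endo = x_endo, tau_ex = tau_ex, chi_m = chi_m,
                 p_endo = p_endo, p_exo = p_exo,
                 libration_sd = libration_sd, dtheta = dtheta,
                 tau_c = tau_c, dt = dt, n_steps = as.integer(n_steps),
                 seed = as.integer(seed)),
            class = "synthetic_params")
}

#' Named presets for the studied peptide systems
#'
#' Returns `synthetic_params` mirroring the experimentally characterised
#' systems: `"gpgg"` (x_endo 0.543, tau_e 29.7 ps, tau_c 48.2 ps, jump angle
#' 82.56 deg), `"vapg"` (0.523, 30.7, 82.8, 82.56) and `"ahm"`
#' (hydroxyproline: 0.119, 82.6, 32.8, 82.64).
#'
#' @param name preset name.
#' @param ... overrides passed on to [synthetic_params()].
#' @return `synthetic_params`.
#' @export
synthetic_preset <- function(name = c("gpgg", "vapg", "ahm"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    gpgg = list(x_endo = 0.543, tau_ex = 29.7, tau_c = 48.2, dtheta = 82.56,
                p_endo = 185, p_exo = 14, chi_m = 40.3),
    vapg = list(x_endo = 0.523, tau_ex = 30.7, tau_c = 82.8, dtheta = 82.56,
                p_endo = 189, p_exo = 11, chi_m = 41),
    ahm  = list(x_endo = 0.119, tau_ex = 82.6, tau_c = 32.8, dtheta = 82.64,
                p_endo = 215, p_exo = 12, chi_m = 42))
  do.call(synthetic_params, utils::modifyList(base, list(...)))
}

# exact discrete-time transition probabilities of the two-state chain with
# stationary distribution (x_endo, x_exo) and relaxation time tau_ex:
# p(e->o) = x_exo (1 - exp(-dt/tau_ex)), p(o->e) = x_endo (1 - exp(-dt/tau_ex))
two_state_probs <- function(p) {
  a <- 1 - exp(-p$dt / p$tau_ex)
  c(eo = (1 - p$x_endo) * a, oe = p$x_endo * a)
}

#' Simulate the two-state state series and ring torsions
#'
#' Discretised continuous-time Markov chain with exact stationary
#' distribution (x_endo, 1 - x_endo) and exchange relaxation time tau_ex;
#' per-frame ring torsions are the ideal torsions of the current state's
#' pucker plus independent Gaussian libration on each torsion.  States are
#' generated through geometric sojourn lengths, so the cost is linear in the
#' number of transitions.
#'
#' @param p `synthetic_params`.
#' @return list with `states` (integer, 1 = endo, 2 = exo), `chi2` (degrees),
#'   `torsions` (n x 5 matrix, degrees), `dt`, `params`.
#' @export
simulate_states <- function(p) {
  stopifnot(inherits(p, "synthetic_params"))
  set.seed(p$seed)
  pr <- two_state_probs(p)
  n <- p$n_steps
  state0 <- if (stats::runif(1) < p$x_endo) 1L else 2L
  # alternating geometric sojourns: a sojourn in state s lasts 1 + rgeom(p_s)
  # steps, where p_s is the per-step leaving probability of s; cost is linear
  # in the number of transitions, not in n
  p_leave <- c(pr[["eo"]], pr[["oe"]])
  chunks <- list(); total <- 0L; cur <- state0
  while (total < n) {
    k <- 256L
    s_seq <- rep(c(cur, 3L - cur), length.out = k)
    runs <- stats::rgeom(k, p_leave[s_seq]) + 1L
    cs <- cumsum(runs)
    need <- n - total
    m <- which(cs >= need)[1]
    if (!is.na(m)) {        # last needed sojourn: truncate at the horizon
      runs[m] <- need - (if (m > 1) cs[m - 1] else 0L)
    } else m <- k
    chunks[[length(chunks) + 1L]] <- rep(s_seq[seq_len(m)], runs[seq_len(m)])
    total <- total + sum(runs[seq_len(m)])
    cur <- 3L - s_seq[k]
  }
  states <- unlist(chunks, use.names = FALSE)[seq_len(n)]
  tors_states <- rbind(as.numeric(ideal_ring_torsions(p$p_endo, p$chi_m)),
                       as.numeric(ideal_ring_torsions(p$p_exo, p$chi_m)))
  torsions <- tors_states[states, , drop = FALSE]
  if (p$libration_sd > 0)
    torsions <- torsions + matrix(stats::rnorm(n * 5, 0, p$libration_sd), n, 5)
  colnames(torsions) <- paste0("chi", 1:5)
  list(states = states, chi2 = torsions[, 2], torsions = torsions,
       dt = p$dt, params = p)
}

#' Simulate the C-H bond-vector trajectory
#'
#' The bond direction jumps by exactly `dtheta` between two body-fixed
#' orientations following the two-state series; when `tau_c > 0` an overall
#' isotropic rotational diffusion (small-step random rotations calibrated so
#' the free P2 correlation decays as exp(-t/tau_c)) is composed on top.
#'
#' @param p `synthetic_params`.
#' @return `vector_series` of unit C-H vectors, with the state series
#'   attached as attribute `"states"`.  When tumbling is on, a rigid
#'   "backbone" reference vector experiencing the same overall rotations (the
#'   analogue of a backbone C-alpha H bond, which reports tau_c free of the
#'   ring jump) is attached as attribute `"reference"`.
#' @export
simulate_ch_vectors <- function(p) {
  sim <- simulate_states(p)
  n <- p$n_steps
  half <- deg2rad(p$dtheta) / 2
  u_body <- rbind(c(sin(half), 0, cos(half)),     # endo orientation
                  c(-sin(half), 0, cos(half)))    # exo orientation
  u <- u_body[sim$states, , drop = FALSE]
  ref <- NULL
  if (p$tau_c > 0) {
    # small-step isotropic rotational diffusion: per step rotate by fixed
    # angle eps = sqrt(dt/tau_c) about a uniformly random axis, giving
    # <P2(u(0).u(t))> ~ exp(-t/tau_c) for a jump-free vector
    eps <- sqrt(p$dt / p$tau_c)
    ax <- matrix(stats::rnorm(3 * n), n, 3)
    ax <- ax / sqrt(rowSums(ax^2))
    ce <- cos(eps); se <- sin(eps)
    R <- diag(3)
    ref <- matrix(0, n, 3)
    r_body <- c(1, 0, 0)
    for (i in seq_len(n)) {
      k <- ax[i, ]
      # Rodrigues rotation composed into the accumulated frame
      Kv <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
      R <- (diag(3) * ce + se * Kv + (1 - ce) * tcrossprod(k)) %*% R
      u[i, ] <- R %*% u[i, ]
      ref[i, ] <- R %*% r_body
    }
  }
  vs <- vector_series(u / sqrt(rowSums(u^2)), p$dt)
  attr(vs, "states") <- sim$states
  if (!is.null(ref))
    attr(vs, "reference") <- vector_series(ref / sqrt(rowSums(ref^2)), p$dt)
  vs
}

#' Analytic internal P2 autocorrelation of the two-site jump
#'
#' `C(t) = S^2 + (1 - S^2) exp(-t / tau_ex)` with S^2 from the populations
#' and jump angle: the closed-form oracle for the simulator.
#'
#' @param t lags, ps.
#' @param p `synthetic_params`.
#' @return C(t) values.
#' @export
two_state_acf <- function(t, p) {
  s2 <- order_parameter(p$x_endo, p$dtheta)
  s2 + (1 - s2) * exp(-t / p$tau_ex)
}

#' Synthetic variable-temperature T1 dataset
#'
#' Forward two-site-jump T1 values on a temperature grid with Arrhenius
#' tau_e(T) and tau_c(T), plus multiplicative Gaussian noise emulating
#' measurement reproducibility.
#'
#' @param ctx `spectrometer_context` for the reporter carbon.
#' @param temperatures_k temperature grid, K.
#' @param arr_e,arr_c lists `list(tau0_s=, ea_kj_mol=)` giving the Arrhenius
#'   laws of the internal and overall correlation times.
#' @param x_endo,dtheta two-site jump parameters (temperature independent).
#' @param noise_frac relative (1-sigma) multiplicative noise on T1.
#' @param seed RNG seed.
#' @return data.frame with `temperature_k`, `tau_c_ps`, `tau_e_ps`, `t1_ms`.
#' @export
synth_t1_dataset <- function(ctx, temperatures_k, arr_e, arr_c,
                             x_endo, dtheta, noise_frac = 0, seed = 1L) {
  set.seed(seed)
  tau_e <- arr_e$tau0_s * exp(arr_e$ea_kj_mol * 1000 /
                                (RGAS * temperatures_k)) * 1e12
  tau_c <- arr_c$tau0_s * exp(arr_c$ea_kj_mol * 1000 /
                                (RGAS * temperatures_k)) * 1e12
  t1 <- vapply(seq_along(temperatures_k), function(i)
    1000 / dipolar_r1(ctx, tau_c[i],
                      two_state_model(x_endo, tau_e[i], dtheta)),
    numeric(1))
  if (noise_frac > 0)
    t1 <- t1 * (1 + stats::rnorm(length(t1), 0, noise_frac))
  data.frame(temperature_k = temperatures_k, tau_c_ps = tau_c,
             tau_e_ps = tau_e, t1_ms = t1)
}

#' Synthetic QM torsion-scan profile
#'
#' `E_QM = baseline + E_torsion(true_term) + noise`, `E_MM_base = baseline`,
#' where the baseline is a smooth low-order cosine series with seeded random
#' coefficients of the requested roughness.  The planted term is exactly
#' recoverable at zero noise (up to the constant absorbed by k0).
#'
#' @param true_term planted `torsion_term` (kJ/mol).
#' @param angles scan angles, degrees.
#' @param baseline_roughness amplitude scale of the smooth baseline,
#'   kcal/mol.
#' @param noise_sd Gaussian noise on E_QM, kcal/mol.
#' @param seed RNG seed.
#' @return `qm_profile`.
#' @export
synth_qm_profile <- function(true_term, angles = seq(-75, 75, by = 5),
                             baseline_roughness = 0.5, noise_sd = 0,
                             seed = 1L) {
  set.seed(seed)
  a <- stats::rnorm(2, 0, baseline_roughness)
  baseline <- a[1] * cos(deg2rad(angles)) + a[2] * cos(deg2rad(2 * angles))
  e_tors <- torsion_energy(angles, true_term) * KCAL_PER_KJ
  e_qm <- baseline + e_tors + stats::rnorm(length(angles), 0, noise_sd)
  qm_profile(angles, e_qm, baseline)
}
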