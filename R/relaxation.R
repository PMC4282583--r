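# Dipolar 13C T1 forward model with the two-site-jump spectral density,
# generalized order parameter, inversion of T1 for the overall (tau_c) and
# internal (tau_e) correlation times, the CSA contribution, and Arrhenius
# analysis of correlation times.
#
# Units at the interface: T1 in ms, correlation times in ps, angles in
# degrees.  All internal arithmetic is SI.

# CODATA physical constants
GAMMA_H <- 2.6752219e8    # 1H gyromagnetic ratio, rad s^-1 T^-1
GAMMA_C <- 6.728284e7     # 13C gyromagnetic ratio, rad s^-1 T^-1
HBAR    <- 1.054572e-34   # J s
MU0_4PI <- 1e-7           # T^2 J^-1 m^3
RGAS    <- 8.314462618    # J mol^-1 K^-1

#' Spectrometer context
#'
#' Field and nucleus constants entering the dipolar and CSA relaxation rates.
#' Defaults correspond to a 14.1 T instrument (1H 600.13 MHz, 13C 150.90 MHz)
#' and a 1.09 Angstrom C-H bond.
#'
#' @param nu_h,nu_c 1H and 13C Larmor frequencies, Hz.
#' @param r_ch C-H bond length, Angstrom.
#' @param n_h number of protons attached to the carbon (1, 2 or 3).
#' @param dsigma_ppm chemical shift anisotropy, ppm (e.g. -43 for C-alpha,
#'   -30 for C-gamma of proline).
#' @return object of class `spectrometer_context`.
#' @export
spectrometer_context <- function(nu_h = 600.13e6, nu_c = 150.90e6,
                                 r_ch = 1.09, n_h = 1, dsigma_ppm = -43) {
  stopifnot(r_ch > 0, n_h %in% 1:3)
  if (abs(nu_h / nu_c - GAMMA_H / GAMMA_C) / (GAMMA_H / GAMMA_C) > 0.002)
    warning("nu_H/nu_C deviates from gamma_H/gamma_C by more than 0.2%")
  structure(list(nu_h = nu_h, nu_c = nu_c, r_ch = r_ch, n_h = n_h,
                 dsigma_ppm = dsigma_ppm,
                 omega_h = 2 * pi * nu_h, omega_c = 2 * pi * nu_c),
            class = "spectrometer_context")
}

#' Lorentzian reduced spectral density
#'
#' `j(omega, tau) = tau / (1 + omega^2 tau^2)` (seconds).
#'
#' @param omega angular frequency, rad s^-1.
#' @param tau correlation time, seconds (> 0).
#' @return spectral density, seconds.
#' @export
spectral_density <- function(omega, tau) {
  if (any(tau <= 0)) stop("correlation time must be positive")
  tau / (1 + (omega * tau)^2)
}

#' Two-site jump dynamics model
#'
#' The dynamics contract shared by the relaxation model, the autocorrelation
#' analysis and the synthetic simulator: endo population `x_endo`, internal
#' exchange correlation time `tau_e` (ps) and jump angle `dtheta` (degrees),
#' with derived order parameter `S^2 = 1 - 3 x (1 - x) sin^2(dtheta)`.
#'
#' @param x_endo endo-state population in \[0, 1\].
#' @param tau_e internal correlation time, ps (> 0).
#' @param dtheta jump angle of the C-H bond, degrees.
#' @return object of class `two_state_model` with elements `x_endo`, `tau_e`,
#'   `dtheta`, `s2`.
#' @export
two_state_model <- function(x_endo, tau_e, dtheta) {
  stopifnot(x_endo >= 0, x_endo <= 1, tau_e > 0)
  structure(list(x_endo = x_endo, tau_e = tau_e, dtheta = dtheta,
                 s2 = order_parameter(x_endo, dtheta)),
            class = "two_state_model")
}

#' Generalized order parameter of the two-site jump model
#'
#' `S^2 = 1 - 3 x_endo (1 - x_endo) sin^2(dtheta)`.
#'
#' @param x_endo endo population in \[0, 1\].
#' @param dtheta jump angle, degrees.
#' @return S^2 (dimensionless, in (0, 1\]).
#' @export
order_parameter <- function(x_endo, dtheta) {
  stopifnot(all(x_endo >= 0), all(x_endo <= 1))
  1 - 3 * x_endo * (1 - x_endo) * sin(deg2rad(dtheta))^2
}

# dipolar prefactor K = (mu0/4pi)^2 hbar^2 gH^2 gC^2 / (10 r^6), s^-2
dipolar_k <- function(ctx) {
  r <- ctx$r_ch * 1e-10
  (MU0_4PI * HBAR * GAMMA_H * GAMMA_C)^2 / (10 * r^6)
}

# g(tau) = j(wH - wC) + 3 j(wC) + 6 j(wH + wC), tau in seconds
dipolar_g <- function(ctx, tau_s) {
  spectral_density(ctx$omega_h - ctx$omega_c, tau_s) +
    3 * spectral_density(ctx$omega_c, tau_s) +
    6 * spectral_density(ctx$omega_h + ctx$omega_c, tau_s)
}

#' Dipolar 13C longitudinal relaxation rate (two-site jump model)
#'
#' The Ernst-style two-site-jump dipolar rate
#' `R1 = N K [S^2 g(tau_c) + (1 - S^2) g(tau')]` with
#' `K = (mu0/4pi)^2 hbar^2 gH^2 gC^2 / (10 r_CH^6)`,
#' `g(tau) = j(wH - wC) + 3 j(wC) + 6 j(wH + wC)` and
#' `1/tau' = 1/tau_c + 1/tau_e`.  With `dyn = NULL` the carbon is treated as
#' rigid (S^2 = 1, single correlation time tau_c).
#'
#' @param ctx `spectrometer_context`.
#' @param tau_c overall tumbling correlation time, ps.
#' @param dyn optional `two_state_model` describing the internal jump.
#' @return R1 in s^-1.
#' @export
dipolar_r1 <- function(ctx, tau_c, dyn = NULL) {
  stopifnot(inherits(ctx, "spectrometer_context"), tau_c > 0)
  k <- dipolar_k(ctx)
  tc <- tau_c * 1e-12
  if (is.null(dyn)) return(ctx$n_h * k * dipolar_g(ctx, tc))
  stopifnot(inherits(dyn, "two_state_model"))
  tp <- 1 / (1 / tc + 1 / (dyn$tau_e * 1e-12))
  ctx$n_h * k * (dyn$s2 * dipolar_g(ctx, tc) +
                   (1 - dyn$s2) * dipolar_g(ctx, tp))
}

#' CSA longitudinal relaxation rate
#'
#' Axially symmetric chemical-shift-anisotropy rate
#' `R1_CSA = (2/15) (omega_C dsigma)^2 j(omega_C, tau)`.  At 14.1 T and the
#' measured proline anisotropies this contributes on the order of 1% of the
#' dipolar rate and is reported as a diagnostic, not folded into inversions.
#'
#' @param ctx `spectrometer_context` (uses `dsigma_ppm`).
#' @param tau correlation time, ps.
#' @return R1 in s^-1.
#' @export
csa_r1 <- function(ctx, tau) {
  ds <- ctx$dsigma_ppm * 1e-6
  (2 / 15) * (ctx$omega_c * ds)^2 * spectral_density(ctx$omega_c, tau * 1e-12)
}

# location of the rigid-model R1 maximum (T1 minimum), ps
rigid_t1min_tau <- function(ctx) {
  stats::optimize(function(lt) -dipolar_r1(ctx, exp(lt)),
                  c(log(1), log(1e6)), tol = 1e-10)$minimum |> exp()
}

#' Invert T1 for the overall correlation time (rigid model, fast branch)
#'
#' Solves `dipolar_r1(ctx, tau_c) = 1/T1` for tau_c on the fast-motion branch
#' (tau below the T1 minimum), the regime of small peptides at 14.1 T.
#'
#' @param ctx `spectrometer_context` (its `n_h` is the number of attached
#'   protons of the reporter carbon).
#' @param t1_ms measured T1, ms.
#' @return tau_c in ps (solved to 1e-4 ps).
#' @export
invert_t1_tauc <- function(ctx, t1_ms) {
  stopifnot(t1_ms > 0)
  target <- 1000 / t1_ms
  tau_top <- rigid_t1min_tau(ctx)
  r1_max <- dipolar_r1(ctx, tau_top)
  if (target > r1_max)
    stop(sprintf(
      "T1 = %.3g ms is below the attainable minimum (%.3g ms) of the rigid model",
      t1_ms, 1000 / r1_max))
  f <- function(tau) dipolar_r1(ctx, tau) - target
  stats::uniroot(f, c(1e-4, tau_top), tol = 1e-6)$root
}

#' Invert T1 for the internal correlation time (two-site jump model)
#'
#' Given the overall correlation time, populations and jump angle, solves the
#' two-site-jump dipolar model for tau_e:
#' `dipolar_r1(ctx, tau_c, two_state_model(x_endo, tau_e, dtheta)) = 1/T1`.
#' The rate is monotone in tau_e between the motionally averaged limit
#' (tau_e -> 0) and the rigid limit (tau_e -> Inf) on the fast branch, so the
#' root is bracketed and unique.
#'
#' @param ctx `spectrometer_context`.
#' @param t1_ms measured T1 of the jumping carbon, ms.
#' @param tau_c overall correlation time, ps.
#' @param x_endo endo population.
#' @param dtheta jump angle, degrees.
#' @return tau_e in ps (solved to 1e-4 ps).
#' @export
invert_t1_taue <- function(ctx, t1_ms, tau_c, x_endo, dtheta) {
  stopifnot(t1_ms > 0, tau_c > 0)
  target <- 1000 / t1_ms
  r1_of <- function(te) dipolar_r1(ctx, tau_c, two_state_model(x_endo, te, dtheta))
  lo <- 1e-6; hi <- 1e9
  r_lo <- r1_of(lo); r_hi <- r1_of(hi)
  if (target < min(r_lo, r_hi) || target > max(r_lo, r_hi))
    stop(sprintf(
      paste0("required R1 = %.4g s^-1 outside the attainable range ",
             "[%.4g, %.4g] s^-1 for tau_e in (0, Inf)"),
      target, min(r_lo, r_hi), max(r_lo, r_hi)))
  stats::uniroot(function(te) r1_of(te) - target, c(lo, hi), tol = 1e-6)$root
}

#' Arrhenius fit of correlation times
#'
#' Least squares of `ln tau` versus `1/T` under the Arrhenius law
#' `tau = tau0 exp(Ea / RT)`.
#'
#' @param temperature_k temperatures, K (>= 3 distinct values).
#' @param tau_ps correlation times, ps.
#' @param duplicates `"error"` to refuse duplicated temperatures, `"mean"` to
#'   average ln(tau) within a temperature first.
#' @return object of class `arrhenius_fit`: `ea_kj_mol`, `tau0_s`,
#'   `residuals` (on ln tau) and the underlying `lm` fit.
#' @export
arrhenius_fit <- function(temperature_k, tau_ps,
                          duplicates = c("error", "mean")) {
  duplicates <- match.arg(duplicates)
  stopifnot(length(temperature_k) == length(tau_ps), all(tau_ps > 0))
  if (anyDuplicated(temperature_k)) {
    if (duplicates == "error")
      stop("duplicated temperatures; set duplicates = \"mean\" to aggregate")
    lt <- tapply(log(tau_ps * 1e-12), temperature_k, mean)
    temperature_k <- as.numeric(names(lt)); ln_tau <- as.numeric(lt)
  } else ln_tau <- log(tau_ps * 1e-12)
  if (length(unique(temperature_k)) < 3)
    stop("need at least 3 distinct temperatures")
  invT <- 1 / temperature_k
  fit <- stats::lm(ln_tau ~ invT)
  structure(list(ea_kj_mol = unname(stats::coef(fit)[2]) * RGAS / 1000,
                 tau0_s = exp(unname(stats::coef(fit)[1])),
                 residuals = stats::residuals(fit), lm = fit),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit: Ea = %.3f kJ/mol, tau0 = %.3g s\n",
              x$ea_kj_mol, x$tau0_s))
  invisible(x)
}

#' Evaluate an Arrhenius fit
#'
#' @param object `arrhenius_fit`.
#' @param temperature_k temperatures, K.
#' @param ... unused.
#' @return predicted correlation times, ps.
#' @export
predict.arrhenius_fit <- function(object, temperature_k, ...) {
  object$tau0_s * exp(object$ea_kj_mol * 1000 / (RGAS * temperature_k)) * 1e12
}

#' @export
coef.arrhenius_fit <- function(object, ...) {
  c(ea_kj_mol = object$ea_kj_mol, tau0_s = object$tau0_s)
}
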