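# Torsion-energy terms, QM-profile merit fitting (Phi, simulated annealing),
# Nelder-Mead fitting with the restart-factor initial-vertex scheme, (V, gamma)
# grid scans, single-trajectory reweighting, and the ln-linear timescale
# matching calibration of torsion force constants.

KCAL_PER_KJ <- 1 / 4.184

#' Torsion energy term
#'
#' Either a cosine (AMBER-style) series or a Ryckaert-Bellemans polynomial.
#' The cosine form is `E(theta) = sum_n (V_n / 2) (1 + cos(n theta - gamma_n))`
#' so that for a pure V3 term with gamma3 = 0 the barrier at theta = 0 above
#' the minima equals V3 (the normalisation used for the chi2 interconversion
#' barrier).  The Ryckaert-Bellemans form is
#' `E(theta) = sum_k C_k cos^k(psi)` with `psi = theta - 180`.
#'
#' @param form `"cosine_series"` or `"ryckaert_bellemans"`.
#' @param v force constants V_n, kJ/mol (cosine form; V_n >= 0 when fitted).
#' @param gamma phases gamma_n, degrees (cosine form).
#' @param n periodicities (cosine form; default `seq_along(v)`).
#' @param c_coef coefficients C0..C5, kJ/mol (RB form).
#' @return object of class `torsion_term`.
#' @export
torsion_term <- function(form = c("cosine_series", "ryckaert_bellemans"),
                         v = NULL, gamma = NULL, n = NULL, c_coef = NULL) {
  form <- match.arg(form)
  if (form == "cosine_series") {
    stopifnot(!is.null(v))
    if (is.null(n)) n <- seq_along(v)
    if (is.null(gamma)) gamma <- rep(0, length(v))
    stopifnot(length(v) == length(gamma), length(v) == length(n), all(n >= 1))
    structure(list(form = form, v = v, gamma = gamma, n = n),
              class = "torsion_term")
  } else {
    stopifnot(!is.null(c_coef))
    structure(list(form = form, c_coef = c_coef), class = "torsion_term")
  }
}

#' @export
print.torsion_term <- function(x, ...) {
  if (x$form == "cosine_series") {
    cat("Cosine torsion term (kJ/mol):\n")
    print(data.frame(n = x$n, V = x$v, gamma = x$gamma))
  } else {
    cat("Ryckaert-Bellemans torsion term, C0..C5 (kJ/mol):\n")
    print(x$c_coef)
  }
  invisible(x)
}

#' Torsion energy
#'
#' @param theta dihedral angle(s), degrees (vectorised).
#' @param term a `torsion_term`.
#' @return energy in kJ/mol.
#' @export
torsion_energy <- function(theta, term) {
  if (!inherits(term, "torsion_term")) stop("unknown torsion term form")
  if (term$form == "cosine_series") {
    e <- 0
    for (i in seq_along(term$v))
      e <- e + (term$v[i] / 2) *
        (1 + cos(deg2rad(term$n[i] * theta - term$gamma[i])))
    e
  } else {
    psi <- deg2rad(theta - 180)
    e <- 0
    for (k in seq_along(term$c_coef))
      e <- e + term$c_coef[k] * cos(psi)^(k - 1)
    e
  }
}

#' QM torsion-scan profile
#'
#' @param angle_deg strictly increasing scan angles, degrees (>= 3 points).
#' @param e_qm QM energies, kcal/mol.
#' @param e_mm_base molecular-mechanics baseline energies, kcal/mol, with the
#'   original torsion contribution for the scanned angle already removed.
#' @param beta inverse temperature weighting the merit, mol/kcal (default 1).
#' @return object of class `qm_profile`.
#' @export
qm_profile <- function(angle_deg, e_qm, e_mm_base, beta = 1.0) {
  stopifnot(length(angle_deg) >= 3, all(diff(angle_deg) > 0),
            length(e_qm) == length(angle_deg),
            length(e_mm_base) == length(angle_deg))
  structure(list(angle_deg = angle_deg, e_qm = e_qm,
                 e_mm_base = e_mm_base, beta = beta),
            class = "qm_profile")
}

#' Boltzmann-weighted merit Phi of a torsion term against a QM profile
#'
#' `Phi = sqrt( sum_i w_i (E_QM_i - k0 - E_MM_i)^2 )` with weights
#' `w_i ~ exp(-beta E_QM_i)` (normalised) and
#' `E_MM = E_MM_base + E_torsion(term)`.  Torsion energies (kJ/mol) are
#' converted to the profile's kcal/mol at this boundary.  When `k0 = NULL` the
#' offset is optimised in closed form (the weighted mean residual), making
#' Phi invariant to constant shifts between the profiles.
#'
#' @param p a `qm_profile`.
#' @param term a `torsion_term`.
#' @param k0 fixed offset (kcal/mol) or `NULL` to optimise.
#' @return list with `phi` (kcal/mol) and `k0`.
#' @export
qm_merit_phi <- function(p, term, k0 = NULL) {
  stopifnot(inherits(p, "qm_profile"))
  e_mm <- p$e_mm_base + torsion_energy(p$angle_deg, term) * KCAL_PER_KJ
  w <- exp(-p$beta * (p$e_qm - min(p$e_qm)))
  w <- w / sum(w)
  d <- p$e_qm - e_mm
  if (is.null(k0)) k0 <- sum(w * d)
  list(phi = sqrt(sum(w * (d - k0)^2)), k0 = k0)
}

#' Simulated-annealing fit of a torsion term to a QM profile
#'
#' Minimises Phi over the cosine-series force constants V_1..V_N (constrained
#' non-negative), re-optimising the offset k0 in closed form for each
#' candidate.  Phases follow the AMBER convention for the aliphatic C-C-C-C
#' torsion class (gamma = 180 for n = 1, 2 and 0 for n >= 3) and are held
#' fixed by default; on a limited scan window, freeing the phases makes the
#' three-term basis nearly degenerate with the offset and is best avoided.
#' With `free_gamma = TRUE` discrete 0/180 flips are proposed as well.
#' Geometric cooling, deterministic under a fixed seed.
#'
#' @param p a `qm_profile`.
#' @param n_terms number of cosine terms N (default 3).
#' @param gamma fixed phases, degrees (default AMBER convention
#'   `c(180, 180, 0, 0, ...)`).
#' @param free_gamma if `TRUE`, phases may flip between 0 and 180 during the
#'   anneal.
#' @param n_temps,n_props annealing schedule: `n_temps` geometrically cooled
#'   temperatures with `n_props` proposals each.
#' @param t0,t1 initial and final annealing temperatures (in squared-kcal
#'   merit units).
#' @param seed RNG seed.
#' @return object of class `anneal_fit`: `term` (best `torsion_term`), `phi`,
#'   `k0` and the per-temperature `trace` of the best merit.
#' @export
anneal_torsion_fit <- function(p, n_terms = 3, gamma = NULL,
                               free_gamma = FALSE,
                               n_temps = 200, n_props = 50,
                               t0 = 1, t1 = 1e-6, seed = 1L) {
  stopifnot(inherits(p, "qm_profile"))
  set.seed(seed)
  vmax <- max(1, 4 * (max(p$e_qm) - min(p$e_qm)) / KCAL_PER_KJ)
  v <- rep(0.5, n_terms)
  g <- if (is.null(gamma)) ifelse(seq_len(n_terms) <= 2, 180, 0)
       else rep_len(gamma, n_terms)
  phi_of <- function(v, g)
    qm_merit_phi(p, torsion_term("cosine_series", v = v, gamma = g))$phi
  cur <- phi_of(v, g)
  best <- list(v = v, g = g, phi = cur)
  temps <- t0 * (t1 / t0)^((seq_len(n_temps) - 1) / (n_temps - 1))
  trace <- numeric(n_temps)
  scale0 <- vmax / 10
  for (it in seq_len(n_temps)) {
    sc <- scale0 * sqrt(temps[it] / t0)
    for (k in seq_len(n_props)) {
      vn <- v; gn <- g
      j <- sample.int(n_terms, 1)
      if (free_gamma && stats::runif(1) < 0.15) {
        gn[j] <- 180 - gn[j]
      } else {
        vn[j] <- max(0, vn[j] + stats::rnorm(1, 0, sc))
      }
      cand <- phi_of(vn, gn)
      if (cand < cur || stats::runif(1) < exp((cur - cand) / temps[it])) {
        v <- vn; g <- gn; cur <- cand
        if (cur < best$phi) best <- list(v = v, g = g, phi = cur)
      }
    }
    trace[it] <- best$phi
  }
  # greedy polish: Phi is smooth in V at fixed phases, so finish the anneal
  # with a bounded quasi-Newton descent from the best vertex
  pol <- stats::optim(best$v, function(v) phi_of(pmax(v, 0), best$g),
                      method = "L-BFGS-B", lower = rep(0, n_terms),
                      control = list(maxit = 500))
  if (pol$value < best$phi) best <- list(v = pol$par, g = best$g,
                                         phi = pol$value)
  term <- torsion_term("cosine_series", v = best$v, gamma = best$g)
  structure(list(term = term, phi = best$phi,
                 k0 = qm_merit_phi(p, term)$k0, trace = trace, seed = seed),
            class = "anneal_fit")
}

#' @export
print.anneal_fit <- function(x, ...) {
  cat(sprintf("Annealed torsion fit: Phi = %.4f kcal/mol, k0 = %.4f\n",
              x$phi, x$k0))
  print(x$term)
  invisible(x)
}

#' Nelder-Mead fit with restart-factor initial simplex
#'
#' Downhill simplex over positive parameters with the initial-vertex scheme
#' in which vertex j perturbs parameter j multiplicatively, `x_j -> x_j + c
#' x_j`.  Restarting with different factors c probes different basins of the
#' merit surface.  Positivity (`x_j > 0`) is enforced by projection.
#'
#' @param backend function mapping a parameter vector to a scalar merit
#'   (e.g. rms_Jp evaluated through a trajectory model).
#' @param x0 initial parameter vector (all > 0).
#' @param c restart factor scaling the initial vertex displacements
#'   (must be non-zero; `c = 0` gives a degenerate simplex).
#' @param max_steps maximum simplex iterations.
#' @param tol relative merit spread at which the simplex is converged.
#' @return list with `par`, `value`, `trace` (best merit per iteration),
#'   `n_eval`, `converged`.
#' @export
simplex_fit <- function(backend, x0, c = 0.5, max_steps = 500, tol = 1e-8) {
  stopifnot(is.function(backend), all(x0 > 0))
  if (c == 0) stop("c = 0 gives a degenerate initial simplex")
  n <- length(x0)
  proj <- function(x) pmax(x, 1e-12)
  verts <- matrix(rep(x0, n + 1), n + 1, n, byrow = TRUE)
  for (j in seq_len(n)) verts[j + 1, j] <- x0[j] + c * x0[j]
  verts <- t(apply(verts, 1, proj))
  if (n == 1) verts <- matrix(verts, n + 1, n)
  n_eval <- 0L
  evalf <- function(x) { n_eval <<- n_eval + 1L; backend(x) }
  f <- apply(verts, 1, evalf)
  trace <- numeric(0)
  alpha <- 1; gamma_e <- 2; rho <- 0.5; sigma <- 0.5
  converged <- FALSE
  for (it in seq_len(max_steps)) {
    ord <- order(f); verts <- verts[ord, , drop = FALSE]; f <- f[ord]
    trace <- c(trace, f[1])
    if (abs(f[n + 1] - f[1]) <= tol * (abs(f[1]) + tol)) {
      converged <- TRUE; break
    }
    centroid <- colMeans(verts[1:n, , drop = FALSE])
    xr <- proj(centroid + alpha * (centroid - verts[n + 1, ]))
    fr <- evalf(xr)
    if (fr < f[1]) {
      xe <- proj(centroid + gamma_e * (centroid - verts[n + 1, ]))
      fe <- evalf(xe)
      if (fe < fr) { verts[n + 1, ] <- xe; f[n + 1] <- fe }
      else { verts[n + 1, ] <- xr; f[n + 1] <- fr }
    } else if (fr < f[n]) {
      verts[n + 1, ] <- xr; f[n + 1] <- fr
    } else {
      xc <- proj(centroid + rho * (verts[n + 1, ] - centroid))
      fc <- evalf(xc)
      if (fc < f[n + 1]) { verts[n + 1, ] <- xc; f[n + 1] <- fc }
      else {
        for (i in 2:(n + 1)) {
          verts[i, ] <- proj(verts[1, ] + sigma * (verts[i, ] - verts[1, ]))
          f[i] <- evalf(verts[i, ])
        }
      }
    }
  }
  ord <- order(f)
  list(par = verts[ord[1], ], value = f[ord[1]], trace = trace,
       n_eval = n_eval, converged = converged)
}

#' Grid scan of a merit backend over (V, gamma)
#'
#' Evaluates the backend at every pair on the grid (e.g. V3 from 1 to 5
#' kJ/mol in 1 kJ/mol steps crossed with gamma3 from -50 to 50 degrees in 10
#' degree steps) and returns the table sorted by merit.
#'
#' @param backend function of `(v, gamma)` returning a scalar merit.
#' @param v_values,gamma_values grid values (non-empty).
#' @return data.frame with columns `v`, `gamma`, `merit`, sorted ascending by
#'   merit.
#' @export
grid_scan <- function(backend, v_values, gamma_values) {
  if (length(v_values) == 0 || length(gamma_values) == 0)
    stop("empty grid")
  g <- expand.grid(v = v_values, gamma = gamma_values)
  g$merit <- mapply(backend, g$v, g$gamma)
  g[order(g$merit), , drop = FALSE]
}

#' Single-trajectory reweighting of an observable
#'
#' Boltzmann reweighting of a parent trajectory from one torsion term to
#' another: frame weights `w_i ~ exp(-beta (E_new(chi_i) - E_old(chi_i)))`,
#' normalised.  Returns the reweighted observable mean and the effective
#' sample size `ESS = (sum w)^2 / sum w^2` as the overlap diagnostic (the
#' reweighted trajectory creates no new conformations, so a small ESS signals
#' an unreliable estimate).
#'
#' @param chi_series dihedral series of the scanned angle, degrees.
#' @param old_term,new_term `torsion_term`s in the same dihedral convention.
#' @param observable per-frame observable: numeric vector of length
#'   `length(chi_series)`, or a function of the dihedral vector.
#' @param beta_rw inverse temperature, mol/kJ (default 1/RT at 298.15 K).
#' @param ess_warn_frac warn when ESS falls below this fraction of n.
#' @return list with `mean`, `ess`, `n`, `weights`.
#' @export
reweighted_average <- function(chi_series, old_term, new_term, observable,
                               beta_rw = 1000 / (RGAS * 298.15),
                               ess_warn_frac = 0.1) {
  de <- torsion_energy(chi_series, new_term) -
    torsion_energy(chi_series, old_term)
  lw <- -beta_rw * de
  lw <- lw - max(lw)
  w <- exp(lw)
  sw <- sum(w)
  if (!is.finite(sw) || sw <= 0) stop("all reweighting weights vanished")
  w <- w / sw
  obs <- if (is.function(observable)) observable(chi_series) else observable
  stopifnot(length(obs) == length(chi_series))
  ess <- 1 / sum(w^2)
  if (ess < ess_warn_frac * length(w))
    warning(sprintf("low overlap: ESS = %.1f of n = %d frames",
                    ess, length(w)))
  list(mean = sum(w * obs), ess = ess, n = length(w), weights = w)
}

#' ln-linear timescale-matching calibration
#'
#' Fits `V = a ln(tau) + b` by least squares to (force constant, correlation
#' time) pairs obtained from simulations with different torsion barriers, and
#' evaluates the force constant matching a target (experimental) correlation
#' time.  This is the calibration that selects the torsion barrier whose
#' simulated internal timescale matches experiment.
#'
#' @param v_kj force constants, kJ/mol.
#' @param tau_ps correlation times, ps (> 0, >= 2 distinct).
#' @return object of class `timescale_calibration` with `slope`, `intercept`,
#'   `r2` and the source pairs.  Evaluate with [predict()].
#' @export
timescale_calibration <- function(v_kj, tau_ps) {
  stopifnot(length(v_kj) == length(tau_ps), all(tau_ps > 0))
  if (length(unique(tau_ps)) < 2) stop("degenerate pairs: need distinct tau")
  fit <- stats::lm(v_kj ~ log(tau_ps))
  ss_tot <- sum((v_kj - mean(v_kj))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2,
                 pairs = data.frame(v_kj = v_kj, tau_ps = tau_ps)),
            class = "timescale_calibration")
}

#' Calibration from published slope and intercept
#'
#' Builds a `timescale_calibration` directly from known coefficients of
#' `V = a ln(tau) + b`, for evaluating a published calibration line.
#'
#' @param slope a, kJ/mol per ln(ps).
#' @param intercept b, kJ/mol.
#' @return `timescale_calibration` (without source pairs or r2).
#' @export
calibration_line <- function(slope, intercept) {
  structure(list(slope = slope, intercept = intercept, r2 = NA_real_,
                 pairs = NULL),
            class = "timescale_calibration")
}

#' @export
predict.timescale_calibration <- function(object, tau_ps, ...) {
  stopifnot(all(tau_ps > 0))
  object$slope * log(tau_ps) + object$intercept
}

#' @export
print.timescale_calibration <- function(x, ...) {
  cat(sprintf("Timescale calibration: V = %.4f ln(tau/ps) %+.4f kJ/mol",
              x$slope, x$intercept))
  if (!is.na(x$r2)) cat(sprintf("  (r2 = %.4f)", x$r2))
  cat("\n")
  invisible(x)
}

#' Match a torsion force constant to a target timescale
#'
#' Convenience wrapper: fit the ln-linear calibration to (V, tau) pairs and
#' evaluate it at the target correlation time.
#'
#' @param v_kj,tau_ps calibration pairs as in [timescale_calibration()].
#' @param target_tau_ps target correlation time, ps.
#' @return list with `v_star` (kJ/mol) and the `calibration`.
#' @export
timescale_match <- function(v_kj, tau_ps, target_tau_ps) {
  stopifnot(target_tau_ps > 0)
  cal <- timescale_calibration(v_kj, tau_ps)
  list(v_star = predict(cal, target_tau_ps), calibration = cal)
}
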