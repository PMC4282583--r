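# Trajectory time-series analysis: overall-motion removal, P2 bond-vector
# autocorrelation, Lipari-Szabo model-free fitting, torsional transition
# counting with hysteresis, and state populations.

#' Bond-vector time series
#'
#' @param vectors n x 3 matrix of unit vectors, one frame per row.
#' @param dt frame spacing, ps.
#' @return object of class `vector_series`.
#' @export
vector_series <- function(vectors, dt) {
  vectors <- as.matrix(vectors)
  stopifnot(ncol(vectors) == 3, dt > 0)
  nrm <- sqrt(rowSums(vectors^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("vectors must be unit-norm within 1e-6")
  structure(list(vectors = vectors, dt = dt, n = nrow(vectors)),
            class = "vector_series")
}

#' P2 orientational autocorrelation function
#'
#' `C(t) = < P2( u(s) . u(s+t) ) >` over all overlapping time origins s, with
#' `P2(x) = (3 x^2 - 1) / 2`.  Computed through the tensor identity
#' `(u.u')^2 = sum_ab (u_a u_b)(u'_a u'_b)` so the average reduces to six
#' scalar autocorrelations evaluated by FFT.
#'
#' @param v `vector_series` (or bare n x 3 matrix with `dt` supplied).
#' @param max_lag maximum lag, ps (must be below the series duration).
#' @param dt frame spacing when `v` is a bare matrix.
#' @param se `"none"` or `"jackknife"`: delete-one-block jackknife standard
#'   errors from `blocks` contiguous segments.
#' @param blocks number of blocks for the jackknife.
#' @return object of class `acf_curve`: list with `lag_ps`, `c` (C(t)), and
#'   optionally `se`.
#' @export
acf_p2 <- function(v, max_lag, dt = NULL, se = c("none", "jackknife"),
                   blocks = 10) {
  se <- match.arg(se)
  if (!inherits(v, "vector_series")) v <- vector_series(v, dt)
  n <- v$n
  if (n < 2) stop("empty or single-frame series")
  nlag <- floor(max_lag / v$dt)
  if (nlag >= n) stop("max_lag must be smaller than the series duration")
  cfun <- function(u) {
    m <- nrow(u)
    nl <- min(nlag, m - 1)
    # products u_a u_b with multiplicity weights
    w <- cbind(u[, 1]^2, u[, 2]^2, u[, 3]^2,
               sqrt(2) * u[, 1] * u[, 2],
               sqrt(2) * u[, 1] * u[, 3],
               sqrt(2) * u[, 2] * u[, 3])
    np <- stats::nextn(2 * m)
    s <- numeric(nl + 1)
    for (k in 1:6) {
      f <- stats::fft(c(w[, k], rep(0, np - m)))
      ac <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / np
      s <- s + ac[1:(nl + 1)]
    }
    dot2 <- s / (m - 0:nl)           # <(u(s).u(s+t))^2>
    (3 * dot2 - 1) / 2
  }
  cc <- cfun(v$vectors)
  out <- list(lag_ps = (0:(length(cc) - 1)) * v$dt, c = cc, dt = v$dt)
  if (se == "jackknife") {
    idx <- split(seq_len(n), cut(seq_len(n), blocks, labels = FALSE))
    reps <- sapply(idx, function(i) {
      r <- cfun(v$vectors[i, , drop = FALSE])
      length(r) <- length(cc)        # pad with NA if block shorter than nlag
      r
    })
    out$se <- apply(reps, 1, stats::sd, na.rm = TRUE) / sqrt(blocks)
  }
  structure(out, class = "acf_curve")
}

#' @export
print.acf_curve <- function(x, ...) {
  cat(sprintf("P2 ACF: %d lags, dt = %g ps, C(0) = %.4f\n",
              length(x$c), x$dt, x$c[1]))
  invisible(x)
}

#' @export
plot.acf_curve <- function(x, ...) {
  plot(x$lag_ps, x$c, type = "l", xlab = "lag (ps)", ylab = "C(t)", ...)
  invisible(x)
}

#' Lipari-Szabo model-free fit of an autocorrelation curve
#'
#' Nonlinear least squares of `C(t) = S^2 + (1 - S^2) exp(-t / tau_e)` over
#' the lag window \[0, window\].  S^2 is clipped to \[0, 1\].  A flat curve
#' (C ~ 1) returns S^2 = 1 with `tau_e_identifiable = FALSE`.
#'
#' @param c an `acf_curve`.
#' @param window fit window, ps (default 20000 = 20 ns).
#' @return object of class `lipari_szabo_fit` with `s2`, `tau_e` (ps),
#'   `window`, residual `rms`, `tau_e_identifiable`.
#' @export
lipari_szabo_fit <- function(c, window = 20000) {
  stopifnot(inherits(c, "acf_curve"))
  keep <- c$lag_ps <= window
  if (sum(keep) < 3) stop("fit window must contain at least 3 lags")
  t <- c$lag_ps[keep]; y <- c$c[keep]
  if (max(y) - min(y) < 1e-9) {
    return(structure(list(s2 = max(0, min(1, mean(y))), tau_e = NA_real_,
                          window = window, rms = 0,
                          tau_e_identifiable = FALSE),
                     class = "lipari_szabo_fit"))
  }
  s2_0 <- max(0, min(1, mean(utils::tail(y, max(3, length(y) %/% 5)))))
  # initial tau from the first crossing of the mid-amplitude
  mid <- s2_0 + (y[1] - s2_0) * exp(-1)
  i <- which(y < mid)[1]
  tau_0 <- if (is.na(i)) max(t) / 3 else max(t[i], c$dt)
  dat <- data.frame(t = t, y = y)
  fit <- minpack.lm::nlsLM(
    y ~ s2 + (1 - s2) * exp(-t / tau),
    data = dat, start = list(s2 = s2_0, tau = tau_0),
    lower = c(0, 1e-6), upper = c(1, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  structure(list(s2 = unname(cf["s2"]), tau_e = unname(cf["tau"]),
                 window = window,
                 rms = sqrt(mean(stats::residuals(fit)^2)),
                 tau_e_identifiable = TRUE),
            class = "lipari_szabo_fit")
}

#' @export
print.lipari_szabo_fit <- function(x, ...) {
  cat(sprintf("Lipari-Szabo fit: S2 = %.4f, tau_e = %s ps (rms %.2e)\n",
              x$s2, ifelse(x$tau_e_identifiable, sprintf("%.3f", x$tau_e),
                           "unidentifiable"), x$rms))
  invisible(x)
}

#' @export
coef.lipari_szabo_fit <- function(object, ...) {
  c(s2 = object$s2, tau_e = object$tau_e)
}

# hysteresis two-state assignment of a dihedral series.
# rule: endo core chi <= -core, exo core chi >= +core; frames in the band
# inherit the last assigned state (leading band frames inherit the first
# assigned state).  Returns integer vector: 1 = endo, 2 = exo, per frame.
assign_states <- function(series, core = 10) {
  raw <- ifelse(series <= -core, 1L, ifelse(series >= core, 2L, NA_integer_))
  if (all(is.na(raw))) stop("no frame reaches either core region")
  # carry last observation forward, then backfill the head
  pos <- which(!is.na(raw))
  take <- findInterval(seq_along(raw), pos)
  take[take == 0L] <- 1L
  raw[pos[take]]
}

#' Torsional transition count with hysteresis
#'
#' Assigns frames to the two pucker states from the sign of the dihedral with
#' hysteresis (no state change is registered until the opposite core region,
#' `|chi| >= core`, is entered), then counts state changes per nanosecond.
#' The hysteresis suppresses chatter from within-state libration.
#'
#' @param series dihedral angle time series, degrees.
#' @param dt frame spacing of `series`, ps.
#' @param core half-width of the hysteresis core, degrees (default 10).
#' @param stride counting stride, ps: frames are subsampled to this spacing
#'   before counting (default 1 ps).
#' @return list with `rate_per_ns`, `n_transitions`, `duration_ns`.
#' @export
transition_count <- function(series, dt, core = 10, stride = 1) {
  stopifnot(dt > 0, stride >= dt)
  step <- max(1L, round(stride / dt))
  sub <- series[seq(1, length(series), by = step)]
  if (length(sub) < 2) stop("series shorter than the counting stride")
  st <- assign_states(sub, core)
  n_tr <- sum(diff(st) != 0)
  dur_ns <- (length(sub) - 1) * step * dt / 1000
  list(rate_per_ns = n_tr / dur_ns, n_transitions = n_tr,
       duration_ns = dur_ns)
}

#' Endo-state population of a dihedral series
#'
#' Fraction of frames assigned to the endo state (chi <= -core, with
#' hysteresis-band frames inheriting the last state).
#'
#' @param series dihedral angle time series, degrees.
#' @param core hysteresis half-width, degrees.
#' @return x_endo in \[0, 1\].
#' @export
state_populations <- function(series, core = 10) {
  st <- assign_states(series, core)
  mean(st == 1L)
}

#' Remove overall rotational/translational motion from a trajectory
#'
#' Superposes every frame onto a reference frame over a set of anchor atoms
#' (by default the midpoint frame of the trajectory, anchored on four bonded
#' backbone atoms), leaving only internal motion in the anchored frame of
#' reference.
#'
#' @param frames list of n_atoms x 3 coordinate matrices, one per frame.
#' @param anchor integer indices of the anchor atoms (>= 3, non-collinear).
#' @param reference index of the reference frame (default: midpoint).
#' @return list with `frames` (transformed trajectory) and `anchor_rmsd`
#'   (per-frame rmsd over the anchor atoms after superposition, Angstrom).
#' @export
remove_overall_motion <- function(frames, anchor,
                                  reference = ceiling(length(frames) / 2)) {
  stopifnot(length(frames) >= 1, length(anchor) >= 3)
  ref <- as.matrix(frames[[reference]])
  out <- vector("list", length(frames))
  rmsd <- numeric(length(frames))
  for (i in seq_along(frames)) {
    tf <- superpose_fragment(as.matrix(frames[[i]]), ref, indices = anchor)
    out[[i]] <- apply_transform(tf, as.matrix(frames[[i]]))
    rmsd[i] <- tf$rmsd
  }
  list(frames = out, anchor_rmsd = rmsd, reference = reference)
}
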