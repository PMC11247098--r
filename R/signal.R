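#' Enumerate the Raman-active term structure
#'
#' Internal table of the triple sum over (e, e', e'') that builds every
#' signal: the monitored density-matrix element (e, e'), the intermediate
#' state e'', the polarizability weight `alpha[e', e''] * alpha[e'', e]`,
#' the intermediate coherence frequency `w_eppep = E(e'') - E(e')` (eV),
#' its dephasing rate (fs^-1), and the monitored element's frequency
#' `w_eep = E(e) - E(e')` (eV). Terms with zero weight are dropped.
#'
#' @param basis an [diagonalize()] result.
#' @param dephasing matrix of coherence decay rates (fs^-1), e.g. from
#'   [dephasing_rates()]; NULL means all zero.
#' @param alpha polarizability matrix over exciton labels; default ones
#'   off the diagonal.
#' @return data.frame with columns `e`, `ep`, `epp`, `w`, `om_eppep`,
#'   `om_eep`, `gam`.
#' @keywords internal
raman_terms <- function(basis, dephasing = NULL, alpha = NULL) {
  n <- basis$n
  if (is.null(alpha)) {
    alpha <- matrix(1, n, n); diag(alpha) <- 0
  }
  if (is.null(dephasing)) dephasing <- matrix(0, n, n)
  ev <- basis$eigenvalues
  out <- expand.grid(e = seq_len(n), ep = seq_len(n), epp = seq_len(n))
  out$w <- complex(real = 0)
  for (r in seq_len(nrow(out))) {
    out$w[r] <- alpha[out$ep[r], out$epp[r]] * alpha[out$epp[r], out$e[r]]
  }
  out$om_eppep <- ev[out$epp] - ev[out$ep]
  out$om_eep <- ev[out$e] - ev[out$ep]
  out$gam <- dephasing[cbind(out$epp, out$ep)]
  out[Mod(out$w) > 0, , drop = FALSE]
}

#' Table of Raman resonance positions and widths
#'
#' Enumerates the spectral-line positions of the entangled signal: each
#' term (e, e', e'') produces a Lorentzian at
#' `omega_minus = -(E(e'') - E(e')) + (E(e) - E(e'))/2` on the primary
#' (parametric) branch -- so an exciton population `e` yields lines at its
#' signed gaps `E(e) - E(e'')` -- plus the mirrored branch at the negated
#' position contributed by the `s <-> i` exchange term. Widths are
#' `sigma0 + hbar * gamma_e''e'` (HWHM, eV).
#'
#' @param basis an [diagonalize()] result.
#' @param sigma0 pump bandwidth (eV).
#' @param dephasing coherence decay-rate matrix (fs^-1) or NULL.
#' @param alpha polarizability over exciton labels (default: all pairs).
#' @param drop_zero_weight drop lines whose polarizability weight
#'   vanishes (default FALSE so degenerate/bare systems still list their
#'   formal entries).
#' @return Tibble with columns `e`, `ep`, `epp`, `branch`, `position`
#'   (eV), `width` (eV, HWHM), `weight`.
#' @export
resonance_table <- function(basis, sigma0 = 0.001, dephasing = NULL,
                            alpha = NULL, drop_zero_weight = FALSE) {
  n <- basis$n
  if (is.null(alpha)) {
    alpha <- matrix(1, n, n); diag(alpha) <- 0
  }
  if (is.null(dephasing)) dephasing <- matrix(0, n, n)
  ev <- basis$eigenvalues
  g <- expand.grid(e = seq_len(n), ep = seq_len(n), epp = seq_len(n))
  w <- alpha[cbind(g$ep, g$epp)] * alpha[cbind(g$epp, g$e)]
  pos <- -(ev[g$epp] - ev[g$ep]) + (ev[g$e] - ev[g$ep]) / 2
  wid <- sigma0 + hbar_ev_fs * dephasing[cbind(g$epp, g$ep)]
  tb <- tibble::tibble(
    e = rep(g$e, 2), ep = rep(g$ep, 2), epp = rep(g$epp, 2),
    branch = rep(c("parametric", "exchange"), each = nrow(g)),
    position = c(pos, -pos),
    width = rep(wid, 2),
    weight = rep(Mod(w), 2)
  )
  if (drop_zero_weight) tb <- tb[tb$weight > 0, , drop = FALSE]
  tb[order(tb$position), , drop = FALSE]
}

#' Bundle a signal computation request
#'
#' Validates and stores everything a signal method needs: the photon
#' state, the density-matrix trajectory, the exciton basis, the
#' dephasing-rate matrix, the polarizability, the Raman-shift and arrival
#' time axes, and the optical delay.
#'
#' @param photon a [twin_photon_spec()].
#' @param trajectory a [propagate()] / [density_trajectory()] result.
#' @param basis an [diagonalize()] result.
#' @param omega_minus strictly increasing Raman-shift axis (eV).
#' @param T_axis strictly increasing arrival-time axis (fs), `Ts` values.
#' @param deltaT optical delay `Ti - Ts` (fs), default 0.
#' @param method one of `"double_time"` (direct double-time quadrature),
#'   `"narrowband"` (narrowband analytic form), `"population"`
#'   (population-only Lorentzian limit), `"classical"` (classical or
#'   uncorrelated light).
#' @param bath optional [bath_spec()] used to derive [dephasing_rates()].
#' @param dephasing optional explicit coherence decay matrix (fs^-1);
#'   overrides `bath`.
#' @param alpha optional polarizability matrix over exciton labels.
#' @param include_exchange include the mirrored `s <-> i` branch
#'   (default FALSE: the primary parametric branch, whose resonance signs
#'   carry the population assignments; see the methods vignette).
#' @return Object of class `signal_request`.
#' @export
signal_request <- function(photon, trajectory, basis, omega_minus, T_axis,
                           deltaT = 0,
                           method = c("narrowband", "double_time",
                                      "population", "classical"),
                           bath = NULL, dephasing = NULL, alpha = NULL,
                           include_exchange = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(photon, "twin_photon_spec"),
            inherits(trajectory, "density_trajectory"),
            inherits(basis, "exciton_basis"))
  if (any(diff(omega_minus) <= 0)) stop("omega_minus axis must be strictly increasing")
  if (any(diff(T_axis) < 0)) stop("T_axis must be non-decreasing")
  if (method %in% c("double_time", "narrowband", "population") &&
      photon$kind != "entangled") {
    stop("methods double_time/narrowband/population require entangled photons")
  }
  if (method == "classical" && !photon$kind %in% c("classical", "uncorrelated")) {
    stop("classical requires classical or uncorrelated light")
  }
  if (method == "population" && deltaT != 0) {
    stop("population is defined at deltaT = 0")
  }
  if (is.null(dephasing) && !is.null(bath)) dephasing <- dephasing_rates(basis, bath)
  structure(
    list(photon = photon, trajectory = trajectory, basis = basis,
         omega_minus = as.numeric(omega_minus), T_axis = as.numeric(T_axis),
         deltaT = deltaT, method = method, dephasing = dephasing,
         alpha = alpha, include_exchange = include_exchange),
    class = "signal_request"
  )
}

new_signal_grid <- function(omega_minus, T_axis, values, method, normalized,
                            provenance = list()) {
  structure(
    list(omega_minus = omega_minus, T = T_axis, values = values,
         method = method, normalized = normalized, provenance = provenance),
    class = "signal_grid"
  )
}

#' @export
print.signal_grid <- function(x, ...) {
  cat("<signal_grid> ", length(x$omega_minus), " shifts x ", length(x$T),
      " times, method=", x$method,
      if (x$normalized) ", normalized" else "", "\n", sep = "")
  invisible(x)
}

normalize_grid <- function(values, normalize) {
  if (!normalize) return(values)
  m <- max(abs(values))
  if (m > 0) values / m else values
}

# trajectory elements resampled to a half-step grid starting at t0
traj_half_grid <- function(traj, h) {
  t0 <- traj$times[1]
  t1 <- traj$times[length(traj$times)]
  tq <- seq(t0, t1, by = h / 2)
  n <- traj$n
  q <- vector("list", n * n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      y <- vapply(traj$states, function(s) s[a, b], complex(1))
      qre <- approx(traj$times, Re(y), xout = tq, rule = 2)$y
      qim <- approx(traj$times, Im(y), xout = tq, rule = 2)$y
      q[[(a - 1) * n + b]] <- complex(real = qre, imaginary = qim)
    }
  }
  list(tq = tq, q = q, t0 = t0, t1 = t1)
}

traj_element_fun <- function(traj, a, b) {
  y <- vapply(traj$states, function(s) s[a, b], complex(1))
  fre <- approxfun(traj$times, Re(y), rule = 2)
  fim <- approxfun(traj$times, Im(y), rule = 2)
  function(t) {
    out <- complex(real = fre(t), imaginary = fim(t))
    out[t < traj$times[1] | t > traj$times[length(traj$times)]] <- 0
    out
  }
}

# gate-window integral: int rho_ab(t) W((2t - 2Tc - tau0)/tau0) dt
# W(x) = e^{-2x} theta(x) e^{-2(x + dT/tau0)} theta(x + dT/tau0)
gate_window_integral <- function(traj, a, b, Tc, tau0, dT) {
  tmin <- Tc + tau0 / 2 + max(0, -dT) / 2
  tmax <- tmin + 3 * tau0
  tt <- seq(tmin, tmax, by = min(tau0 / 100, 0.25))
  x <- (2 * tt - 2 * Tc - tau0) / tau0
  wv <- exp(-2 * x) * exp(-2 * (x + dT / tau0))
  f <- traj_element_fun(traj, a, b)
  y <- f(tt) * wv
  ht <- tt[2] - tt[1]
  sum(y) * ht - (y[1] + y[length(y)]) * ht / 2
}

# core of the analytic narrowband signal: complex S(omega_minus) for one
# (Ts, Ti) pair, primary branch. Exchange branch = same core with
# omega_minus negated and Ts <-> Ti.
narrowband_core <- function(req, omv, Ts, Ti) {
  ph <- req$photon
  terms <- raman_terms(req$basis, req$dephasing, req$alpha)
  tau0 <- ph$tau0; s0 <- ph$sigma0
  dT <- Ti - Ts
  varpi <- ph$omega_plus + omv
  pref <- exp(-0.5i * varpi * dT / hbar_ev_fs) / (2 * pi * tau0)^2
  acc <- complex(length(omv))
  for (r in seq_len(nrow(terms))) {
    Wint <- gate_window_integral(req$trajectory, terms$e[r], terms$ep[r],
                                Ti, tau0, dT)
    L <- 1 / (terms$gam[r] * hbar_ev_fs + s0 +
                1i * (terms$om_eppep[r] + omv - terms$om_eep[r] / 2))
    acc <- acc + terms$w[r] * L * Wint
  }
  pref * acc
}

#' Entangled Raman signal: analytic narrowband form
#'
#' Evaluates the closed-form narrowband signal: for each term
#' (e, e', e'') a complex Lorentzian of HWHM `sigma0 + hbar gamma_e''e'`
#' centred at `omega_minus = -(E(e'')-E(e')) + (E(e)-E(e'))/2`, weighted
#' by the time-gated window integral of the monitored density-matrix
#' element around `Ti` (gate width `tau0`), with the Hong-Ou-Mandel
#' delay entering through the overlap window and the beat prefactor
#' `exp(-i (omega_plus + omega_minus) DeltaT / (2 hbar))`.
#'
#' @param req a [signal_request()] with `method = "narrowband"`.
#' @param normalize scale the grid to `max |S| = 1` (default TRUE).
#' @return A `signal_grid`.
#' @export
signal_narrowband <- function(req, normalize = TRUE) {
  stopifnot(inherits(req, "signal_request"))
  omv <- req$omega_minus
  Ts <- req$T_axis
  vals <- matrix(0, length(omv), length(Ts))
  for (k in seq_along(Ts)) {
    s <- Re(narrowband_core(req, omv, Ts[k], Ts[k] + req$deltaT))
    if (req$include_exchange) {
      s <- s + Re(narrowband_core(req, -omv, Ts[k] + req$deltaT, Ts[k]))
    }
    vals[, k] <- s
  }
  new_signal_grid(omv, Ts, normalize_grid(vals, normalize), "narrowband",
                  normalize,
                  list(deltaT = req$deltaT, kind = req$photon$kind,
                       include_exchange = req$include_exchange))
}

#' Entangled Raman signal: population-only Lorentzian limit
#'
#' At zero optical delay and for population dynamics only, the signal
#' reduces to a sum of Lorentzians at the signed exciton gaps
#' `omega_minus = E(e) - E(e'')` with HWHM `sigma0 + hbar gamma`, each
#' weighted by the population gated through the window
#' `|phi_tilde((2t - 2Ts - tau0)/tau0)|^2` (so `Ts <= t <= Ts + tau0`).
#'
#' @param req a [signal_request()] with `method = "population"`.
#' @param normalize scale to unit maximum (default TRUE).
#' @return A `signal_grid`.
#' @export
signal_population <- function(req, normalize = TRUE) {
  stopifnot(inherits(req, "signal_request"))
  if (req$deltaT != 0) stop("population is defined at deltaT = 0")
  omv <- req$omega_minus
  Ts <- req$T_axis
  terms <- raman_terms(req$basis, req$dephasing, req$alpha)
  terms <- terms[terms$e == terms$ep, , drop = FALSE]
  tau0 <- req$photon$tau0; s0 <- req$photon$sigma0
  vals <- matrix(0, length(omv), length(Ts))
  for (k in seq_along(Ts)) {
    acc <- numeric(length(omv))
    for (r in seq_len(nrow(terms))) {
      wdt <- s0 + hbar_ev_fs * terms$gam[r]
      lor <- wdt / ((omv - (-terms$om_eppep[r]))^2 + wdt^2)
      Wint <- Re(gate_window_integral(req$trajectory, terms$e[r], terms$ep[r],
                                     Ts[k], tau0, 0))
      acc <- acc + Mod(terms$w[r]) * lor * Wint
    }
    vals[, k] <- acc / (2 * pi * tau0)^2
  }
  new_signal_grid(omv, Ts, normalize_grid(vals, normalize), "population",
                  normalize, list(kind = req$photon$kind))
}

# numeric double-time integral, primary branch, deltaT = 0.
# Coordinates u = t - tau >= 0, v = t + tau; for each term the u integral
# is an exponential-kernel convolution of the trajectory element,
# evaluated exactly by a one-step recurrence, and the v integral applies
# the tau0 gate window around each arrival time.
double_time_engine <- function(req, omv_signed) {
  traj <- req$trajectory
  ph <- req$photon
  tau0 <- ph$tau0; s0 <- ph$sigma0
  terms <- raman_terms(req$basis, req$dephasing, req$alpha)
  tt <- traj$times
  h <- tt[2] - tt[1]
  t0 <- tt[1]
  Tmax <- max(req$T_axis)
  vmax <- 2 * Tmax + tau0 + 4 * tau0
  if (2 * tt[length(tt)] < vmax) {
    stop("trajectory window shorter than integration support: need times up to ",
         format(vmax / 2), " fs")
  }
  half <- traj_half_grid(traj, h)
  J <- floor((vmax - 2 * t0) / h)
  vgrid <- 2 * t0 + h * (0:J)
  n <- req$basis$n
  # gate window F_T(v) for every T (columns)
  Fmat <- matrix(0, J + 1, length(req$T_axis))
  for (k in seq_along(req$T_axis)) {
    Tk <- req$T_axis[k]
    x <- (vgrid - 2 * Tk - tau0) / tau0
    Fmat[, k] <- ifelse(x >= 0 & x <= 4, exp(-2 * x), 0)
  }
  Smat <- matrix(0, length(omv_signed), length(req$T_axis))
  for (r in seq_len(nrow(terms))) {
    q <- half$q[[(terms$e[r] - 1) * n + terms$ep[r]]]
    z <- terms$gam[r] + s0 / hbar_ev_fs +
      1i * (terms$om_eppep[r] + omv_signed) / hbar_ev_fs
    ez <- exp(-z * h)
    Cmat <- matrix(0 + 0i, J + 1, length(omv_signed))
    Cv <- complex(length(omv_signed))
    for (j in seq_len(J)) {
      # C(v_{j+1}) = e^{-z h} C(v_j) + (h/2) (e^{-z h} q(v_j/2) + q(v_{j+1}/2))
      Cv <- ez * Cv + (h / 2) * (ez * q[j] + q[j + 1])
      Cmat[j + 1, ] <- Cv
    }
    contrib <- t(Cmat) %*% Fmat * (h / 2)
    Smat <- Smat + Re(terms$w[r] * contrib)
  }
  Smat
}

#' Entangled Raman signal: direct double-time quadrature
#'
#' Integrates the double-time expression for the entangled signal
#' directly: the intermediate-coherence phase factor
#' `exp(-i (w_e''e' - i hbar gamma)(t - tau)/hbar)` against the
#' time-ordered (`t >= tau`) product of twin-photon wavepackets, with the
#' trajectory element `rho_ee'(tau)` under the integral (no narrowband
#' approximation: the finite memory `1/(sigma0/hbar + gamma)` of the
#' Raman coherence is kept exactly). Restricted to zero optical delay;
#' delay scans go through [signal_narrowband()].
#'
#' The trajectory must extend `2.5 tau0` beyond the last arrival time;
#' for stationary-state checks supply a trajectory starting at negative
#' times so the Raman coherence integral is fully accumulated.
#'
#' @param req a [signal_request()] with `method = "double_time"`.
#' @param normalize scale to unit maximum (default TRUE).
#' @param richardson if TRUE, repeat at double step and warn when the
#'   normalized spectra deviate by more than 2% (quadrature check).
#' @return A `signal_grid` (attribute `converged` when `richardson`).
#' @export
signal_double_time <- function(req, normalize = TRUE, richardson = FALSE) {
  stopifnot(inherits(req, "signal_request"))
  if (req$deltaT != 0) {
    stop("double_time supports deltaT = 0 only; use narrowband for delay scans")
  }
  vals <- double_time_engine(req, req$omega_minus)
  if (req$include_exchange) {
    vals <- vals + double_time_engine(req, -req$omega_minus)
  }
  out <- new_signal_grid(req$omega_minus, req$T_axis,
                         normalize_grid(vals, normalize), "double_time",
                         normalize, list(kind = req$photon$kind,
                                         include_exchange = req$include_exchange))
  if (richardson) {
    traj2 <- req$trajectory
    keep <- seq(1, length(traj2$times), by = 2)
    traj2 <- density_trajectory(traj2$times[keep], traj2$states[keep])
    req2 <- req; req2$trajectory <- traj2
    v2 <- double_time_engine(req2, req$omega_minus)
    if (req$include_exchange) v2 <- v2 + double_time_engine(req2, -req$omega_minus)
    dev <- max(abs(normalize_grid(v2, TRUE) - normalize_grid(vals, TRUE)))
    attr(out, "converged") <- dev <= 0.02
    if (dev > 0.02) {
      warning("quadrature not converged: step-halving deviation ", format(dev))
    }
  }
  out
}

# classical / uncorrelated engine at the (t, tau) grid level with
# anti-diagonal reduction over u = t - tau.
classical_engine <- function(req, Tk) {
  ph <- req$photon
  traj <- req$trajectory
  terms <- raman_terms(req$basis, req$dephasing, req$alpha)
  st <- ph$sigma_tilde
  hb <- hbar_ev_fs
  Ts <- Tk; Ti <- Tk + req$deltaT
  h <- 0.25
  if (ph$kind == "classical") {
    lo <- max(Ts, Ti)
    hi <- lo + 6 * hb / st
  } else {
    lo <- max(traj$times[1], Tk - 4 * hb / st)
    hi <- Tk + 4 * hb / st
  }
  tg <- seq(lo, hi, by = h)
  nt <- length(tg)
  U <- outer(tg, tg, "-") # t - tau
  mask <- U >= 0
  # molecular part
  M <- matrix(0 + 0i, nt, nt)
  n <- req$basis$n
  qfun <- list()
  for (r in seq_len(nrow(terms))) {
    key <- paste(terms$e[r], terms$ep[r])
    if (is.null(qfun[[key]])) {
      qfun[[key]] <- traj_element_fun(traj, terms$e[r], terms$ep[r])
    }
    qrow <- qfun[[key]](tg) # over tau
    GI <- exp((-1i * terms$om_eppep[r] / hb - terms$gam[r]) * U)
    M <- M + terms$w[r] * GI * matrix(qrow, nt, nt, byrow = TRUE)
    if (ph$kind == "classical") {
      # dissipative pathway survives for classical light
      ev <- req$basis$eigenvalues
      om2 <- ev[terms$epp[r]] - ev[terms$e[r]]
      gam2 <- if (is.null(req$dephasing)) 0 else req$dephasing[terms$epp[r], terms$e[r]]
      GII <- exp((1i * om2 / hb - gam2) * U)
      M <- M - terms$w[r] * GII * matrix(qrow, nt, nt, byrow = TRUE)
    }
  }
  M[!mask] <- 0
  # field envelopes (omega_minus-independent)
  if (ph$kind == "classical") {
    envt <- exp(-st * ((tg - Ts) + (tg - Ti)) / hb) * (tg >= lo)
    env <- outer(envt, envt) # product of t and tau one-sided envelopes
  } else {
    if (req$deltaT != 0) stop("uncorrelated signal supports deltaT = 0 only")
    envt <- exp(-2 * st * abs(tg - Tk) / hb)
    env <- outer(envt, envt)
  }
  B <- M * env
  # anti-diagonal sums over u = t - tau >= 0
  uidx <- row(B) - col(B)
  keep <- uidx >= 0
  dre <- rowsum(Re(B[keep]), uidx[keep]) # sums for u = 0, h, 2h, ...
  dim_ <- rowsum(Im(B[keep]), uidx[keep])
  uvals <- as.numeric(rownames(dre)) * h
  list(d = complex(real = as.vector(dre), imaginary = as.vector(dim_)),
       u = uvals, h = h)
}

#' Raman signal for classical or uncorrelated light
#'
#' Classical pulses: the six-point correlators reduce to products of four
#' c-number fields; both the parametric and the dissipative pathways
#' survive and enter with opposite signs, producing an exactly
#' Stokes/anti-Stokes symmetric spectrum. Uncorrelated photon pairs: the
#' factorised two-photon wavepacket is pushed through the same
#' double-time machinery (the dissipative pathway still cancels for a
#' one-photon-per-arm state); the broad single-photon bandwidth
#' `hbar/(2 tau0)` blurs the spectral lines.
#'
#' @param req a [signal_request()] with `method = "classical"`.
#' @param normalize scale to unit maximum (default TRUE).
#' @return A `signal_grid`.
#' @export
signal_classical <- function(req, normalize = TRUE) {
  stopifnot(inherits(req, "signal_request"))
  if (!req$photon$kind %in% c("classical", "uncorrelated")) {
    stop("classical requires classical or uncorrelated light")
  }
  omv <- req$omega_minus
  vals <- matrix(0, length(omv), length(req$T_axis))
  for (k in seq_along(req$T_axis)) {
    eng <- classical_engine(req, req$T_axis[k])
    ph1 <- exp(outer(1i * omv / hbar_ev_fs, eng$u)) # e^{+i w- u / hbar}
    tot <- (ph1 %*% eng$d + Conj(ph1) %*% eng$d) * eng$h^2
    # classical fields leave the commutator (response) structure, whose
    # product with the real field factor lives in the imaginary part;
    # for uncorrelated photon pairs the quantum detection phases keep the
    # observable in the real part
    vals[, k] <- if (req$photon$kind == "classical") Im(tot) else Re(tot)
  }
  new_signal_grid(omv, req$T_axis, normalize_grid(vals, normalize),
                  "classical", normalize, list(kind = req$photon$kind))
}

#' Dispatch a signal request
#'
#' @param req a [signal_request()].
#' @param ... passed to the method implementations.
#' @return A `signal_grid`.
#' @export
raman_signal <- function(req, ...) {
  switch(req$method,
    narrowband = signal_narrowband(req, ...),
    double_time = signal_double_time(req, ...),
    population = signal_population(req, ...),
    classical = signal_classical(req, ...)
  )
}

#' Hong-Ou-Mandel delay scan
#'
#' Sweeps the optical delay `DeltaT = Ti - Ts` at a fixed Raman shift and
#' arrival time through the analytic narrowband signal. The returned scan
#' carries both the observable `Re S` (which beats at
#' `|omega_plus + omega_minus| / 2` through the delay prefactor) and the
#' complex modulus envelope, which for frozen populations decays as
#' `exp(-2 |DeltaT| / tau0)` -- the decay of the destructive two-photon
#' interference once the photons no longer overlap. A nonzero residue
#' remains at `DeltaT = 0`.
#'
#' @param req a [signal_request()] (entangled; its `omega_minus` and
#'   `T_axis` must be single values: the fixed shift and arrival time).
#' @param deltaT_axis delays to scan (fs).
#' @return Object of class `hom_scan`: tibble-backed with columns
#'   `deltaT`, `value`, `envelope`.
#' @export
hom_scan <- function(req, deltaT_axis) {
  stopifnot(inherits(req, "signal_request"))
  if (length(req$omega_minus) != 1 || length(req$T_axis) != 1) {
    stop("hom_scan needs a single fixed omega_minus and T")
  }
  vals <- numeric(length(deltaT_axis))
  env <- numeric(length(deltaT_axis))
  for (k in seq_along(deltaT_axis)) {
    dT <- deltaT_axis[k]
    s <- narrowband_core(req, req$omega_minus, req$T_axis, req$T_axis + dT)
    if (req$include_exchange) {
      s2 <- narrowband_core(req, -req$omega_minus, req$T_axis + dT, req$T_axis)
      vals[k] <- Re(s) + Re(s2)
      env[k] <- Mod(s) + Mod(s2)
    } else {
      vals[k] <- Re(s)
      env[k] <- Mod(s)
    }
  }
  structure(
    list(deltaT = as.numeric(deltaT_axis), values = vals, envelope = env,
         fixed_omega_minus = req$omega_minus, fixed_T = req$T_axis),
    class = "hom_scan"
  )
}

#' @export
print.hom_scan <- function(x, ...) {
  cat("<hom_scan> ", length(x$deltaT), " delays at omega_-=",
      format(x$fixed_omega_minus), " eV, T=", format(x$fixed_T), " fs\n",
      sep = "")
  invisible(x)
}

#' Dominant beat frequency of a HOM scan
#'
#' FFT argmax of the mean-removed scan, returned in eV
#' (`2 pi hbar / period`).
#'
#' @param scan a [hom_scan()] result.
#' @return List with `frequency` (eV) and `bin_width` (eV).
#' @export
hom_beat_frequency <- function(scan) {
  y <- scan$values - mean(scan$values)
  n <- length(y)
  dT <- scan$deltaT[2] - scan$deltaT[1]
  sp <- Mod(fft(y))[seq_len(floor(n / 2))]
  k <- which.max(sp[-1]) # skip DC
  freq_fs <- k / (n * dT) # cycles per fs
  list(frequency = 2 * pi * hbar_ev_fs * freq_fs,
       bin_width = 2 * pi * hbar_ev_fs / (n * dT))
}

#' Fit a Lorentzian to an isolated spectral line
#'
#' Least-squares fit of `a * w^2 / ((x - x0)^2 + w^2) + b` started from
#' moment estimates; used to verify line positions and HWHM.
#'
#' @param x axis values (eV).
#' @param y signal values.
#' @return List with `center`, `hwhm`, `amplitude`, `offset`.
#' @export
fit_lorentzian <- function(x, y) {
  i0 <- which.max(y)
  x0 <- x[i0]; a0 <- max(y) - min(y); b0 <- min(y)
  half <- b0 + a0 / 2
  above <- which(y >= half)
  w0 <- max(diff(range(x[above])) / 2, diff(x)[1])
  obj <- function(p) {
    sum((p[3] * p[2]^2 / ((x - p[1])^2 + p[2]^2) + p[4] - y)^2)
  }
  fit <- optim(c(x0, w0, a0, b0), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  list(center = fit$par[1], hwhm = abs(fit$par[2]),
       amplitude = fit$par[3], offset = fit$par[4])
}

#' Local maxima of a spectrum slice
#'
#' @param x axis, `y` values.
#' @param y signal values.
#' @param frac discard maxima below `frac * max(y)`.
#' @return Numeric vector of `x` positions of interior local maxima.
#' @export
find_peaks <- function(x, y, frac = 0.02) {
  n <- length(y)
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1
  idx <- idx[y[idx] >= frac * max(y)]
  x[idx]
}
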