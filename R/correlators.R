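#' Discretised two-photon state on a frequency grid
#'
#' Represents the twin-photon state on discrete frequency bins per arm,
#' for the brute-force Fock-space evaluation of the six-point field
#' correlators. The amplitude matrix is `Phi(w_s, w_i) sqrt(dws dwi)`
#' normalised to unit total probability. The Fock space is truncated at
#' total photon number 2, which is exact for two-photon inputs.
#'
#' @param x a [joint_amplitude()], or a complex matrix of amplitudes with
#'   `length(grid_s)` rows and `length(grid_i)` columns.
#' @param grid_s,grid_i uniform frequency bins (eV) for the s and i arms;
#'   when `x` is a joint amplitude they default to `n_bins` bins spanning
#'   `span` half-widths of `max(sigma0, hbar/tau0)` around the central
#'   frequencies.
#' @param n_bins bins per arm used for the default grids (<= 64).
#' @param span half-range of the default grids in units of the larger
#'   bandwidth scale (default 6).
#' @return Object of class `fock_grid_state`.
#' @export
fock_grid_state <- function(x, grid_s = NULL, grid_i = NULL, n_bins = 12,
                            span = 6) {
  if (inherits(x, "joint_amplitude")) {
    sp <- x$spec
    if (is.null(grid_s) || is.null(grid_i)) {
      bw <- max(sp$sigma0, hbar_ev_fs / sp$tau0)
      ws0 <- (sp$omega_plus + sp$omega_minus) / 2
      wi0 <- (sp$omega_plus - sp$omega_minus) / 2
      grid_s <- seq(ws0 - span * bw, ws0 + span * bw, length.out = n_bins)
      grid_i <- seq(wi0 - span * bw, wi0 + span * bw, length.out = n_bins)
    }
    amp <- outer(grid_s, grid_i, x$freq)
  } else {
    amp <- as.matrix(x)
    if (is.null(grid_s) || is.null(grid_i)) stop("grids required with a raw amplitude matrix")
    if (nrow(amp) != length(grid_s) || ncol(amp) != length(grid_i)) {
      stop("amplitude matrix does not match the grids")
    }
  }
  ns <- length(grid_s); ni <- length(grid_i)
  if (ns > 64 || ni > 64) {
    stop("resource error: at most 64 bins per arm for the Fock oracle")
  }
  dws <- if (ns > 1) grid_s[2] - grid_s[1] else 1
  dwi <- if (ni > 1) grid_i[2] - grid_i[1] else 1
  amp <- amp * sqrt(dws * dwi)
  nrm <- sqrt(sum(Mod(amp)^2))
  if (nrm == 0) stop("zero amplitude")
  amp <- amp / nrm
  structure(
    list(grid_s = grid_s, grid_i = grid_i, dws = dws, dwi = dwi,
         amplitude = amp, ns = ns, ni = ni),
    class = "fock_grid_state"
  )
}

#' @export
print.fock_grid_state <- function(x, ...) {
  cat("<fock_grid_state> ", x$ns, " x ", x$ni, " bins\n", sep = "")
  invisible(x)
}

# ---- truncated Fock machinery (total photon number <= 2) -------------------
# modes: 1..ns are s-arm bins, ns+1..ns+ni are i-arm bins.
# basis: 1 = vacuum; 1+m = one photon in mode m; pairs (m <= mp) follow.

fock_space <- function(ns, ni) {
  M <- ns + ni
  pair_index <- matrix(NA_integer_, M, M)
  idx <- 1 + M
  for (m in seq_len(M)) {
    for (mp in m:M) {
      idx <- idx + 1
      pair_index[m, mp] <- idx
      pair_index[mp, m] <- idx
    }
  }
  list(ns = ns, ni = ni, M = M, D = idx, pair_index = pair_index)
}

# apply annihilation operator a_m to state vector psi
fock_annihilate <- function(fs, psi, m) {
  out <- complex(fs$D)
  out[1] <- psi[1 + m]
  for (mp in seq_len(fs$M)) {
    fac <- if (mp == m) sqrt(2) else 1
    out[1 + mp] <- out[1 + mp] + fac * psi[fs$pair_index[m, mp]]
  }
  out
}

# apply creation operator a^dagger_m (truncated: 2-photon states map to 0)
fock_create <- function(fs, psi, m) {
  out <- complex(fs$D)
  out[1 + m] <- psi[1]
  for (mp in seq_len(fs$M)) {
    fac <- if (mp == m) sqrt(2) else 1
    out[fs$pair_index[m, mp]] <- out[fs$pair_index[m, mp]] + fac * psi[1 + mp]
  }
  out
}

# time-domain field operator E_arm(t) = sum_k sqrt(dw) e^{-i w_k t/hbar} a_k
fock_E <- function(fs, st, psi, arm, t, dagger = FALSE) {
  if (arm == "s") {
    bins <- seq_len(st$ns); w <- st$grid_s; dw <- st$dws
  } else {
    bins <- st$ns + seq_len(st$ni); w <- st$grid_i; dw <- st$dwi
  }
  out <- complex(fs$D)
  for (k in seq_along(bins)) {
    ph <- exp(-1i * w[k] * t / hbar_ev_fs)
    if (dagger) {
      out <- out + sqrt(dw) * Conj(ph) * fock_create(fs, psi, bins[k])
    } else {
      out <- out + sqrt(dw) * ph * fock_annihilate(fs, psi, bins[k])
    }
  }
  out
}

fock_bin_of <- function(st, arm, omega) {
  g <- if (arm == "s") st$grid_s else st$grid_i
  which.min(abs(g - omega))
}

# frequency-domain density operator N_arm(omega') = a+k a_k / dw
fock_N <- function(fs, st, psi, arm, omega) {
  k <- fock_bin_of(st, arm, omega)
  m <- if (arm == "s") k else st$ns + k
  dw <- if (arm == "s") st$dws else st$dwi
  fock_create(fs, fock_annihilate(fs, psi, m), m) / dw
}

# frequency-domain creation operator Epsilon^dagger_arm(omega) = a+_k / sqrt(dw)
fock_Edag_freq <- function(fs, st, psi, arm, omega) {
  k <- fock_bin_of(st, arm, omega)
  m <- if (arm == "s") k else st$ns + k
  dw <- if (arm == "s") st$dws else st$dwi
  fock_create(fs, psi, m) / sqrt(dw)
}

fock_initial_psi <- function(fs, st) {
  psi <- complex(fs$D)
  for (k in seq_len(st$ns)) {
    for (l in seq_len(st$ni)) {
      psi[fs$pair_index[k, st$ns + l]] <- st$amplitude[k, l]
    }
  }
  psi
}

#' Six-point correlators by brute-force Fock algebra
#'
#' Applies the discretised operator strings of the parametric (I) and
#' dissipative (II) pathways literally to the two-photon state vector in
#' the truncated Fock space and takes inner products. This is the
#' independent verification engine for the analytic Wick contraction and
#' for the Hong-Ou-Mandel cancellation: for any state with exactly one
#' photon per arm, the pathway-II string annihilates the single s photon
#' before the s-arm number operator acts, so `C_II` vanishes.
#'
#' @param state a [fock_grid_state()].
#' @param times list or vector `(t, tau, Ts, Ti)` (fs).
#' @param frequencies vector `(omega, omega_prime)` (eV): detection
#'   frequency of the created photon and the narrowband counting
#'   frequency; snapped to the nearest grid bins.
#' @return List with complex `C_I`, `C_II` and the bare pathway
#'   amplitudes `F_I`, `F_II` (direct term, before the `s <-> i`
#'   exchange is added to `C_I`/`C_II`).
#' @export
correlators_fock <- function(state, times, frequencies) {
  stopifnot(inherits(state, "fock_grid_state"))
  tt <- as.numeric(times); names(tt) <- NULL
  t <- tt[1]; tau <- tt[2]; Ts <- tt[3]; Ti <- tt[4]
  om <- frequencies[1]; omp <- frequencies[2]
  fs <- fock_space(state$ns, state$ni)
  psi0 <- fock_initial_psi(fs, state)
  hb <- hbar_ev_fs

  one_orientation <- function(arm_s, arm_i, Ts., Ti.) {
    # pathway I: <Psi| N_s(w') Eps_i^+(w) E_s(t-Ts) E_s^+(tau-Ts) E_i(tau-Ti) |Psi>
    p <- fock_E(fs, state, psi0, arm_i, tau - Ti.)
    p <- fock_E(fs, state, p, arm_s, tau - Ts., dagger = TRUE)
    p <- fock_E(fs, state, p, arm_s, t - Ts.)
    p <- fock_Edag_freq(fs, state, p, arm_i, om)
    p <- fock_N(fs, state, p, arm_s, omp)
    FI <- sum(Conj(psi0) * p)
    # pathway II: <Psi| E_s^+(tau-Ts) E_i(tau-Ti) N_s(w') Eps_i^+(w) E_s(t-Ts) |Psi>
    q <- fock_E(fs, state, psi0, arm_s, t - Ts.)
    q <- fock_Edag_freq(fs, state, q, arm_i, om)
    q <- fock_N(fs, state, q, arm_s, omp)
    q <- fock_E(fs, state, q, arm_i, tau - Ti.)
    q <- fock_E(fs, state, q, arm_s, tau - Ts., dagger = TRUE)
    FII <- sum(Conj(psi0) * q)
    list(FI = FI, FII = FII, phase = exp(1i * om * (t - Ts.) / hb))
  }

  d <- one_orientation("s", "i", Ts, Ti)
  x <- one_orientation("i", "s", Ti, Ts) # s <-> i exchange
  list(
    C_I = d$phase * d$FI + x$phase * x$FI,
    C_II = d$phase * d$FII + x$phase * x$FII,
    F_I = d$FI, F_II = d$FII
  )
}

#' Six-point correlators by analytic two-photon contraction
#'
#' Wick-style contraction of the two-photon state through the pathway-I
#' operator string. The surviving contractions give products of the joint
#' amplitude and its time-domain wavepacket; the dissipative pathway-II
#' string gives exactly zero for any state with one photon per arm (the
#' Hong-Ou-Mandel cancellation), so `C_II = 0` identically.
#'
#' When `state` is supplied, the contraction is evaluated with the same
#' discretised amplitude the Fock oracle uses (discrete sums in place of
#' the frequency integrals, including the plane-wave background term), so
#' the two routes agree to numerical round-off. Without `state` the
#' continuum closed forms of [joint_amplitude()] are used and the
#' delta-like background is dropped (it produces no spectral lines).
#'
#' @param amp a [joint_amplitude()] from a two-photon state
#'   (`entangled` or `uncorrelated`).
#' @param times vector `(t, tau, Ts, Ti)` (fs).
#' @param frequencies vector `(omega, omega_prime)` (eV).
#' @param state optional [fock_grid_state()] for grid-matched evaluation.
#' @param include_background include the plane-wave (non-resonant)
#'   contraction term; only meaningful in grid-matched mode.
#' @return List with complex `C_I` and `C_II` (the latter exactly 0).
#' @export
correlators_analytic <- function(amp, times, frequencies, state = NULL,
                                 include_background = !is.null(state)) {
  if (inherits(amp, "twin_photon_spec") && amp$kind == "classical") {
    stop("classical light: use correlators_classical()")
  }
  stopifnot(inherits(amp, "joint_amplitude"))
  tt <- as.numeric(times)
  t <- tt[1]; tau <- tt[2]; Ts <- tt[3]; Ti <- tt[4]
  om <- frequencies[1]; omp <- frequencies[2]
  hb <- hbar_ev_fs

  if (!is.null(state)) {
    c_ <- state$amplitude
    ws <- state$grid_s; wi <- state$grid_i
    term <- function(t., tau., Ts., Ti., cmat, ws., wi.) {
      # direct orientation on (s-grid ws., i-grid wi.) with amplitude cmat
      kp <- which.min(abs(ws. - omp))
      lo <- which.min(abs(wi. - om))
      F2 <- as.vector(cmat %*% exp(-1i * wi. * (tau. - Ti.) / hb))
      Ct <- sum(exp(-1i * ws. * (t. - Ts.) / hb) * F2)
      bg <- if (include_background) {
        sum(exp(1i * ws. * ((tau. - Ts.) - (t. - Ts.)) / hb)) * F2[kp]
      } else 0
      FI <- Conj(cmat[kp, lo]) * (bg + Ct * exp(1i * ws.[kp] * (tau. - Ts.) / hb))
      exp(1i * om * (t. - Ts.) / hb) * FI
    }
    CI <- term(t, tau, Ts, Ti, c_, ws, wi) +
      term(t, tau, Ti, Ts, t(c_), wi, ws) # s <-> i exchange
    return(list(C_I = CI, C_II = 0 + 0i))
  }

  # continuum closed forms; 4pi^2 Phi_tilde is the double Fourier integral
  fourpi2 <- 4 * pi^2
  CI <- exp(1i * om * (t - Ts) / hb) * Conj(amp$freq(omp, om)) *
    exp(1i * omp * (tau - Ts) / hb) * fourpi2 * amp$time(t - Ts, tau - Ti) +
    exp(1i * om * (t - Ti) / hb) * Conj(amp$freq(om, omp)) *
    exp(1i * omp * (tau - Ti) / hb) * fourpi2 * amp$time(tau - Ts, t - Ti)
  list(C_I = CI, C_II = 0 + 0i)
}

#' Classical six-point correlators
#'
#' For classical pulses the correlators reduce to products of four
#' c-number fields. Both orderings contain the same commuting factors, so
#' `C_I = C_II` exactly — classical light cannot separate the parametric
#' and dissipative pathways.
#'
#' @param spec a [twin_photon_spec()] with `kind = "classical"`.
#' @param times vector `(t, tau, Ts, Ti)` (fs).
#' @return List with complex `C_I` and `C_II` (identical).
#' @export
correlators_classical <- function(spec, times) {
  stopifnot(inherits(spec, "twin_photon_spec"))
  if (spec$kind != "classical") stop("correlators_classical needs kind = 'classical'")
  tt <- as.numeric(times)
  t <- tt[1]; tau <- tt[2]; Ts <- tt[3]; Ti <- tt[4]
  s0 <- spec$sigma_tilde
  es <- function(x) classical_field(x, spec$omega_s0, s0)
  ei <- function(x) classical_field(x, spec$omega_i0, s0)
  # the two operator orderings; c-numbers commute so they coincide
  CI <- Conj(ei(t - Ti)) * es(t - Ts) * Conj(es(tau - Ts)) * ei(tau - Ti) +
    Conj(es(t - Ts)) * ei(t - Ti) * Conj(ei(tau - Ti)) * es(tau - Ts)
  CII <- Conj(es(tau - Ts)) * ei(tau - Ti) * Conj(ei(t - Ti)) * es(t - Ts) +
    Conj(ei(tau - Ti)) * es(tau - Ts) * Conj(es(t - Ts)) * ei(t - Ti)
  list(C_I = CI, C_II = CII)
}
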