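#' Specify a twin-photon (or classical two-pulse) field
#'
#' Parameters of the light driving the stimulated Raman process.
#' For `kind = "entangled"` the pair is described by the pump bandwidth
#' `sigma0` (Lorentzian half width, eV), the entanglement time `tau0`
#' (fs, identical group-velocity delay for both arms), the fixed sum
#' frequency `omega_plus` and the tunable difference frequency
#' `omega_minus` (the Raman shift variable). For `kind = "uncorrelated"`
#' each photon is an independent wave with central frequencies
#' `omega_s0`, `omega_i0` and bandwidth `sigma_tilde = hbar / (2 tau0)`;
#' for `kind = "classical"` two laser pulses with the same bandwidth are
#' used and the correlators factorise into c-number fields.
#'
#' @param kind `"entangled"`, `"uncorrelated"` or `"classical"`.
#' @param omega_plus sum frequency (eV).
#' @param omega_minus difference frequency = Raman shift (eV).
#' @param sigma0 pump bandwidth (eV), > 0.
#' @param tau0 entanglement / pulse time (fs), > 0.
#' @param Ts,Ti central arrival times of the s and i photons (fs).
#' @param omega_s0,omega_i0 central frequencies for
#'   uncorrelated/classical kinds; default `(omega_plus +/- omega_minus)/2`.
#' @return Object of class `twin_photon_spec`.
#' @export
twin_photon_spec <- function(kind = c("entangled", "uncorrelated", "classical"),
                             omega_plus = 0.3, omega_minus = 0,
                             sigma0 = 0.001, tau0 = 25,
                             Ts = 0, Ti = 0,
                             omega_s0 = NULL, omega_i0 = NULL) {
  kind <- match.arg(kind)
  if (sigma0 <= 0) stop("sigma0 must be > 0")
  if (tau0 <= 0) stop("tau0 must be > 0")
  if (is.null(omega_s0)) omega_s0 <- (omega_plus + omega_minus) / 2
  if (is.null(omega_i0)) omega_i0 <- (omega_plus - omega_minus) / 2
  structure(
    list(
      kind = kind, omega_plus = omega_plus, omega_minus = omega_minus,
      sigma0 = sigma0, tau0 = tau0, Ts = Ts, Ti = Ti,
      omega_s0 = omega_s0, omega_i0 = omega_i0,
      sigma_tilde = hbar_ev_fs / (2 * tau0)
    ),
    class = "twin_photon_spec"
  )
}

#' @export
print.twin_photon_spec <- function(x, ...) {
  cat("<twin_photon_spec> kind=", x$kind,
      " omega+=", format(x$omega_plus), " eV",
      " omega-=", format(x$omega_minus), " eV",
      " sigma0=", format(x$sigma0), " eV",
      " tau0=", format(x$tau0), " fs\n", sep = "")
  invisible(x)
}

#' Lorentzian pump envelope
#'
#' `A(detuning) = sigma0 / (detuning^2 + sigma0^2)`: peak `1/sigma0` at
#' zero detuning, half-width-at-half-maximum `sigma0`, tending to a
#' delta-like spike as `sigma0 -> 0`.
#'
#' @param detuning frequency detuning (eV), vectorised.
#' @param sigma0 bandwidth (eV), > 0.
#' @return Real amplitude (eV^-1).
#' @export
pump_envelope <- function(detuning, sigma0) {
  if (sigma0 <= 0) stop("sigma0 must be > 0")
  sigma0 / (detuning^2 + sigma0^2)
}

#' Phase-matching amplitude of the entangling crystal
#'
#' `phi = (2i/tau0) / (v + 2i/tau0)` with `v = sum_detuning / hbar` the
#' angular sum-frequency detuning. Unit modulus at zero detuning;
#' `|phi|^2 = 1/2` at a sum detuning of `2 hbar / tau0`.
#'
#' @param sum_detuning `omega_s + omega_i - omega_plus` (eV), vectorised.
#' @param tau0 entanglement time (fs), > 0.
#' @return Complex amplitude (dimensionless).
#' @export
phase_matching_amplitude <- function(sum_detuning, tau0) {
  if (tau0 <= 0) stop("tau0 must be > 0")
  (2i / tau0) / (sum_detuning / hbar_ev_fs + 2i / tau0)
}

#' Time-domain phase-matching wavepacket
#'
#' Contour integration of the Lorentzian-pole phase-matching amplitude
#' gives a one-sided decaying exponential,
#' `phi_tilde(u) = (2/tau0) exp(-2 u)` for `u > 0` and `0` for `u < 0`,
#' where `u = t / tau0` is dimensionless time. At the jump `u = 0` the
#' Fourier convention assigns the half weight `(1/2)(2/tau0)`.
#'
#' @param u dimensionless time `t / tau0`, vectorised.
#' @param tau0 entanglement time (fs), sets the overall `2/tau0` scale.
#' @return Complex amplitude (fs^-1; real-valued in this convention).
#' @export
phi_tilde_time <- function(u, tau0 = 25) {
  amp <- (2 / tau0) * exp(-2 * pmax(u, 0))
  amp * (ifelse(u > 0, 1, ifelse(u == 0, 0.5, 0))) + 0i
}

#' Two-photon overlap window of the HOM delay
#'
#' `W(u) = Conj(phi_tilde(u)) * phi_tilde(u + DeltaT/tau0)`: the product
#' of the conjugated and delay-shifted one-sided wavepackets. At zero
#' delay `W(u) = |phi_tilde(u)|^2 >= 0`; its integral over `u` decays as
#' `exp(-2 |DeltaT| / tau0)`, which is the HOM envelope of the signal.
#'
#' @param u dimensionless time, vectorised.
#' @param deltaT_over_tau0 optical delay in units of `tau0`.
#' @param tau0 entanglement time (fs).
#' @return Complex value of `W` (real, >= 0 in this convention).
#' @export
overlap_window <- function(u, deltaT_over_tau0 = 0, tau0 = 25) {
  Conj(phi_tilde_time(u, tau0)) * phi_tilde_time(u + deltaT_over_tau0, tau0)
}

#' Classical pulse field
#'
#' `eps(t) = exp(i (omega + i sigma0) t / hbar)`: a phase factor with an
#' exponentially decaying envelope `|eps(t)| = exp(-sigma0 t / hbar)`.
#' The signal-level integrals switch the pulse on at its central time.
#'
#' @param t time relative to the pulse centre (fs), vectorised.
#' @param omega carrier frequency (eV).
#' @param sigma0 bandwidth (eV).
#' @return Complex field value.
#' @export
classical_field <- function(t, omega, sigma0) {
  exp(1i * (omega + 1i * sigma0) * t / hbar_ev_fs)
}

#' Joint spectral amplitude and time-domain wavepacket
#'
#' Builds the two-photon wave function for an entangled or uncorrelated
#' pair. Entangled: `Phi(ws, wi) = A(ws - wi - omega_minus) *
#' phi(ws + wi - omega_plus) * exp(i k L / 2)` with the linear phase
#' matching `kL/2 = (ws + wi - omega_plus) tau0 / 2`; the `|Phi|` ridge
#' lies along `ws - wi = omega_minus` (positive frequency correlation).
#' Uncorrelated: `Phi = A(ws - omega_s0) A(wi - omega_i0)` with bandwidth
#' `sigma_tilde = hbar/(2 tau0)`, exactly separable (Schmidt rank 1).
#'
#' The time-domain wavepacket `Phi_tilde(t1, t2)` (2D Fourier transform
#' with the `1/4pi^2` prefactor and `exp(-i (w1 t1 + w2 t2)/hbar)` kernel)
#' is attached in closed form; for the entangled pair it factorises into a
#' difference-time Lorentzian envelope, a one-sided sum-time exponential
#' gated at `tau0`, and carrier phases.
#'
#' @param spec a [twin_photon_spec()]; `kind = "classical"` is refused
#'   (classical light never forms a joint amplitude; use
#'   [correlators_classical()]).
#' @return Object of class `joint_amplitude` with vectorised functions
#'   `freq(ws, wi)` and `time(t1, t2)` plus the originating `spec`.
#' @export
joint_amplitude <- function(spec) {
  stopifnot(inherits(spec, "twin_photon_spec"))
  if (spec$kind == "classical") {
    stop("classical light has no joint amplitude; use correlators_classical()")
  }
  hb <- hbar_ev_fs
  if (spec$kind == "entangled") {
    wm <- spec$omega_minus; wp <- spec$omega_plus
    s0 <- spec$sigma0; t0 <- spec$tau0
    freq <- function(ws, wi) {
      pump_envelope(ws - wi - wm, s0) *
        phase_matching_amplitude(ws + wi - wp, t0) *
        exp(1i * (ws + wi - wp) * t0 / (2 * hb))
    }
    time <- function(t1, t2) {
      ts <- (t1 + t2 - t0) / 2
      phi_sum <- (2 / t0) * exp(-2 * pmax(ts, 0) / t0) *
        ifelse(ts > 0, 1, ifelse(ts == 0, 0.5, 0))
      (hb / 4) * exp(-s0 * abs(t1 - t2) / (2 * hb)) * phi_sum *
        exp(-1i * (wp * (t1 + t2) + wm * (t1 - t2)) / (2 * hb))
    }
  } else {
    st <- spec$sigma_tilde; ws0 <- spec$omega_s0; wi0 <- spec$omega_i0
    freq <- function(ws, wi) {
      (pump_envelope(ws - ws0, st) * pump_envelope(wi - wi0, st)) + 0i
    }
    time <- function(t1, t2) {
      (0.5 * exp(-st * abs(t1) / hb) * exp(-1i * ws0 * t1 / hb)) *
        (0.5 * exp(-st * abs(t2) / hb) * exp(-1i * wi0 * t2 / hb))
    }
  }
  structure(
    list(kind = spec$kind, spec = spec, freq = freq, time = time,
         normalization = "unnormalised amplitude convention; signals normalised afterwards"),
    class = "joint_amplitude"
  )
}

#' @export
print.joint_amplitude <- function(x, ...) {
  cat("<joint_amplitude> kind=", x$kind, "\n", sep = "")
  invisible(x)
}

#' Evaluate a joint amplitude on a frequency grid
#'
#' @param ja a [joint_amplitude()].
#' @param omega_s,omega_i frequency axes (eV).
#' @return Tibble with columns `omega_s`, `omega_i`, `re`, `im`, `mod2`.
#' @export
amplitude_grid <- function(ja, omega_s, omega_i) {
  g <- expand.grid(omega_s = omega_s, omega_i = omega_i)
  val <- ja$freq(g$omega_s, g$omega_i)
  tibble::tibble(
    omega_s = g$omega_s, omega_i = g$omega_i,
    re = Re(val), im = Im(val), mod2 = Mod(val)^2
  )
}
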