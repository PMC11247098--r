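test_that("the pump envelope is a unit-area-free Lorentzian of HWHM sigma0", {
  s0 <- 0.001
  expect_equal(pump_envelope(0, s0), 1 / s0)
  expect_equal(pump_envelope(c(-s0, s0), s0), rep(1 / (2 * s0), 2))
  # full width at half maximum = 2 sigma0
  half <- pump_envelope(0, s0) / 2
  expect_equal(pump_envelope(s0, s0), half)
  expect_error(pump_envelope(0, 0), "> 0")
})

test_that("the phase-matching amplitude has the Lorentzian-pole moduli", {
  t0 <- 25
  expect_equal(Mod(phase_matching_amplitude(0, t0)), 1)
  expect_equal(Mod(phase_matching_amplitude(2 * hbar_ev_fs / t0, t0))^2, 0.5)
  expect_lt(Mod(phase_matching_amplitude(50, t0)), 5e-3)
  expect_error(phase_matching_amplitude(0, -1), "> 0")
})

test_that("the time-domain wavepacket is the one-sided decaying exponential", {
  expect_identical(phi_tilde_time(-1, 25), 0 + 0i)
  u <- 1e-9 # right limit
  expect_equal(Re(phi_tilde_time(1 + u, 25) / phi_tilde_time(u, 25)), exp(-2),
               tolerance = 1e-6)
  expect_equal(Re(phi_tilde_time(0, 25)), 0.5 * 2 / 25) # half-weight at the jump

  # Fourier-pair check in the convergent direction: the transform of the
  # one-sided exponential reproduces the phase-matching amplitude
  t0 <- 10
  for (v in c(-0.3, -0.05, 0.02, 0.2)) { # rad/fs
    fre <- integrate(function(t) Re((2 / t0) * exp(-2 * t / t0) * exp(1i * v * t)),
                     0, Inf, rel.tol = 1e-10)$value
    fim <- integrate(function(t) Im((2 / t0) * exp(-2 * t / t0) * exp(1i * v * t)),
                     0, Inf, rel.tol = 1e-10)$value
    expect_equal(complex(real = fre, imaginary = fim),
                 phase_matching_amplitude(v * hbar_ev_fs, t0),
                 tolerance = 1e-6)
  }

  # direct numeric transform of the frequency amplitude (truncation-limited)
  u <- 0.7
  ft <- integrate(function(v) Re(phase_matching_amplitude(v * hbar_ev_fs, t0) *
                                   exp(-1i * v * u * t0)),
                  -400, 400, rel.tol = 1e-9, subdivisions = 10000L)$value / (2 * pi)
  expect_equal(ft, Re(phi_tilde_time(u, t0)), tolerance = 2e-3)
})

test_that("the overlap window has one-sided support and exponential delay decay", {
  u <- seq(-2, 6, by = 0.001)
  W0 <- overlap_window(u, 0, 25)
  expect_true(all(Re(W0) >= 0) && all(Im(W0) == 0))
  expect_equal(Re(W0), Mod(phi_tilde_time(u, 25))^2)

  iw <- function(d) integrate(function(x) Re(overlap_window(x, d, 25)),
                              max(0, -d), 20 + max(0, -d),
                              rel.tol = 1e-10, subdivisions = 2000L)$value
  expect_equal(iw(3) / iw(0), exp(-6), tolerance = 1e-6)
  expect_equal(iw(-3) / iw(0), exp(-6), tolerance = 1e-6)

  # non-overlapping supports
  expect_true(all(overlap_window(seq(-5, -0.01, by = 0.01), 0.5, 25) == 0))
})

test_that("the classical field is a decaying phase factor", {
  expect_identical(classical_field(0, 0.2, 0.001), 1 + 0i)
  t <- c(5, 50, 500)
  expect_equal(Mod(classical_field(t, 0.2, 0.001)),
               exp(-0.001 * t / hbar_ev_fs))
  expect_equal(classical_field(30, 0.2, 0.002) * Conj(classical_field(30, 0.2, 0.002)),
               exp(-2 * 0.002 * 30 / hbar_ev_fs) + 0i)
})

test_that("joint amplitudes have the correct correlation structure", {
  ja <- joint_amplitude(twin_photon_spec("entangled", omega_minus = 0.02,
                                         sigma0 = 0.005, tau0 = 10))
  ws <- seq(0.05, 0.27, length.out = 181)
  g <- amplitude_grid(ja, ws, ws)
  top <- g[which.max(g$mod2), ]
  expect_lt(abs(top$omega_s - top$omega_i - 0.02), 2e-3)
  expect_lt(abs(top$omega_s + top$omega_i - 0.3), 2e-3)

  # positive frequency correlation (not the anti-correlated ridge)
  p <- g$mod2 / sum(g$mod2)
  cov <- sum(p * (g$omega_s - sum(p * g$omega_s)) *
               (g$omega_i - sum(p * g$omega_i)))
  expect_gt(cov, 0)

  # uncorrelated twins: zero covariance and exact separability
  ju <- joint_amplitude(twin_photon_spec("uncorrelated", sigma0 = 0.001, tau0 = 25))
  gu <- amplitude_grid(ju, ws, ws)
  pu <- gu$mod2 / sum(gu$mod2)
  covu <- sum(pu * (gu$omega_s - sum(pu * gu$omega_s)) *
                (gu$omega_i - sum(pu * gu$omega_i)))
  expect_lt(abs(covu), 1e-8)
  sv <- svd(outer(ws, ws, ju$freq))$d
  expect_lt(sv[2] / sv[1], 1e-8)
  sve <- svd(outer(ws, ws, ja$freq))$d
  expect_gt(sve[2] / sve[1], 0.01) # entangled: Schmidt rank > 1

  expect_error(joint_amplitude(twin_photon_spec("classical")), "classical")
})

test_that("the closed-form time wavepacket matches the 2D Fourier transform", {
  tw <- twin_photon_spec("entangled", sigma0 = 0.02, tau0 = 10)
  ja <- joint_amplitude(tw)
  hb <- hbar_ev_fs
  # rotated-coordinate quadrature: difference-frequency Lorentzian factor
  # and sum-frequency phase-matching factor transform independently
  for (pt in list(c(14, 9), c(6, 6), c(21, 3))) {
    t1 <- pt[1]; t2 <- pt[2]
    Id <- integrate(function(d) pump_envelope(d, tw$sigma0) *
                      cos(d * (t1 - t2) / (2 * hb)),
                    -60, 60, rel.tol = 1e-9, subdivisions = 10000L)$value
    arg <- (t1 + t2 - tw$tau0) / 2
    Isr <- integrate(function(s) Re(phase_matching_amplitude(s, tw$tau0) *
                                      exp(-1i * s * arg / hb)),
                     -60, 60, rel.tol = 1e-9, subdivisions = 10000L)$value
    Isi <- integrate(function(s) Im(phase_matching_amplitude(s, tw$tau0) *
                                      exp(-1i * s * arg / hb)),
                     -60, 60, rel.tol = 1e-9, subdivisions = 10000L)$value
    carrier <- exp(-1i * (tw$omega_plus * (t1 + t2) +
                            tw$omega_minus * (t1 - t2)) / (2 * hb))
    val_num <- (1 / (8 * pi^2)) * Id * complex(real = Isr, imaginary = Isi) * carrier
    expect_equal(ja$time(t1, t2), val_num, tolerance = 5e-3)
  }

  # the analytic Lorentzian difference-frequency factor (closed form used
  # inside time()) transforms back to the pump envelope exactly
  s0 <- 0.02
  for (d in c(0, 0.01, 0.05)) {
    v <- integrate(function(x) pi * exp(-s0 * abs(x)) * cos(d * x) / (2 * pi),
                   -Inf, Inf, rel.tol = 1e-10)$value
    expect_equal(v, pump_envelope(d, s0), tolerance = 1e-8)
  }
})

test_that("narrow pump concentrates the amplitude on the difference-frequency line", {
  ws <- seq(0.08, 0.22, length.out = 281)
  for (s0 in c(0.004, 0.001)) {
    ja <- joint_amplitude(twin_photon_spec("entangled", sigma0 = s0, tau0 = 10))
    g <- amplitude_grid(ja, ws, ws)
    on_ridge <- abs(g$omega_s - g$omega_i - 0) < 3 * s0
    frac <- sum(g$mod2[on_ridge]) / sum(g$mod2)
    expect_gt(frac, if (s0 == 0.001) 0.9 else 0.8)
  }
})
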