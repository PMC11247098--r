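test_that("the resonance table enumerates the reference trimer lines", {
  b <- trimer_basis()
  tb <- resonance_table(b, sigma0 = 0.001, drop_zero_weight = TRUE)
  ev <- b$eigenvalues
  # populations sit at their signed gaps E(e) - E(e'')
  for (pos in c(ev[1] - ev[2], ev[1] - ev[3], ev[2] - ev[3], ev[2] - ev[1],
                ev[3] - ev[2], ev[3] - ev[1])) {
    expect_lt(min(abs(tb$position - pos)), 1e-12)
  }
  # coherence rho_e2e3 side line at gap arithmetic +/- 0.124
  coh <- ev[3] - ev[1] - (ev[3] - ev[2]) / 2
  expect_lt(min(abs(tb$position - coh)), 1e-12)
  expect_lt(min(abs(tb$position + coh)), 1e-12)
  expect_equal(coh, 0.124, tolerance = 0.002)

  # width = sigma0 + hbar gamma
  deph <- matrix(0.001, 3, 3)
  tb2 <- resonance_table(b, sigma0 = 0.001, dephasing = deph)
  expect_true(all(abs(tb2$width - (0.001 + hbar_ev_fs * 0.001)) < 1e-12))

  # single-state system: single formal entry at zero shift
  b1 <- structure(list(eigenvalues = 2.1, modal_matrix = matrix(1),
                       modal_inverse = matrix(1), n = 1L,
                       jump_up = list(), jump_down = list()),
                  class = "exciton_basis")
  tb1 <- resonance_table(b1)
  expect_true(all(tb1$position == 0))
})

test_that("frozen populations give Lorentzian lines of HWHM sigma0 at zero dephasing", {
  b <- trimer_basis()
  frozen <- stationary_trajectory(diag(c(1, 0, 0)))
  ph <- twin_photon_spec("entangled", sigma0 = 0.001, tau0 = 25)
  req <- signal_request(ph, frozen, b, seq(-0.069, -0.049, by = 0.0001),
                        T_axis = 0, method = "narrowband")
  g <- signal_narrowband(req)
  fit <- fit_lorentzian(g$omega_minus, g$values[, 1])
  expect_equal(fit$hwhm, 0.001, tolerance = 0.05)
  expect_equal(fit$center, b$eigenvalues[1] - b$eigenvalues[2], tolerance = 1e-3)

  # population limit coincides with the analytic form for populations
  g9 <- signal_population(signal_request(ph, frozen, b,
                                             g$omega_minus, 0,
                                             method = "population"))
  expect_equal(g9$values, g$values, tolerance = 1e-10)

  # time gating: constant populations make the signal T-independent
  req2 <- signal_request(ph, frozen, b, c(-0.0591), seq(0, 80, by = 20),
                         method = "narrowband")
  g2 <- signal_narrowband(req2, normalize = FALSE)
  expect_lt(diff(range(g2$values)) / max(abs(g2$values)), 1e-10)

  expect_error(signal_request(ph, frozen, b, c(0.1), 0, deltaT = 10,
                              method = "population"), "deltaT = 0")
})

test_that("numeric and analytic methods agree on slowly varying states", {
  b <- trimer_basis(); bath <- study_bath()
  ph <- twin_photon_spec("entangled")
  omv <- seq(-0.20, 0.20, by = 0.01)
  Tax <- seq(0, 100, by = 10)
  frozen <- stationary_trajectory(diag(c(0.5, 0.2, 0.3)))
  g7 <- signal_double_time(signal_request(ph, frozen, b, omv, Tax,
                                          method = "double_time", bath = bath))
  g8 <- signal_narrowband(signal_request(ph, frozen, b, omv, Tax,
                                           method = "narrowband", bath = bath))
  expect_lt(max(abs(g7$values - g8$values)), 0.02)

  # zero trajectory gives a zero signal (linearity)
  zero <- density_trajectory(seq(-500, 150, 0.5),
                             rep(list(matrix(0 + 0i, 3, 3)), length(seq(-500, 150, 0.5))))
  gz <- signal_double_time(signal_request(ph, zero, b, omv, c(0),
                                          method = "double_time"),
                           normalize = FALSE)
  expect_true(all(gz$values == 0))

  # trajectory window too short for the requested arrival times
  short <- stationary_trajectory(diag(c(1, 0, 0)), t0 = 0, t1 = 40)
  expect_error(signal_double_time(signal_request(ph, short, b, omv, c(100),
                                                 method = "double_time")),
               "integration support")
})

test_that("cross-method agreement holds on random near-stationary fixtures", {
  ph <- twin_photon_spec("entangled")
  omv <- seq(-0.15, 0.15, by = 0.015)
  for (seed in c(2, 23, 31)) {
    fx <- generate_fixture(seed, n_sites = 3)
    b <- diagonalize(build_hamiltonian(fx$spec))
    p <- abs(rnorm(3, c(0.5, 0.3, 0.2), 0.1)); p <- p / sum(p)
    frozen <- stationary_trajectory(diag(p), t0 = -2000)
    g7 <- signal_double_time(signal_request(ph, frozen, b, omv, c(0, 50),
                                            method = "double_time", bath = fx$bath))
    g8 <- signal_narrowband(signal_request(ph, frozen, b, omv, c(0, 50),
                                             method = "narrowband", bath = fx$bath))
    expect_lt(max(abs(g7$values - g8$values)), 0.02)
  }
})

test_that("population decay rates are recovered from arrival-time slices", {
  d <- aggregate_spec(c(2.2, 2.0), 0.02)
  b <- diagonalize(build_hamiltonian(d))
  bath <- bath_spec(gamma0 = 2e-3, temperature = 0)
  W <- build_dissipator(b, bath)
  L <- build_liouvillian(diag(b$eigenvalues), W, b, bath)
  G <- population_out_rates(b, bath)[2]
  tr <- propagate(L, initial_state(d, b, mode = "eigenstate", which = 2),
                  seq(0, 1500, by = 0.5))
  gap <- b$eigenvalues[2] - b$eigenvalues[1]
  req <- signal_request(twin_photon_spec("entangled"), tr, b,
                        omega_minus = gap, T_axis = seq(0, 800, by = 40),
                        method = "population", bath = bath)
  g <- signal_population(req, normalize = FALSE)
  k_fit <- -coef(lm(log(g$values[1, ]) ~ g$T))[[2]]
  expect_equal(k_fit, G, tolerance = 0.05)
})

test_that("classical light yields an exactly symmetric Stokes/anti-Stokes spectrum", {
  b <- trimer_basis(); bath <- study_bath()
  tr <- relaxed_trimer_trajectory(t_max = 400, by = 0.5)
  cl <- twin_photon_spec("classical")
  omv <- seq(-0.2, 0.2, by = 0.005)
  g <- signal_classical(signal_request(cl, tr, b, omv, c(100),
                                       method = "classical", bath = bath))
  expect_lt(max(abs(g$values - g$values[length(omv):1, , drop = FALSE])) /
              max(abs(g$values)), 1e-6)

  # zero trajectory: zero signal
  zero <- density_trajectory(seq(0, 500, 0.5),
                             rep(list(matrix(0 + 0i, 3, 3)), length(seq(0, 500, 0.5))))
  gz <- signal_classical(signal_request(cl, zero, b, omv, c(100),
                                        method = "classical"),
                         normalize = FALSE)
  expect_true(all(gz$values == 0))

  expect_error(signal_request(twin_photon_spec("entangled"), tr, b, omv, 0,
                              method = "classical"), "classical")
})

test_that("uncorrelated twins blur the lines to the single-photon bandwidth", {
  # isolated line: dimer with a 0.2 eV splitting, frozen upper population
  d <- aggregate_spec(c(2.3, 2.1), 0.01)
  b <- diagonalize(build_hamiltonian(d))
  frozen <- stationary_trajectory(diag(c(0, 1)), t0 = -400, t1 = 300)
  un <- twin_photon_spec("uncorrelated", tau0 = 25)
  gap <- b$eigenvalues[2] - b$eigenvalues[1]
  omv <- seq(gap - 0.09, gap + 0.09, by = 0.002)
  g <- signal_classical(signal_request(un, frozen, b, omv, c(0),
                                       method = "classical"))
  fit <- fit_lorentzian(g$omega_minus, g$values[, 1])
  expect_equal(fit$center, gap, tolerance = 0.004)
  # linewidth of order sigma_tilde = hbar/(2 tau0) ~ 13 meV, far above sigma0
  expect_gt(fit$hwhm, un$sigma_tilde)
  expect_lt(fit$hwhm, 4 * un$sigma_tilde)
})

test_that("the HOM scan decays at 2/tau0 with the delay-prefactor beat", {
  b <- trimer_basis()
  frozen <- stationary_trajectory(diag(c(1, 0, 0)))
  ph <- twin_photon_spec("entangled")
  req <- signal_request(ph, frozen, b, omega_minus = -0.0591, T_axis = 0,
                        method = "narrowband")
  hs <- hom_scan(req, seq(0, 100, by = 1))
  rate <- -coef(lm(log(hs$envelope) ~ hs$deltaT))[[2]]
  expect_equal(rate, 2 / 25, tolerance = 1e-6)

  hs2 <- hom_scan(req, seq(-80, 0, by = 1))
  rate2 <- coef(lm(log(hs2$envelope) ~ hs2$deltaT))[[2]]
  expect_equal(rate2, 2 / 25, tolerance = 1e-6)

  # beat at |omega_plus + omega_minus| / 2 on both branches
  bath <- study_bath()
  tr <- relaxed_trimer_trajectory(t_max = 400, by = 0.5)
  for (om in c(0.1294, -0.1294)) {
    reqb <- signal_request(ph, tr, b, omega_minus = om, T_axis = 0,
                           method = "narrowband", bath = bath)
    sc <- hom_scan(reqb, seq(-120, 120, by = 0.5))
    bf <- hom_beat_frequency(sc)
    expect_lt(abs(bf$frequency - abs(0.3 + om) / 2), bf$bin_width)
  }

  # zero-delay consistency with the 2D spectrum
  reqc <- signal_request(ph, frozen, b, omega_minus = -0.0591, T_axis = 0,
                         method = "narrowband")
  sc0 <- hom_scan(reqc, c(0))
  g0 <- signal_narrowband(reqc, normalize = FALSE)
  expect_equal(sc0$values[1], g0$values[1, 1], tolerance = 1e-12)
  expect_gt(abs(sc0$values[1]), 0) # nonzero residue at DeltaT = 0
})

test_that("entangled light is pathway-selective where classical light is not", {
  b <- trimer_basis(); bath <- study_bath()
  tr <- relaxed_trimer_trajectory(t_max = 850, by = 0.25)
  ph <- twin_photon_spec("entangled")
  omv <- seq(-0.21, 0.21, by = 0.001)
  g <- signal_narrowband(signal_request(ph, tr, b, omv, c(700),
                                          method = "narrowband", bath = bath))
  s <- g$values[, 1]
  v <- function(x) s[which.min(abs(omv - x))]
  asym <- function(p) abs(v(p) - v(-p)) / (abs(v(p)) + abs(v(-p)))
  e1_lines <- c(b$eigenvalues[2] - b$eigenvalues[1],
                b$eigenvalues[3] - b$eigenvalues[1])
  expect_gt(asym(e1_lines[1]), 0.2)
  expect_gt(asym(e1_lines[2]), 0.2)

  cl <- twin_photon_spec("classical")
  gc <- signal_classical(signal_request(cl, tr, b, seq(-0.2, 0.2, by = 0.002),
                                        c(300), method = "classical",
                                        bath = bath))
  sc <- gc$values[, 1]
  for (p in c(0.059, 0.13, 0.189)) {
    ia <- which.min(abs(gc$omega_minus - p))
    ib <- length(gc$omega_minus) + 1 - ia # mirror grid point
    a <- sc[ia]; bb <- sc[ib]
    expect_lt(abs(a - bb) / (abs(a) + abs(bb)), 1e-3)
  }
})

test_that("signal grids and scans tidy and plot", {
  b <- trimer_basis()
  frozen <- stationary_trajectory(diag(c(1, 0, 0)), t1 = 150)
  ph <- twin_photon_spec("entangled")
  req <- signal_request(ph, frozen, b, seq(-0.08, -0.04, by = 0.002),
                        T_axis = c(0, 50), method = "narrowband")
  g <- signal_narrowband(req)
  td <- tidy(g)
  expect_equal(nrow(td), length(g$omega_minus) * 2)
  expect_s3_class(autoplot(g), "ggplot")
  expect_true(glance(g)$normalized)

  hs <- hom_scan(signal_request(ph, frozen, b, -0.0591, 0,
                                method = "narrowband"), seq(-20, 20, 5))
  expect_s3_class(autoplot(hs), "ggplot")
  expect_equal(nrow(tidy(hs)), 9)

  tr <- relaxed_trimer_trajectory(t_max = 50, by = 0.5)
  expect_s3_class(autoplot(tr), "ggplot")
  expect_equal(nrow(tidy(tr)) , length(tr$times) * 9)
})
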