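# shared fixtures built in code; the reference trimer study parameters
trimer_spec <- function() aggregate_spec(c(2.25, 2.1, 2.1), 0.03)

trimer_basis <- function() diagonalize(build_hamiltonian(trimer_spec()))

study_bath <- function(...) bath_spec(...)

# stationary (constant-state) trajectory; start it at negative times so
# Raman-coherence integrals are fully accumulated at T = 0
stationary_trajectory <- function(rho, t0 = -1800, t1 = 200, by = 0.5) {
  tt <- seq(t0, t1, by = by)
  density_trajectory(tt, rep(list(rho + 0i), length(tt)))
}

relaxed_trimer_trajectory <- function(t_max = 900, by = 0.25) {
  spec <- trimer_spec()
  b <- diagonalize(build_hamiltonian(spec))
  bath <- study_bath()
  W <- build_dissipator(b, bath)
  L <- build_liouvillian(diag(b$eigenvalues), W, b, bath)
  propagate(L, initial_state(spec, b), seq(0, t_max, by = by))
}

random_fock_state <- function(seed, nbins = 5) {
  set.seed(seed)
  amp <- matrix(complex(real = rnorm(nbins^2), imaginary = rnorm(nbins^2)),
                nbins, nbins)
  gs <- seq(0.12, 0.20, length.out = nbins)
  gi <- seq(0.08, 0.17, length.out = nbins)
  fock_grid_state(amp, grid_s = gs, grid_i = gi)
}
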