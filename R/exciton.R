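#' Specify a Frenkel-exciton aggregate
#'
#' Collects the parameters of a linear molecular aggregate of `n_sites`
#' two-level chromophores: one site energy per molecule and a single
#' nearest-neighbour dipole-dipole coupling `J`. The one-exciton
#' Hamiltonian built from this spec is tridiagonal with the site energies
#' on the diagonal and `-J` on the first off-diagonals.
#'
#' The Raman polarizability matrix `alpha` couples pairs of exciton
#' eigenstates in the Raman interaction. It must be Hermitian with zero
#' diagonal (the polarizability operator is a sum over distinct-state
#' raising terms plus Hermitian conjugate, so it has no diagonal part).
#' The default couples all pairs with unit strength.
#'
#' @param site_energies numeric vector of site excitation energies (eV),
#'   one per molecule, all positive.
#' @param coupling_J nearest-neighbour coupling (eV).
#' @param polarizability optional Hermitian matrix of dimension
#'   `n_sites x n_sites` over exciton labels (dimensionless). Default:
#'   ones off the diagonal, zeros on it.
#' @return An object of class `aggregate_spec`.
#' @examples
#' trimer <- aggregate_spec(c(2.25, 2.1, 2.1), coupling_J = 0.03)
#' build_hamiltonian(trimer)
#' @export
aggregate_spec <- function(site_energies, coupling_J, polarizability = NULL) {
  n_sites <- length(site_energies)
  if (n_sites < 2) {
    stop("invalid aggregate spec: need at least 2 sites")
  }
  if (!is.numeric(site_energies) || any(!is.finite(site_energies)) ||
      any(site_energies <= 0)) {
    stop("invalid aggregate spec: site energies must be positive finite numbers")
  }
  if (!is.numeric(coupling_J) || length(coupling_J) != 1 || !is.finite(coupling_J)) {
    stop("invalid aggregate spec: coupling_J must be a single finite number")
  }
  if (is.null(polarizability)) {
    polarizability <- matrix(1, n_sites, n_sites)
    diag(polarizability) <- 0
  }
  polarizability <- as.matrix(polarizability)
  if (!all(dim(polarizability) == c(n_sites, n_sites))) {
    stop("invalid aggregate spec: polarizability must be n_sites x n_sites")
  }
  if (max(Mod(polarizability - Conj(t(polarizability)))) > 1e-12) {
    stop("invalid aggregate spec: polarizability must be Hermitian (alpha + h.c. structure)")
  }
  structure(
    list(
      n_sites = n_sites,
      site_energies = as.numeric(site_energies),
      coupling_J = coupling_J,
      polarizability = polarizability
    ),
    class = "aggregate_spec"
  )
}

#' @export
print.aggregate_spec <- function(x, ...) {
  cat("<aggregate_spec> ", x$n_sites, " sites\n", sep = "")
  cat("  site energies (eV): ", paste(format(x$site_energies), collapse = ", "), "\n", sep = "")
  cat("  J (eV): ", format(x$coupling_J), "\n", sep = "")
  invisible(x)
}

#' Specify the vibrational bath
#'
#' The bath enters only through the spectral density `D(w)` evaluated at
#' the exciton gaps and the thermal occupation of those gaps. The default
#' form is Ohmic with exponential cutoff, `D(w) = w exp(-w / cutoff)`,
#' normalised so that `gamma0` is the downward rate at a gap equal to the
#' cutoff frequency.
#'
#' @param gamma0 overall system-bath coupling scale (fs^-1), >= 0.
#' @param cutoff cutoff frequency of the spectral density (eV), > 0.
#' @param temperature bath temperature (K), >= 0.
#' @param pure_dephasing extra coherence decay rate (fs^-1) added to every
#'   off-diagonal element's damping; default 0.
#' @param form spectral density family; currently `"ohmic"`.
#' @return An object of class `bath_spec`.
#' @export
bath_spec <- function(gamma0 = 1.3e-3, cutoff = 0.2, temperature = 300,
                      pure_dephasing = 0, form = "ohmic") {
  if (gamma0 < 0) stop("gamma0 must be >= 0")
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (temperature < 0) stop("temperature must be >= 0")
  if (pure_dephasing < 0) stop("pure_dephasing must be >= 0")
  form <- match.arg(form, c("ohmic"))
  structure(
    list(
      form = form, gamma0 = gamma0, cutoff = cutoff,
      temperature = temperature, pure_dephasing = pure_dephasing
    ),
    class = "bath_spec"
  )
}

#' @export
print.bath_spec <- function(x, ...) {
  cat("<bath_spec> form=", x$form,
      " gamma0=", format(x$gamma0), " fs^-1",
      " cutoff=", format(x$cutoff), " eV",
      " T=", format(x$temperature), " K\n", sep = "")
  invisible(x)
}

#' Build the one-exciton Frenkel Hamiltonian
#'
#' Returns the real symmetric `n_sites x n_sites` matrix with the site
#' energies on the diagonal and `-J` on the first off-diagonals
#' (nearest-neighbour chain, open boundaries).
#'
#' @param spec an [aggregate_spec()].
#' @return Real symmetric matrix (eV).
#' @export
build_hamiltonian <- function(spec) {
  stopifnot(inherits(spec, "aggregate_spec"))
  n <- spec$n_sites
  H <- diag(spec$site_energies, n, n)
  idx <- seq_len(n - 1)
  H[cbind(idx, idx + 1)] <- -spec$coupling_J
  H[cbind(idx + 1, idx)] <- -spec$coupling_J
  H
}

#' Diagonalize an exciton Hamiltonian
#'
#' Computes the exciton eigenbasis of a real symmetric Hamiltonian. The
#' eigenvalues are sorted ascending, with `e1` the lowest-energy exciton
#' (population relaxes downhill towards `e1`). Eigenvector signs are fixed
#' deterministically: the largest-magnitude component of each column of
#' the modal matrix `P` is made positive.
#'
#' Unit jump operators `L+_ji = |psi_j><psi_i|` (raising, `j > i`) and
#' their adjoints `L-_ij` are attached; the bath physics (spectral density
#' and thermal occupation) enters through [relaxation_rates()].
#'
#' @param H square real symmetric matrix (eV).
#' @return An object of class `exciton_basis` with fields `eigenvalues`,
#'   `modal_matrix` (columns = eigenvectors), `modal_inverse`, `n`,
#'   `jump_up`, `jump_down` (named lists of matrices in the exciton basis).
#' @export
diagonalize <- function(H) {
  H <- as.matrix(H)
  if (nrow(H) != ncol(H)) stop("H must be square")
  if (max(abs(H - t(H))) > 1e-10) stop("H must be symmetric")
  n <- nrow(H)
  es <- eigen(H, symmetric = TRUE)
  ord <- order(es$values)
  vals <- es$values[ord]
  P <- es$vectors[, ord, drop = FALSE]
  # deterministic sign: largest-|.| component of each eigenvector positive
  for (k in seq_len(n)) {
    imax <- which.max(abs(P[, k]))
    if (P[imax, k] < 0) P[, k] <- -P[, k]
  }
  Pinv <- t(P) # orthogonal
  jump_up <- list()
  jump_down <- list()
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      if (j > i) {
        Lp <- matrix(0, n, n)
        Lp[j, i] <- 1 # |e_j><e_i| in the exciton basis
        jump_up[[paste0("L+_", j, i)]] <- Lp
        jump_down[[paste0("L-_", i, j)]] <- t(Lp)
      }
    }
  }
  structure(
    list(
      eigenvalues = vals,
      modal_matrix = P,
      modal_inverse = Pinv,
      n = n,
      jump_up = jump_up,
      jump_down = jump_down
    ),
    class = "exciton_basis"
  )
}

#' @export
print.exciton_basis <- function(x, ...) {
  cat("<exciton_basis> ", x$n, " excitons; eigenvalues (eV): ",
      paste(format(x$eigenvalues, digits = 5), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Bose-Einstein thermal occupation of a vibrational gap
#'
#' `nbar = 1 / (exp(gap / kB T) - 1)`; returns 0 at zero temperature.
#'
#' @param gap positive energy gap (eV).
#' @param temperature bath temperature (K).
#' @return Dimensionless occupation number (vectorised over `gap`).
#' @export
thermal_occupation <- function(gap, temperature) {
  if (any(gap <= 0)) stop("thermal occupation only defined for positive gaps")
  if (temperature < 0) stop("temperature must be >= 0")
  if (temperature == 0) {
    return(rep(0, length(gap)))
  }
  1 / (expm1(gap / (kb_ev_k * temperature)))
}

#' Vibrational spectral density
#'
#' Ohmic with exponential cutoff: `D(w) = w exp(-w / cutoff)`.
#'
#' @param omega frequency (eV), vectorised.
#' @param cutoff cutoff frequency (eV).
#' @param form spectral density family; currently `"ohmic"`.
#' @return `D(omega)` (eV units; only ratios matter).
#' @export
spectral_density <- function(omega, cutoff, form = "ohmic") {
  form <- match.arg(form, c("ohmic"))
  omega * exp(-omega / cutoff)
}

#' Downward relaxation rates between exciton eigenstates
#'
#' For each pair `j > i` the downward rate is
#' `gamma_ji = gamma0 * D(w_ji) / D(cutoff)`, i.e. `gamma0` is the rate at
#' a gap equal to the cutoff where the Ohmic density peaks. Inside the
#' dissipator the downward channel is scaled by `nbar + 1` and the upward
#' channel by `nbar`, which enforces detailed balance
#' (up/down ratio `exp(-gap / kB T)`).
#'
#' @param basis an [diagonalize()] result.
#' @param bath a [bath_spec()].
#' @return Matrix `gamma` with `gamma[j, i]` (fs^-1) the bare rate for the
#'   pair `(j, i)`, `j > i`; zero elsewhere.
#' @export
relaxation_rates <- function(basis, bath) {
  stopifnot(inherits(basis, "exciton_basis"), inherits(bath, "bath_spec"))
  if (bath$gamma0 < 0) stop("gamma0 must be >= 0")
  n <- basis$n
  g <- matrix(0, n, n)
  dnorm0 <- spectral_density(bath$cutoff, bath$cutoff, bath$form)
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      if (j > i) {
        gap <- basis$eigenvalues[j] - basis$eigenvalues[i]
        if (gap > 0) {
          g[j, i] <- bath$gamma0 * spectral_density(gap, bath$cutoff, bath$form) / dnorm0
        } else {
          # degenerate pair: no thermal channel
          g[j, i] <- 0
        }
      }
    }
  }
  g
}

# vec / superoperator helpers (column-major vectorisation):
# vec(A rho B) = (t(B) %x% A) vec(rho)
spre <- function(A) {
  n <- nrow(A)
  diag(n) %x% A
}
spost <- function(B) {
  t(B) %x% diag(nrow(B))
}
lindblad_term <- function(L, rate) {
  LdL <- Conj(t(L)) %*% L
  rate * (Conj(L) %x% L - 0.5 * (spre(LdL) + spost(LdL)))
}

#' Build the thermal jump-operator dissipator
#'
#' Assembles the superoperator `W` acting on the column-vectorised density
#' matrix in the exciton basis. For every eigenstate pair `j > i` the
#' downward jump `|e_i><e_j|` enters with rate `gamma_ji (nbar + 1)` and
#' the upward jump `|e_j><e_i|` with `gamma_ji nbar`, where `nbar` is the
#' thermal occupation of the gap. An optional pure-dephasing rate damps
#' the off-diagonal elements only.
#'
#' `W` maps Hermitian matrices to traceless Hermitian matrices and its
#' unique stationary state on the populations is the Boltzmann
#' distribution over the eigenvalues at the bath temperature.
#'
#' @inheritParams relaxation_rates
#' @return Complex matrix of dimension `n^2 x n^2` (fs^-1).
#' @export
build_dissipator <- function(basis, bath) {
  stopifnot(inherits(basis, "exciton_basis"), inherits(bath, "bath_spec"))
  n <- basis$n
  g <- relaxation_rates(basis, bath)
  W <- matrix(0 + 0i, n^2, n^2)
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      if (j > i && g[j, i] > 0) {
        gap <- basis$eigenvalues[j] - basis$eigenvalues[i]
        nb <- thermal_occupation(gap, bath$temperature)
        Ldown <- basis$jump_down[[paste0("L-_", i, j)]]
        Lup <- basis$jump_up[[paste0("L+_", j, i)]]
        W <- W + lindblad_term(Ldown, g[j, i] * (nb + 1))
        W <- W + lindblad_term(Lup, g[j, i] * nb)
      }
    }
  }
  if (bath$pure_dephasing > 0) {
    offdiag <- as.numeric(row(matrix(0, n, n)) != col(matrix(0, n, n)))
    W <- W - bath$pure_dephasing * diag(offdiag)
  }
  W
}

#' Apply a superoperator to a density matrix
#'
#' @param W superoperator matrix (`n^2 x n^2`).
#' @param rho density matrix (`n x n`).
#' @return The matrix `W rho` (un-vectorised).
#' @export
apply_superop <- function(W, rho) {
  n <- nrow(rho)
  matrix(W %*% as.vector(rho), n, n)
}

#' Total outgoing population rate of each eigenstate
#'
#' `Gamma_e` sums the thermal jump rates out of state `e` (downward
#' channels weighted by `nbar + 1`, upward by `nbar`). These feed the
#' Lindblad-consistent coherence dephasing `(Gamma_a + Gamma_b) / 2`.
#'
#' @inheritParams relaxation_rates
#' @return Numeric vector of length `n` (fs^-1).
#' @export
population_out_rates <- function(basis, bath) {
  n <- basis$n
  g <- relaxation_rates(basis, bath)
  out <- numeric(n)
  for (e in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > e && g[j, e] > 0) { # upward e -> j
        gap <- basis$eigenvalues[j] - basis$eigenvalues[e]
        out[e] <- out[e] + g[j, e] * thermal_occupation(gap, bath$temperature)
      }
      if (j < e && g[e, j] > 0) { # downward e -> j
        gap <- basis$eigenvalues[e] - basis$eigenvalues[j]
        out[e] <- out[e] + g[e, j] * (thermal_occupation(gap, bath$temperature) + 1)
      }
    }
  }
  out
}

#' Coherence dephasing-rate matrix
#'
#' `gamma[a, b] = (Gamma_a + Gamma_b) / 2 + pure_dephasing` for `a != b`,
#' with `Gamma_e` the total outgoing population rate of state `e`. The
#' diagonal holds `Gamma_e` (self pair), unused by the Raman lineshapes
#' because the polarizability has no diagonal elements.
#'
#' @inheritParams relaxation_rates
#' @return Matrix (fs^-1).
#' @export
dephasing_rates <- function(basis, bath) {
  Gam <- population_out_rates(basis, bath)
  n <- basis$n
  gm <- (outer(Gam, rep(1, n)) + outer(rep(1, n), Gam)) / 2
  gm[row(gm) != col(gm)] <- gm[row(gm) != col(gm)] + bath$pure_dephasing
  gm
}
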