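#' Assemble the Liouvillian
#'
#' `L vec(rho) = vec(-(i/hbar) [H, rho] + W rho)` on the column-vectorised
#' density matrix, with `H` in eV and `W` in fs^-1, so `L` is in fs^-1.
#' The left trace functional is a null left-eigenvector of `L` (trace
#' conservation) and no eigenvalue has positive real part.
#'
#' @param H Hamiltonian in the exciton basis (eV), usually
#'   `diag(basis$eigenvalues)`.
#' @param W dissipator superoperator from [build_dissipator()] (or zero
#'   matrix for closed dynamics).
#' @param basis optional [diagonalize()] result carried along for
#'   downstream bookkeeping.
#' @param bath optional [bath_spec()]; when given, the coherence dephasing
#'   matrix [dephasing_rates()] is attached.
#' @return An object of class `liouvillian` with fields `matrix`
#'   (complex `n^2 x n^2`, fs^-1), `n`, `basis`, `dephasing` (fs^-1 matrix
#'   or NULL).
#' @export
build_liouvillian <- function(H, W = NULL, basis = NULL, bath = NULL) {
  H <- as.matrix(H)
  n <- nrow(H)
  if (ncol(H) != n) stop("H must be square")
  if (is.null(W)) W <- matrix(0 + 0i, n^2, n^2)
  if (nrow(W) != n^2 || ncol(W) != n^2) {
    stop("dimension mismatch between H and W")
  }
  Lmat <- -(1i / hbar_ev_fs) * (spre(H) - spost(H)) + W
  deph <- if (!is.null(basis) && !is.null(bath)) dephasing_rates(basis, bath) else NULL
  structure(
    list(matrix = Lmat, n = n, basis = basis, bath = bath, dephasing = deph),
    class = "liouvillian"
  )
}

#' @export
print.liouvillian <- function(x, ...) {
  cat("<liouvillian> dim ", x$n^2, "x", x$n^2, " (", x$n, "-level system)\n", sep = "")
  invisible(x)
}

#' Initial density matrix after the resonant pump
#'
#' The reduced exciton model leaves the post-pump state open; the default
#' choice here is a pure excitation localised on the highest-energy site,
#' transformed into the exciton basis. This produces both populations and
#' inter-exciton coherences, so the short-time coherence beats are present
#' in the simulated signal. Alternatives: a single exciton eigenstate, or
#' any user-supplied positive trace-one matrix (site basis not assumed;
#' `custom` is taken to be already in the exciton basis).
#'
#' @param spec an [aggregate_spec()].
#' @param basis matching [diagonalize()] result.
#' @param mode one of `"site"`, `"eigenstate"`, `"custom"`.
#' @param which for `"site"`: site index (default: the highest-energy
#'   site); for `"eigenstate"`: exciton index (1 = lowest energy).
#' @param rho for `"custom"`: the density matrix in the exciton basis.
#' @return Trace-one positive Hermitian matrix in the exciton basis.
#' @export
initial_state <- function(spec, basis, mode = c("site", "eigenstate", "custom"),
                          which = NULL, rho = NULL) {
  mode <- match.arg(mode)
  n <- basis$n
  if (mode == "site") {
    if (is.null(which)) which <- which.max(spec$site_energies)
    if (which < 1 || which > n) stop("unknown site index")
    # |site><site| transformed: <e_k|site> = P[site, k]
    amp <- basis$modal_matrix[which, ]
    rho0 <- outer(amp, amp)
  } else if (mode == "eigenstate") {
    if (is.null(which)) which <- n
    if (which < 1 || which > n) stop("unknown eigenstate index")
    rho0 <- matrix(0, n, n)
    rho0[which, which] <- 1
  } else {
    if (is.null(rho)) stop("custom mode needs rho")
    rho0 <- as.matrix(rho)
    if (!all(dim(rho0) == c(n, n))) stop("custom rho has wrong dimension")
    if (max(Mod(rho0 - Conj(t(rho0)))) > 1e-10) stop("custom rho must be Hermitian")
    ev <- eigen(rho0, symmetric = TRUE, only.values = TRUE)$values
    if (min(Re(ev)) < -1e-10) stop("custom rho must be positive semidefinite")
    rho0 <- rho0 / sum(diag(rho0))
  }
  rho0 / sum(Re(diag(as.matrix(rho0))))
}

# scaling-and-squaring Pade(6) matrix exponential for complex matrices.
# (installed expm implementations are real-only; the Liouvillian is complex.)
expm_complex <- function(A) {
  n <- nrow(A)
  nrmA <- max(rowSums(Mod(A)))
  s <- max(0L, ceiling(log2(max(nrmA, .Machine$double.xmin)) + 1))
  As <- A / 2^s
  # Pade(6,6)
  c6 <- c(1, 1 / 2, 5 / 44, 1 / 66, 1 / 792, 1 / 15840, 1 / 665280)
  I <- diag(1 + 0i, n)
  A2 <- As %*% As
  A4 <- A2 %*% A2
  A6 <- A4 %*% A2
  U <- As %*% (c6[2] * I + c6[4] * A2 + c6[6] * A4)
  V <- c6[1] * I + c6[3] * A2 + c6[5] * A4 + c6[7] * A6
  E <- solve(V - U, V + U)
  if (s > 0) for (k in seq_len(s)) E <- E %*% E
  E
}

#' Propagate the density matrix on a uniform time grid
#'
#' Computes `rho(t_k) = expm(L t_k) rho0` by scaling-and-squaring on the
#' single-step propagator `expm(L dt)`, which is computed once and
#' reapplied. Trace, Hermiticity and positivity are monitored; a
#' propagation-failure error is raised on non-finite entries.
#'
#' @param L a [build_liouvillian()] result.
#' @param rho0 initial density matrix (`n x n`).
#' @param times uniform, increasing time grid (fs) starting at the initial
#'   time of `rho0`.
#' @return An object of class `density_trajectory`: list with `times` and
#'   `states` (list of complex `n x n` matrices in the exciton basis).
#' @export
propagate <- function(L, rho0, times) {
  stopifnot(inherits(L, "liouvillian"))
  n <- L$n
  rho0 <- as.matrix(rho0)
  if (!all(dim(rho0) == c(n, n))) stop("dimension mismatch between L and rho0")
  if (length(times) < 1) stop("empty time grid")
  dt <- diff(times)
  if (length(dt) > 0 && (any(dt <= 0) || diff(range(dt)) > 1e-9 * max(dt))) {
    stop("times must be a uniform increasing grid")
  }
  states <- vector("list", length(times))
  v <- as.vector(rho0) + 0i
  states[[1]] <- matrix(v, n, n)
  if (length(times) > 1) {
    U <- expm_complex(L$matrix * dt[1])
    for (k in 2:length(times)) {
      v <- U %*% v
      if (any(!is.finite(Re(v))) || any(!is.finite(Im(v)))) {
        stop("propagation failure: non-finite density matrix entries")
      }
      states[[k]] <- matrix(v, n, n)
    }
  }
  structure(
    list(times = as.numeric(times), states = states, n = n,
         basis = L$basis),
    class = "density_trajectory"
  )
}

#' @export
print.density_trajectory <- function(x, ...) {
  cat("<density_trajectory> ", length(x$times), " steps, t = ",
      format(min(x$times)), " .. ", format(max(x$times)), " fs, ",
      x$n, "-level system\n", sep = "")
  invisible(x)
}

#' Construct a trajectory from raw matrices
#'
#' Mainly for synthetic inputs in signal-level analyses (e.g. frozen or
#' prescribed populations). With `validate = TRUE` the standard
#' trace/Hermiticity/positivity invariants are enforced.
#'
#' @param times time grid (fs).
#' @param states list of `n x n` matrices.
#' @param validate check density-matrix invariants (default FALSE).
#' @return A `density_trajectory`.
#' @export
density_trajectory <- function(times, states, validate = FALSE) {
  n <- nrow(states[[1]])
  if (validate) {
    for (s in states) {
      if (abs(sum(Re(diag(s))) - 1) > 1e-8) stop("trace != 1")
      if (max(Mod(s - Conj(t(s)))) > 1e-10) stop("not Hermitian")
      if (min(Re(eigen(s, symmetric = TRUE, only.values = TRUE)$values)) < -1e-8) {
        stop("not positive semidefinite")
      }
    }
  }
  structure(list(times = as.numeric(times), states = states, n = n, basis = NULL),
            class = "density_trajectory")
}

#' Extract one density-matrix element as a time series
#'
#' @param traj a `density_trajectory`.
#' @param i,j row/column indices in the exciton basis.
#' @return Complex vector over `traj$times`.
#' @export
trajectory_element <- function(traj, i, j) {
  vapply(traj$states, function(s) s[i, j], complex(1))
}

#' Stationary state of a Liouvillian
#'
#' Normalised null vector of `L` (unit trace). For a thermal dissipator
#' this is the Boltzmann distribution over the exciton eigenvalues.
#'
#' @param L a [build_liouvillian()] result.
#' @return Density matrix (`n x n`).
#' @export
steady_state <- function(L) {
  n <- L$n
  sv <- svd(L$matrix)
  v <- sv$v[, n^2]
  rho <- matrix(v, n, n)
  rho <- (rho + Conj(t(rho))) / 2
  rho / sum(Re(diag(rho)))
}
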