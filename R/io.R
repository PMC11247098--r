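#' Default run configuration
#'
#' The reference study parameters: a trimer with site energies
#' 2.25/2.1/2.1 eV and J = 30 meV, an Ohmic bath relaxing the top exciton
#' on a few hundred fs at 300 K, and entangled twins with
#' sigma0 = 1 meV, tau0 = 25 fs, omega_plus = 0.3 eV.
#'
#' @return Nested list (sections `aggregate`, `bath`, `photon`, `grids`,
#'   `seed`, `output`).
#' @export
default_config <- function() {
  list(
    aggregate = list(
      site_energies = c(2.25, 2.1, 2.1),
      coupling_J = 0.03
    ),
    bath = list(
      form = "ohmic", gamma0 = 1.3e-3, cutoff = 0.2,
      temperature = 300, pure_dephasing = 0
    ),
    photon = list(
      kind = "entangled", omega_plus = 0.3, omega_minus = 0,
      sigma0 = 0.001, tau0 = 25, Ts = 0, Ti = 0
    ),
    grids = list(
      omega_minus = list(from = -0.22, to = 0.22, by = 0.001),
      T_axis = list(from = 0, to = 700, by = 35),
      time_step = 0.25, time_max = 1000
    ),
    seed = 1L,
    output = list(prefix = "qusrs", format = "tsv")
  )
}

check_known_keys <- function(cfg, template, path = "") {
  for (key in names(cfg)) {
    if (!key %in% names(template)) {
      stop("unknown config key: ", path, key)
    }
    if (is.list(cfg[[key]]) && is.list(template[[key]]) &&
        !is.null(names(template[[key]]))) {
      check_known_keys(cfg[[key]], template[[key]], paste0(path, key, "."))
    }
  }
  invisible(TRUE)
}

#' Read a run configuration
#'
#' YAML file with the sections of [default_config()]; missing keys fall
#' back to the defaults, unknown keys are rejected with an explicit
#' error.
#'
#' @param path YAML file path.
#' @return Nested configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  def <- default_config()
  check_known_keys(cfg, def)
  modifyList(def, cfg)
}

#' Write a run configuration
#'
#' @param cfg configuration list.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  check_known_keys(cfg, default_config())
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Build model objects from a configuration
#'
#' @param cfg configuration list from [read_run_config()] or
#'   [default_config()].
#' @return List with `spec`, `bath`, `photon`, `basis`, `grids`.
#' @export
config_objects <- function(cfg) {
  spec <- aggregate_spec(cfg$aggregate$site_energies, cfg$aggregate$coupling_J)
  bath <- bath_spec(gamma0 = cfg$bath$gamma0, cutoff = cfg$bath$cutoff,
                    temperature = cfg$bath$temperature,
                    pure_dephasing = cfg$bath$pure_dephasing,
                    form = cfg$bath$form)
  photon <- twin_photon_spec(kind = cfg$photon$kind,
                             omega_plus = cfg$photon$omega_plus,
                             omega_minus = cfg$photon$omega_minus,
                             sigma0 = cfg$photon$sigma0,
                             tau0 = cfg$photon$tau0,
                             Ts = cfg$photon$Ts, Ti = cfg$photon$Ti)
  basis <- diagonalize(build_hamiltonian(spec))
  list(spec = spec, bath = bath, photon = photon, basis = basis,
       grids = cfg$grids)
}

#' Write a matrix as delimited text with a JSON sidecar
#'
#' @param m matrix (real or complex; complex written as Re/Im column
#'   pairs).
#' @param path output path for the tab-delimited values; the sidecar is
#'   written to `paste0(path, ".json")`.
#' @param meta named list of metadata (units, labels, ...).
#' @return `path`, invisibly.
#' @export
write_matrix_txt <- function(m, path, meta = list()) {
  if (is.complex(m)) {
    out <- cbind(Re(m), Im(m))
    colnames(out) <- c(paste0("re_", seq_len(ncol(m))),
                       paste0("im_", seq_len(ncol(m))))
    meta$complex <- TRUE
  } else {
    out <- m
    meta$complex <- FALSE
  }
  meta$nrow <- nrow(m); meta$ncol <- ncol(m)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_txt()]
#'
#' @param path path of the delimited file (sidecar expected alongside).
#' @return The matrix, with the sidecar attached as attribute `meta`.
#' @export
read_matrix_txt <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  raw <- as.matrix(read.table(path, sep = "\t", header = TRUE))
  if (isTRUE(meta$complex)) {
    nc <- meta$ncol
    m <- matrix(complex(real = raw[, seq_len(nc)],
                        imaginary = raw[, nc + seq_len(nc)]),
                meta$nrow, nc)
  } else {
    m <- raw
    dimnames(m) <- NULL
  }
  attr(m, "meta") <- meta
  m
}

#' Export a density trajectory as delimited text
#'
#' One row per time step: `time` followed by Re/Im pairs of all density
#' matrix elements (row-major), with a JSON metadata sidecar (units,
#' basis labels).
#'
#' @param traj a `density_trajectory`.
#' @param path output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
export_trajectory <- function(traj, path) {
  n <- traj$n
  labs <- as.vector(t(outer(seq_len(n), seq_len(n),
                            function(a, b) paste0(a, b))))
  m <- t(vapply(traj$states, function(s) {
    v <- as.vector(t(s))
    c(rbind(Re(v), Im(v)))
  }, numeric(2 * n * n)))
  colnames(m) <- as.vector(rbind(paste0("re_", labs), paste0("im_", labs)))
  out <- cbind(time = traj$times, m)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(time_unit = "fs", basis = "exciton eigenbasis (ascending energy)",
         n = n, elements = labs),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Export a signal grid as delimited text
#'
#' First column is the Raman-shift axis (eV); remaining columns are the
#' arrival times (fs) named `T_<value>`; JSON sidecar with parameters.
#'
#' @param grid a `signal_grid`.
#' @param path output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
export_signal_grid <- function(grid, path) {
  m <- cbind(grid$omega_minus, grid$values)
  colnames(m) <- c("omega_minus_eV", paste0("T_", grid$T))
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    c(list(method = grid$method, normalized = grid$normalized,
           omega_unit = "eV", T_unit = "fs"), grid$provenance),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
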