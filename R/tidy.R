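#' Tidy a density trajectory
#'
#' Long tibble with one row per (time, element): columns `time`, `row`,
#' `col`, `re`, `im`, `kind` (`"population"` or `"coherence"`).
#'
#' @param x a `density_trajectory`.
#' @param ... unused.
#' @return A tibble.
#' @method tidy density_trajectory
#' @export
tidy.density_trajectory <- function(x, ...) {
  n <- x$n
  rows <- rep(rep(seq_len(n), each = n), length(x$times))
  cols <- rep(rep(seq_len(n), times = n), length(x$times))
  vals <- unlist(lapply(x$states, function(s) as.vector(t(s))))
  tibble::tibble(
    time = rep(x$times, each = n * n),
    row = rows, col = cols,
    re = Re(vals), im = Im(vals),
    kind = ifelse(rows == cols, "population", "coherence")
  )
}

#' Glance at a density trajectory
#'
#' One-row summary: step count, span, final trace deviation, maximum
#' Hermiticity defect and most negative eigenvalue along the trajectory.
#'
#' @param x a `density_trajectory`.
#' @param ... unused.
#' @return A one-row tibble.
#' @method glance density_trajectory
#' @export
glance.density_trajectory <- function(x, ...) {
  trdev <- max(vapply(x$states, function(s) abs(sum(Re(diag(s))) - 1), 0))
  herm <- max(vapply(x$states, function(s) max(Mod(s - Conj(t(s)))), 0))
  mineig <- min(vapply(x$states, function(s) {
    min(Re(eigen((s + Conj(t(s))) / 2, symmetric = TRUE, only.values = TRUE)$values))
  }, 0))
  tibble::tibble(
    n_steps = length(x$times),
    t_min = min(x$times), t_max = max(x$times),
    max_trace_dev = trdev, max_hermiticity_defect = herm,
    min_eigenvalue = mineig
  )
}

#' Tidy a 2D Raman signal grid
#'
#' @param x a `signal_grid`.
#' @param ... unused.
#' @return Tibble with columns `omega_minus`, `T`, `value`.
#' @method tidy signal_grid
#' @export
tidy.signal_grid <- function(x, ...) {
  tibble::tibble(
    omega_minus = rep(x$omega_minus, times = length(x$T)),
    T = rep(x$T, each = length(x$omega_minus)),
    value = as.vector(x$values)
  )
}

#' Glance at a signal grid
#' @param x a `signal_grid`.
#' @param ... unused.
#' @return A one-row tibble with grid shape and value range.
#' @method glance signal_grid
#' @export
glance.signal_grid <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_omega = length(x$omega_minus), n_T = length(x$T),
    min_value = min(x$values), max_value = max(x$values),
    normalized = x$normalized
  )
}

#' Tidy a HOM delay scan
#' @param x a `hom_scan`.
#' @param ... unused.
#' @return Tibble with `deltaT`, `value`, `envelope`.
#' @method tidy hom_scan
#' @export
tidy.hom_scan <- function(x, ...) {
  tibble::tibble(deltaT = x$deltaT, value = x$values, envelope = x$envelope)
}

#' Plot a 2D Raman spectrum
#'
#' Raster of the signal over Raman shift (x, eV) and arrival time (y, fs).
#'
#' @param object a `signal_grid`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot signal_grid
#' @export
autoplot.signal_grid <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$omega_minus, y = .data$T,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "S (arb.)") +
    ggplot2::labs(x = expression(omega["-"] ~ "(eV)"), y = "T (fs)",
                  title = paste0("Stimulated Raman signal (", object$method, ")"))
}

#' Plot a HOM delay scan
#'
#' Signal versus optical delay with its modulus envelope.
#'
#' @param object a `hom_scan`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot hom_scan
#' @export
autoplot.hom_scan <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$deltaT)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$value), colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$envelope), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = -.data$envelope), linetype = 2) +
    ggplot2::labs(x = expression(Delta * T ~ "(fs)"), y = "S (arb.)",
                  title = "Hong-Ou-Mandel delay scan")
}

#' Plot exciton populations and coherences over time
#'
#' @param object a `density_trajectory`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot density_trajectory
#' @export
autoplot.density_trajectory <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$row <= df$col, , drop = FALSE]
  df$element <- paste0("rho[", df$row, df$col, "]")
  df$magnitude <- sqrt(df$re^2 + df$im^2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$magnitude,
                                   colour = .data$element,
                                   linetype = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t (fs)", y = expression("|" * rho[ee * "'"] * "|"),
                  title = "Exciton density-matrix dynamics")
}

#' @importFrom ggplot2 .data
NULL
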