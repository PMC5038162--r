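# tidy()/glance()/autoplot() methods and figure helpers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy probe series into a long tibble
#'
#' @param x an `sa_result`, `cycle_result` or `lvsa_run`.
#' @param ... unused.
#' @return Tibble with columns `t_s`, `probe`, `P_mmHg`, `Q_mL_s`, `A_cm2`.
#' @export
tidy.sa_result <- function(x, ...) series_to_long(x$series)

#' @rdname tidy.sa_result
#' @export
tidy.lvsa_run <- function(x, ...) series_to_long(x$sa)

#' @rdname tidy.sa_result
#' @export
tidy.cycle_result <- function(x, ...) x$lv

series_to_long <- function(series) {
  probes <- colnames(series$P)
  dplyr::bind_rows(lapply(probes, function(nm) {
    tibble::tibble(t_s = series$t, probe = nm, P_mmHg = series$P[, nm],
                   Q_mL_s = series$Q[, nm], A_cm2 = series$A[, nm])
  }))
}

#' One-row summaries
#'
#' `glance()` on a coupled run returns the ventricular index battery plus
#' convergence information.
#'
#' @param x an `lvsa_run`.
#' @param ... unused.
#' @return One-row tibble.
#' @export
glance.lvsa_run <- function(x, ...) {
  base <- tibble::tibble(case_id = x$case_id, iso = x$iso,
                         converged = x$converged,
                         convergence_metric = x$convergence_metric)
  if (!is.null(x$cycle)) {
    base <- dplyr::bind_cols(base, lv_indices(x, refuse_unconverged = FALSE))
  }
  base
}

#' Pressure/flow waveform figure
#'
#' @param x a run object (`lvsa_run` or `sa_result`).
#' @param probes probe names to show (default: all).
#' @param what `"P"` or `"Q"`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot_waveforms <- function(x, probes = NULL, what = c("P", "Q"), ...) {
  what <- match.arg(what)
  long <- if (inherits(x, "sa_result")) tidy.sa_result(x) else tidy.lvsa_run(x)
  if (!is.null(probes)) long <- long[long$probe %in% probes, ]
  long$t_s <- long$t_s - min(long$t_s)
  yvar <- if (what == "P") "P_mmHg" else "Q_mL_s"
  ylab <- if (what == "P") "Pressure (mmHg)" else "Flow (mL/s)"
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_s, y = .data[[yvar]],
                                     colour = .data$probe)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time in cycle (s)", y = ylab, colour = "Probe") +
    ggplot2::theme_minimal()
}

#' @rdname plot_waveforms
#' @export
autoplot.sa_result <- function(x, probes = NULL, what = "P", ...) {
  plot_waveforms(x, probes, what, ...)
}

#' Pressure-volume loop of a coupled cycle
#'
#' @param x a `cycle_result` (or `lvsa_run`).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cycle_result <- function(x, ...) {
  ggplot2::ggplot(x$lv, ggplot2::aes(x = .data$V, y = .data$P_lv)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "Cavity volume (mL)", y = "Cavity pressure (mmHg)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cycle_result
#' @export
autoplot.lvsa_run <- function(x, ...) {
  if (is.null(x$cycle)) return(autoplot.sa_result(x, ...))
  autoplot.cycle_result(x$cycle, ...)
}
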