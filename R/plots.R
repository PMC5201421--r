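#' Plot a cargo trajectory
#'
#' Spatial profiles of bound and detached cargo at each stored time.
#'
#' @param object a `cargo_trajectory` from [evolve_transport()].
#' @param times optional subset of times to draw (nearest stored times are
#'   used); default up to 6 log-spaced snapshots.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cargo_trajectory <- function(object, times = NULL, ...) {
  df <- tibble::as_tibble(object)
  all_t <- sort(unique(df$time_s))
  if (is.null(times)) {
    times <- all_t[unique(round(seq(1, length(all_t), length.out = 6)))]
  } else {
    times <- vapply(times, function(t) all_t[which.min(abs(all_t - t))],
                    numeric(1))
  }
  df <- df[df$time_s %in% times, ]
  long <- tidyr::pivot_longer(df, c("bound", "detached"),
                              names_to = "pool", values_to = "mass")
  ggplot2::ggplot(long, ggplot2::aes(.data$id, .data$mass,
                                     colour = factor(signif(.data$time_s, 3)))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~pool, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "compartment", y = "cargo mass", colour = "time (s)") +
    ggplot2::theme_minimal()
}

#' Plot a speed-precision tradeoff curve
#'
#' @param object a `tradeoff_curve` from [tradeoff_sweep()].
#' @param x `"time_s"` (delivery/convergence time) or `"excess_frac"`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.tradeoff_curve <- function(object, x = c("time_s", "excess_frac"),
                                    ...) {
  x <- match.arg(x)
  df <- tibble::as_tibble(object)
  df <- df[is.finite(df[[x]]) & is.finite(df$error_pct), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data[[x]], .data$error_pct)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$value)) +
    ggplot2::labs(
      x = if (x == "time_s") "time (s)" else "excess (in-transit) fraction",
      y = "mean percent error (%)",
      colour = unique(df$param)
    ) +
    ggplot2::theme_minimal()
  if (x == "time_s") p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot a walk ensemble concentration profile
#'
#' Histogram of particle positions at a few snapshots, the bulk view of the
#' stochastic walks.
#'
#' @param object a `walk_ensemble`.
#' @param times snapshot times (s); default 4 evenly spaced.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.walk_ensemble <- function(object, times = NULL, ...) {
  df <- tidy.walk_ensemble(object)
  all_t <- sort(unique(df$t_s))
  if (is.null(times)) {
    times <- all_t[unique(round(seq(2, length(all_t), length.out = 4)))]
  }
  df <- df[df$t_s %in% times, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um)) +
    ggplot2::geom_histogram(binwidth = object$params$step_length * 2) +
    ggplot2::facet_wrap(~t_s, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "position (um)", y = "particles") +
    ggplot2::theme_minimal()
}
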