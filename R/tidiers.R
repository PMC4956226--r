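#' Tidiers and autoplot methods for fitted objects
#'
#' broom-style accessors: `tidy()` returns per-term/per-resample detail,
#' `glance()` a one-row summary; `autoplot()` gives the standard figure
#' for each result type (bootstrap box plots, BER-versus-subset-size
#' curves with the one-SE threshold, paired-difference histograms).
#'
#' @param x a `shock_model`, `shock_boot`, `shock_comparison` or
#'   `shock_selection`.
#' @param ... unused.
#' @return a tibble (`tidy`, `glance`) or a ggplot (`autoplot`).
#' @name shockable-tidiers
NULL

#' @rdname shockable-tidiers
#' @export
tidy.shock_model <- function(x, ...) {
  tibble(
    feature = x$features,
    attribution = x$attribution
  ) |>
    arrange(desc(.data$attribution))
}

#' @rdname shockable-tidiers
#' @export
glance.shock_model <- function(x, ...) {
  tibble(
    algorithm = x$algorithm, n_features = length(x$features),
    n_train = x$n_train, seed = x$seed
  )
}

#' @rdname shockable-tidiers
#' @export
tidy.shock_boot <- function(x, ...) {
  x$summary
}

#' @rdname shockable-tidiers
#' @export
glance.shock_boot <- function(x, ...) {
  s <- x$summary
  tibble(
    B = x$B, n_missing = x$n_missing,
    se = s$mean[s$metric == "se"], sp = s$mean[s$metric == "sp"],
    ber = s$mean[s$metric == "ber"]
  )
}

#' @rdname shockable-tidiers
#' @export
tidy.shock_comparison <- function(x, ...) {
  tibble(
    metric = x$metric, mean_delta = x$mean,
    ci_lo = x$ci[1], ci_hi = x$ci[2], significant = x$significant
  )
}

#' @rdname shockable-tidiers
#' @export
tidy.shock_selection <- function(x, ...) {
  x$counts
}

#' @rdname shockable-tidiers
#' @export
glance.shock_selection <- function(x, ...) {
  tibble(
    method = x$method, K_s = x$K_s, k_min = x$k_min,
    min_ber = min(x$curve$mean_ber), threshold = x$threshold, B = x$B
  )
}

#' @rdname shockable-tidiers
#' @param object the result object to plot.
#' @export
autoplot.shock_boot <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics, c("se", "sp", "ber"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = toupper(.data$metric), y = .data$value)
  ) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(
      x = NULL, y = "percent",
      title = sprintf("Patient-wise bootstrap (B = %d)", object$B)
    )
}

#' @rdname shockable-tidiers
#' @export
autoplot.shock_selection <- function(object, ...) {
  ggplot2::ggplot(
    object$curve,
    ggplot2::aes(x = .data$k, y = .data$mean_ber)
  ) +
    ggplot2::geom_pointrange(
      ggplot2::aes(
        ymin = .data$mean_ber - .data$sd_ber,
        ymax = .data$mean_ber + .data$sd_ber
      ),
      linewidth = 0.3, size = 0.3
    ) +
    ggplot2::geom_hline(
      yintercept = object$threshold, linetype = 2,
      colour = "red"
    ) +
    ggplot2::geom_vline(
      xintercept = object$K_s, linetype = 3,
      colour = "blue"
    ) +
    ggplot2::labs(
      x = "subset size k", y = "out-of-bag BER (%)",
      title = sprintf("%s: K_s = %d", object$method, object$K_s)
    )
}

#' @rdname shockable-tidiers
#' @export
autoplot.shock_comparison <- function(object, ...) {
  ggplot2::ggplot(
    tibble(delta = object$delta),
    ggplot2::aes(x = .data$delta)
  ) +
    ggplot2::geom_histogram(bins = 40, fill = "grey80", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$ci, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, colour = "red") +
    ggplot2::labs(
      x = sprintf("paired delta %s (percentage points)", object$metric),
      y = "resamples"
    )
}

#' @rdname shockable-tidiers
#' @param segments a labelled segment tibble.
#' @param row which segment row to plot.
#' @param fs sampling rate in Hz.
#' @export
plot_segment <- function(segments, row = 1, fs = 250) {
  x <- segments$samples[[row]]
  d <- tibble(t = (seq_along(x) - 1) / fs, uv = x)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$uv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time (s)", y = "amplitude (uV)",
      title = paste(
        segments$segment_id[row], "-",
        segments$source_rhythm[row]
      )
    )
}
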