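# broom-style tidiers and ggplot2 autoplot methods.

#' Tidy a session summary
#'
#' @param x A `session_summary` from [summarize_session()].
#' @param ... Unused.
#' @return The per-exercise error table as a tibble (one row per exercise:
#'   half means/SDs, test, adjusted p, significance flag).
#' @exportS3Method generics::tidy
#' @export
tidy.session_summary <- function(x, ...) {
  x$errors
}

#' One-row overview of a session summary
#'
#' @param x A `session_summary`.
#' @param ... Unused.
#' @return A one-row tibble: exercise counts, how many half-comparisons
#'   survived FDR control, and the SUS summary when available.
#' @exportS3Method generics::glance
#' @export
glance.session_summary <- function(x, ...) {
  out <- tibble(
    n_exercises = nrow(x$errors),
    n_participants = max(x$errors$n),
    n_significant = sum(x$errors$significant),
    alpha = x$alpha
  )
  if (!is.null(x$sus)) {
    out$sus_mean <- x$sus$mean
    out$sus_sd <- x$sus$sd
    out$sus_p <- x$sus_test$p.value
  }
  out
}

#' Plot a pitch track
#'
#' Voiced frames as a line/point contour over time; unvoiced stretches are
#' gaps. If a target curve is supplied it is drawn with its tolerance band.
#'
#' @param object A [pitch_track()].
#' @param target Optional `target_curve` to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.pitch_track <- function(object, target = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$f0))
  if (!is.null(target)) {
    tt <- seq(0, target$duration - 1e-6, by = 0.005)
    tv <- target_value(target, tt)
    band <- if (target$tolerance_unit == "cents") {
      cbind(tv * 2^(-target$tolerance / 1200), tv * 2^(target$tolerance / 1200))
    } else {
      cbind(tv - target$tolerance, tv + target$tolerance)
    }
    tdf <- tibble(time = tt, target = tv, lo = band[, 1], hi = band[, 2])
    p <- p +
      ggplot2::geom_ribbon(data = tdf,
                           ggplot2::aes(x = .data$time, ymin = .data$lo,
                                        ymax = .data$hi),
                           inherit.aes = FALSE, alpha = 0.15, fill = "steelblue") +
      ggplot2::geom_line(data = tdf,
                         ggplot2::aes(x = .data$time, y = .data$target),
                         inherit.aes = FALSE, colour = "steelblue")
  }
  p +
    ggplot2::geom_line(na.rm = TRUE, colour = "palevioletred3") +
    ggplot2::geom_point(size = 0.4, na.rm = TRUE, colour = "palevioletred3") +
    ggplot2::labs(x = "time (s)", y = "f0 (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a session summary
#'
#' Per-exercise mean error (with SD bars) in the first versus second five
#' repetitions; asterisks mark exercises whose improvement survives FDR
#' control.
#'
#' @param object A `session_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.session_summary <- function(object, ...) {
  df <- object$errors |>
    tidyr::pivot_longer(c("mean_first", "mean_second"),
                        names_to = "half", values_to = "mean_error") |>
    dplyr::mutate(
      sd = ifelse(.data$half == "mean_first", .data$sd_first, .data$sd_second),
      half = ifelse(.data$half == "mean_first", "repetitions 1-5",
                    "repetitions 6-10"),
      exercise = factor(.data$exercise, levels = object$errors$exercise))
  stars <- object$errors |>
    dplyr::filter(.data$significant) |>
    dplyr::mutate(y = pmax(.data$mean_first + .data$sd_first,
                           .data$mean_second + .data$sd_second) * 1.05)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$exercise, y = .data$mean_error,
                                   fill = .data$half)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean_error - .data$sd, 0),
                   ymax = .data$mean_error + .data$sd),
      position = ggplot2::position_dodge(0.8), width = 0.25) +
    ggplot2::geom_text(data = stars,
                       ggplot2::aes(x = .data$exercise, y = .data$y,
                                    label = "*"),
                       inherit.aes = FALSE, size = 6) +
    ggplot2::labs(x = NULL, y = "exercise error (Hz)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
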