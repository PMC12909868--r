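#' Plot a simulated trial
#'
#' Draws both agents' paths on the screen, marking start points and (if it
#' occurs) the collision.
#'
#' @param trial A one-row trial tibble or a frames tibble/matrix.
#' @param geom A [screen_geometry()] for the plot bounds.
#' @return A ggplot object.
#' @export
plot_trial <- function(trial, geom = screen_geometry()) {
  f <- if (is.data.frame(trial) && "frames" %in% names(trial))
    tibble::as_tibble(as.data.frame(trial$frames[[1]]))
  else tibble::as_tibble(as.data.frame(trial))
  long <- dplyr::bind_rows(
    tibble::tibble(agent = "participant", x = f$p_x, y = f$p_y,
                   frame = seq_len(nrow(f))),
    tibble::tibble(agent = "opponent", x = f$o_x, y = f$o_y,
                   frame = seq_len(nrow(f)))
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$y, colour = .data$agent)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = dplyr::filter(long, .data$frame == 1),
                        shape = 21, size = 2, fill = "white") +
    ggplot2::coord_fixed(xlim = c(0, geom$width), ylim = c(0, geom$height)) +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.glop_recovery <- function(object, ...) {
  df <- dplyr::filter(object, .data$bin != "overall", !is.na(.data$r))
  df$mid <- (df$lower + df$upper) / 2
  ggplot2::ggplot(df, ggplot2::aes(.data$mid, .data$r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~parameter) +
    ggplot2::coord_cartesian(ylim = c(-0.2, 1)) +
    ggplot2::labs(x = "censored length (s)",
                  y = "recovery correlation (Pearson r)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.glop_estimator <- function(object, ...) {
  plot_history(object$history, "loss")
}

#' @export
autoplot.glop_classifier <- function(object, ...) {
  plot_history(object$history, "acc")
}

plot_history <- function(history, which = c("loss", "acc")) {
  which <- match.arg(which)
  df <- dplyr::filter(history, grepl(which, .data$metric))
  ggplot2::ggplot(df, ggplot2::aes(.data$step, .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "training step", y = which, colour = NULL) +
    ggplot2::theme_minimal()
}
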