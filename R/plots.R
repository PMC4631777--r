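#' Plot a tracked trajectory
#'
#' Sister centromeres, their midpoint and the two poles along the spindle
#' axis versus time, in the style of projected kymograph traces.
#'
#' @param object A `kt_trajectory` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kt_trajectory
#' @export
autoplot.kt_trajectory <- function(object, ...) {
  mid <- (object$cenA + object$cenB) / 2
  long <- dplyr::bind_rows(
    tibble(t = object$t, x = object$cenA, element = "sister A"),
    tibble(t = object$t, x = object$cenB, element = "sister B"),
    tibble(t = object$t, x = mid, element = "midpoint"),
    tibble(t = object$t, x = object$pole1, element = "pole"),
    tibble(t = object$t, x = object$pole2, element = "pole"))
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$x, colour = .data$element)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_colour_manual(values = c("sister A" = "#c0392b",
                                            "sister B" = "#e67e22",
                                            "midpoint" = "#2980b9",
                                            "pole" = "black")) +
    ggplot2::labs(x = "time (s)", y = "position on spindle axis (um)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a simulated mitosis
#'
#' Kinetochore-pair midpoints of every chromosome and the two poles versus
#' time; the anaphase trigger is marked.
#'
#' @param object A `sim_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sim_trajectory
#' @export
autoplot.sim_trajectory <- function(object, ...) {
  s <- as.data.frame(object$states)
  N <- object$params$N_ch
  long <- purrr::map_dfr(seq_len(N), function(c) {
    tibble(t = s$t,
           x = (s[[paste0("cen_c", c, "A")]] + s[[paste0("cen_c", c, "B")]]) / 2,
           element = paste0("chromosome ", c))
  })
  poles <- dplyr::bind_rows(
    tibble(t = s$t, x = s$x_spbL, element = "pole"),
    tibble(t = s$t, x = s$x_spbR, element = "pole"))
  ggplot2::ggplot(dplyr::bind_rows(long, poles),
                  ggplot2::aes(.data$t, .data$x, colour = .data$element)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_vline(xintercept = object$params$t_meta,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "time (s)", y = "position (um)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a parameter sweep
#'
#' Mean normalized anaphase-onset distance per swept condition, with the
#' length-dependence-on reference drawn as a horizontal line.
#'
#' @param object A `sweep_result` from [parameter_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, ...) {
  ref <- object$mean_nd[object$condition == "ldep_on"]
  d <- object[object$condition != "ldep_on", ]
  ggplot2::ggplot(d, ggplot2::aes(.data$condition, .data$mean_nd)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_nd - .data$sem_nd,
                                        ymax = .data$mean_nd + .data$sem_nd),
                           width = 0.3) +
    ggplot2::geom_hline(yintercept = ref, colour = "#2980b9",
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "normalized distance at anaphase onset") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot binned intensity profiles
#'
#' Mean normalized intensity versus fractional position along the
#' microtubule, one panel per length bin.
#'
#' @param object A `profile_stats` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot profile_stats
#' @export
autoplot.profile_stats <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(.data$position, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "#a9cce3") +
    ggplot2::geom_line(colour = "#21618c") +
    ggplot2::facet_wrap(~bin) +
    ggplot2::labs(x = "fractional position (minus to plus end)",
                  y = "normalized intensity") +
    ggplot2::theme_minimal()
}
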