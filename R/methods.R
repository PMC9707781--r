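#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted STF model
#'
#' @param x An `stf_fit`.
#' @param ... Unused.
#' @return One row per DoG parameter: `term`, `estimate`.
#' @method tidy stf_fit
#' @export
tidy.stf_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kc", "ks", "rc_deg", "rs_deg", "center_x_deg", "center_y_deg"),
    estimate = c(x$kc, x$ks, x$rc_deg, x$rs_deg,
                 x$center_deg[1], x$center_deg[2])
  )
}

#' @rdname tidy.stf_fit
#' @method glance stf_fit
#' @export
glance.stf_fit <- function(x, ...) {
  tibble::tibble(
    rmse = x$rmse, scenario = x$scenario, defocus_D = x$defocus_D,
    offset_applied = x$offset_applied,
    n_freq = nrow(x$measured), n_starts = x$n_starts, seed = x$seed
  )
}

#' @export
print.stf_fit <- function(x, ...) {
  cat("<stf_fit>", x$scenario, "center,",
      sprintf("%.3f D residual defocus", x$defocus_D), "\n")
  cat(sprintf("  kc = %.4g, ks = %.4g, rc = %.4g deg, rs = %.4g deg\n",
              x$kc, x$ks, x$rc_deg, x$rs_deg))
  cat(sprintf("  weighted RMSE = %.4g (%d starts)\n", x$rmse, x$n_starts))
  if (x$offset_applied) cat("  (negative-going STF: offset correction applied)\n")
  invisible(x)
}

#' Plot a fitted STF model against the measured data
#'
#' @param object An `stf_fit`.
#' @param ... Unused.
#' @return A ggplot: measured points with SEM bars and the model curve on a
#'   log frequency axis.
#' @method autoplot stf_fit
#' @export
autoplot.stf_fit <- function(object, ...) {
  meas <- object$measured
  mod <- object$model_stf
  ggplot2::ggplot(meas, ggplot2::aes(x = .data$freq_cpd)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$dff - .data$sem,
                                        ymax = .data$dff + .data$sem),
                           width = 0.02, color = "grey50") +
    ggplot2::geom_point(ggplot2::aes(y = .data$dff), color = "darkgreen") +
    ggplot2::geom_line(data = mod, ggplot2::aes(y = .data$amplitude),
                       color = "darkorange", linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "spatial frequency (c/deg)",
                  y = expression(Delta * "F/F"),
                  title = sprintf("%s center, %.3f D", object$scenario,
                                  object$defocus_D)) +
    ggplot2::theme_minimal()
}

#' Plot a cone mosaic
#'
#' @param object A `cone_mosaic`.
#' @param ... Unused.
#' @return A ggplot of cone positions colored by class, sized by aperture.
#' @method autoplot cone_mosaic
#' @export
autoplot.cone_mosaic <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$x_deg, y = .data$y_deg,
                               color = .data$class,
                               size = .data$aperture_um)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_color_manual(values = c(L = "#C83737", M = "#2E8B57",
                                           S = "#4169E1")) +
    ggplot2::scale_size_continuous(range = c(0.3, 1.5), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (deg)", y = "y (deg)") +
    ggplot2::theme_minimal()
}

#' Plot a physiological-optics STF prediction
#'
#' @param object A `physio_stf` from [predict_physiological_stf()].
#' @param ... Unused.
#' @return A ggplot comparing the stimulation-optics model STF with the
#'   predicted physiological-optics STF and its descriptive DoG fit.
#' @method autoplot physio_stf
#' @export
autoplot.physio_stf <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$aoslo_stf, which = "stimulation optics"),
    dplyr::mutate(object$stf, which = "physiological optics")
  )
  fitted <- tibble::tibble(freq_cpd = object$stf$freq_cpd,
                           amplitude = object$dog_curve,
                           which = "descriptive DoG")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_cpd, y = .data$amplitude,
                                   color = .data$which)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = fitted) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "spatial frequency (c/deg)", y = "response amplitude",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the MTF of an optical transfer object
#'
#' @param object An `optical_transfer`.
#' @param max_freq_cpd Upper frequency limit for the plot.
#' @param ... Unused.
#' @return A ggplot of the radial MTF.
#' @method autoplot optical_transfer
#' @export
autoplot.optical_transfer <- function(object, max_freq_cpd = 250, ...) {
  f <- seq(0, max_freq_cpd, length.out = 200)
  df <- tibble::tibble(freq_cpd = f, mtf = mtf_at(object, f))
  ggplot2::ggplot(df, ggplot2::aes(.data$freq_cpd, .data$mtf)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "spatial frequency (c/deg)", y = "MTF") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
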