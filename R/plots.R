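#' Plot class-mean spectra
#'
#' Draws the mean spectrum of each class, faceted by channel block — the
#' usual first look at a fingerprint dataset.
#'
#' @param d A [spectral_dataset()].
#' @return A ggplot object.
#' @export
plot_spectra <- function(d) {
  cm <- sd_colmeta(d)
  long <- tibble::as_tibble(d) |>
    tidyr::pivot_longer(dplyr::all_of(cm$column), names_to = "column",
                        values_to = "intensity") |>
    dplyr::left_join(cm, by = "column") |>
    dplyr::group_by(.data$class_label, .data$channel, .data$wavenumber) |>
    dplyr::summarise(intensity = mean(.data$intensity), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(.data$wavenumber, .data$intensity,
                                     color = .data$class_label)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, scales = "free") +
    ggplot2::labs(x = expression("Raman shift (cm"^-1*")"),
                  y = "Intensity (a.u.)", color = "Class") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mx_projection <- function(object, ...) {
  sc <- object$scores
  ax <- paste0(object$kind, 1:2)
  ggplot2::ggplot(sc, ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]],
                                   color = .data$class_label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(color = "Class") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mx_barcode <- function(object, ...) {
  b <- tibble::as_tibble(object)
  b$flag <- factor(ifelse(is.na(b$direction), "n/a",
                          ifelse(b$direction > 0, "increase", "decrease")),
                   levels = c("increase", "decrease", "n/a"))
  ggplot2::ggplot(b, ggplot2::aes(x = .data$wavenumber, fill = .data$flag)) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$wavenumber - 0.5,
                                    xmax = .data$wavenumber + 0.5,
                                    ymin = 0, ymax = 1)) +
    ggplot2::scale_fill_manual(values = c(increase = "black", decrease = "grey60",
                                          `n/a` = "steelblue")) +
    ggplot2::facet_wrap(~channel, ncol = 1) +
    ggplot2::labs(x = expression("Raman shift (cm"^-1*")"), y = NULL,
                  fill = NULL, title = attr(object, "name")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @export
autoplot.mx_protocol <- function(object, ...) {
  ggplot2::ggplot(object$accuracy,
                  ggplot2::aes(.data$config, .data$test_accuracy)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(ggplot2::aes(color = .data$class), width = 0.15) +
    ggplot2::labs(x = NULL, y = "Test accuracy (%)", color = "Class") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mx_separation <- function(object, ...) {
  ggplot2::ggplot(object$spread, ggplot2::aes(.data$class, .data$spread)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "Mahalanobis spread",
                  subtitle = sprintf("average Bhattacharyya distance: %.2f (%s space)",
                                     object$average_bhattacharyya, object$kind)) +
    ggplot2::theme_minimal()
}
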