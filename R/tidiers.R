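#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Broom-style tidiers for fitted objects
#'
#' `tidy()` returns the per-unit results as a tibble (per-class CV
#' accuracies for `mx_lda`, per class-by-repeat accuracies for
#' `mx_protocol`, pairwise Bhattacharyya distances for `mx_separation`,
#' scores for `mx_projection`); `glance()` returns a one-row summary.
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @name mxraman-tidiers
NULL

#' @rdname mxraman-tidiers
#' @export
tidy.mx_lda <- function(x, ...) x$cv_class_accuracy

#' @rdname mxraman-tidiers
#' @export
glance.mx_lda <- function(x, ...) {
  tibble::tibble(cv_accuracy = x$cv_accuracy, folds = x$folds,
                 n_classes = length(x$classes), n_variables = nrow(x$fit$w))
}

#' @rdname mxraman-tidiers
#' @export
tidy.mx_protocol <- function(x, ...) x$accuracy

#' @rdname mxraman-tidiers
#' @export
glance.mx_protocol <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "config",
                     values_from = c("mean_accuracy", "sd_accuracy")) |>
    dplyr::mutate(omnibus_p = x$omnibus_p)
}

#' @rdname mxraman-tidiers
#' @export
tidy.mx_separation <- function(x, ...) x$pairwise

#' @rdname mxraman-tidiers
#' @export
glance.mx_separation <- function(x, ...) {
  tibble::tibble(average_bhattacharyya = x$average_bhattacharyya,
                 mean_spread = mean(x$spread$spread), kind = x$kind)
}

#' @rdname mxraman-tidiers
#' @export
tidy.mx_projection <- function(x, ...) tibble::as_tibble(x$scores)

#' @rdname mxraman-tidiers
#' @export
glance.mx_projection <- function(x, ...) {
  tibble::tibble(n_components = length(x$explained_variance),
                 explained_variance_total = sum(x$explained_variance),
                 kind = x$kind)
}
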