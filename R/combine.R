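## MX fusion: end-on-end concatenation of per-channel fingerprints,
## Raman + autofluorescence fusion, and depolarization-ratio spectra.

pairing_order <- function(meta, pairing) {
  # returns a row order such that the i-th rows of all inputs pair up
  if (pairing == "by_acquisition_index") {
    order(meta$class_label, meta$sample_id, meta$acquisition_index)
  } else { # by_rank_within_sample: position within sample, ignoring indices
    o <- order(meta$class_label, meta$sample_id, meta$acquisition_index)
    o
  }
}

check_pairable <- function(metas, pairing) {
  ref <- metas[[1]]
  for (i in seq_along(metas)[-1]) {
    m <- metas[[i]]
    if (!setequal(ref$sample_id, m$sample_id)) {
      stop("pairing error: datasets cover different sample sets", call. = FALSE)
    }
    ta <- table(ref$sample_id)
    tb <- table(m$sample_id)
    if (!all(ta[names(tb)] == tb)) {
      stop("pairing error: per-sample spectrum counts differ", call. = FALSE)
    }
    cls_a <- unique(ref[, c("sample_id", "class_label")])
    cls_b <- unique(m[, c("sample_id", "class_label")])
    if (!identical(cls_a[order(cls_a$sample_id), ]$class_label,
                   cls_b[order(cls_b$sample_id), ]$class_label)) {
      stop("pairing error: class labels disagree across datasets", call. = FALSE)
    }
    if (pairing == "by_acquisition_index") {
      oa <- ref[order(ref$sample_id, ref$acquisition_index), ]
      ob <- m[order(m$sample_id, m$acquisition_index), ]
      if (!identical(oa$acquisition_index, ob$acquisition_index)) {
        stop("pairing error: acquisition indices differ; use pairing = \"by_rank_within_sample\"",
             call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Concatenate per-channel fingerprints into MX spectra
#'
#' Fuses fingerprints acquired under different configurations (e.g. two
#' excitation wavelengths) by end-on-end concatenation: row i of the output
#' is the concatenation of the paired rows of every input. Per-block values
#' are preserved bit-exactly; no joint renormalization is applied, so each
#' block keeps its own unit norm. With a single input the operation is the
#' identity.
#'
#' @param datasets Ordered list of [spectral_dataset()] objects sharing the
#'   same samples and per-sample spectrum counts (each typically
#'   vector-normalized already).
#' @param pairing `"by_acquisition_index"` (default; indices must agree
#'   across datasets) or `"by_rank_within_sample"` (pair by position within
#'   each sample).
#' @return A [spectral_dataset()] whose column map carries one block per
#'   input channel, with a `provenance` attribute listing the source channel
#'   tags in concatenation order.
#' @export
mx_concatenate <- function(datasets,
                           pairing = c("by_acquisition_index", "by_rank_within_sample")) {
  pairing <- match.arg(pairing)
  stopifnot(length(datasets) >= 1)
  if (length(datasets) == 1L) return(datasets[[1]])
  metas <- lapply(datasets, sd_meta)
  check_pairable(metas, pairing)
  orders <- lapply(metas, pairing_order, pairing = pairing)
  mats <- mapply(function(d, o) sd_matrix(d)[o, , drop = FALSE],
                 datasets, orders, SIMPLIFY = FALSE)
  cms <- lapply(datasets, sd_colmeta)
  tags <- vapply(cms, function(cm) cm$channel[1], "")
  if (anyDuplicated(unlist(lapply(cms, function(cm) unique(cm$channel))))) {
    # disambiguate duplicated channel tags (e.g. self-concatenation)
    cms <- lapply(seq_along(cms), function(i) {
      cm <- cms[[i]]
      cm$channel <- paste0(cm$channel, "#", i)
      cm
    })
  }
  cm <- dplyr::bind_rows(lapply(cms, function(x) x[, c("channel", "wavenumber")]))
  out <- spectral_dataset(do.call(cbind, mats), metas[[1]][orders[[1]], ],
                          col_meta = cm, signal_kind = attr(datasets[[1]], "signal_kind"))
  attr(out, "provenance") <- tags
  out
}

#' Fuse Raman fingerprints with their autofluorescence signal
#'
#' Concatenates the Raman fingerprint block with the (vector-normalized)
#' autofluorescence block produced by [remove_fluorescence()]. The
#' autofluorescence block has the same number of variables as the Raman
#' block, so the fused spectrum doubles the variable count.
#'
#' @param raman,fluor Paired [spectral_dataset()] objects.
#' @inheritParams mx_concatenate
#' @return A [spectral_dataset()] with `raman` and autofluorescence blocks.
#' @export
combine_raman_fluor <- function(raman, fluor,
                                pairing = c("by_acquisition_index", "by_rank_within_sample")) {
  fluor <- vector_normalize(fluor)
  mx_concatenate(list(raman, fluor), pairing = match.arg(pairing))
}

#' Depolarization-ratio spectra
#'
#' Computes the per-variable depolarization ratio
#' \eqn{\rho = I_\perp / I_\parallel} from paired parallel- and
#' perpendicular-polarized datasets on the same axis. The denominator is
#' floored (default: 1e-6 of the parallel block's maximum) to avoid
#' divisions by values near zero; affected variables are reported in a
#' message. Bands with \eqn{\rho < 0.75} correspond to totally symmetric
#' vibrations.
#'
#' @param par,perp Paired [spectral_dataset()] objects (parallel,
#'   perpendicular) with identical column maps.
#' @param floor Denominator floor; `NULL` uses `1e-6 * max(parallel)`.
#' @inheritParams mx_concatenate
#' @return A [spectral_dataset()] with `signal_kind = "depolarization_ratio"`.
#' @export
depolarization_spectrum <- function(par, perp, floor = NULL,
                                    pairing = c("by_acquisition_index", "by_rank_within_sample")) {
  pairing <- match.arg(pairing)
  cma <- sd_colmeta(par)
  cmb <- sd_colmeta(perp)
  if (!isTRUE(all.equal(cma$wavenumber, cmb$wavenumber)) ||
      nrow(cma) != nrow(cmb)) {
    stop("alignment error: parallel and perpendicular axes differ", call. = FALSE)
  }
  metas <- list(sd_meta(par), sd_meta(perp))
  check_pairable(metas, pairing)
  oa <- pairing_order(metas[[1]], pairing)
  ob <- pairing_order(metas[[2]], pairing)
  mp <- sd_matrix(par)[oa, , drop = FALSE]
  ms <- sd_matrix(perp)[ob, , drop = FALSE]
  if (is.null(floor)) floor <- 1e-6 * max(mp)
  if (floor <= 0) stop("floor must be positive", call. = FALSE)
  n_floored <- sum(mp < floor)
  if (n_floored > 0) {
    message(n_floored, " parallel intensities below the floor were capped")
  }
  rho <- ms / pmax(mp, floor)
  cm <- cma
  cm$channel <- sub("-par$", "", cm$channel)
  cm$channel <- paste0(cm$channel, "-rho")
  spectral_dataset(rho, metas[[1]][oa, ],
                   col_meta = cm[, c("channel", "wavenumber")],
                   signal_kind = "depolarization_ratio")
}
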