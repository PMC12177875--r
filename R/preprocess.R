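#' Preprocessing configuration
#'
#' Bundles the tunable parameters of the standard preprocessing chain:
#' Haar-wavelet denoising depth, fluorescence polynomial order, intensity
#' normalization, and the optional automated despiking of cosmic-ray
#' artefacts across a sample's repeat acquisitions.
#'
#' @param wavelet_levels Decomposition depth for Haar denoising (default 6).
#' @param poly_order Order of the fluorescence baseline polynomial (default 5).
#' @param normalize `"vector"` (unit Euclidean norm, default) or `"none"`.
#' @param standardize_for_pca Standardize columns after the per-spectrum
#'   chain (useful when the output feeds PCA directly). Default `FALSE`;
#'   [separation_report()] standardizes internally either way.
#' @param despike `"off"` (default) or `"multi_acquisition_median"`: replace
#'   points more than 5 MADs above the median of a sample's repeat
#'   acquisitions by that median.
#'
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(wavelet_levels = 6L, poly_order = 5L,
                              normalize = c("vector", "none"),
                              standardize_for_pca = FALSE,
                              despike = c("off", "multi_acquisition_median")) {
  normalize <- match.arg(normalize)
  despike <- match.arg(despike)
  wavelet_levels <- as.integer(wavelet_levels)
  poly_order <- as.integer(poly_order)
  if (wavelet_levels < 1L) stop("wavelet_levels must be >= 1", call. = FALSE)
  if (poly_order < 0L) stop("poly_order must be >= 0", call. = FALSE)
  structure(list(wavelet_levels = wavelet_levels, poly_order = poly_order,
                 normalize = normalize, standardize_for_pca = standardize_for_pca,
                 despike = despike),
            class = "preprocess_config")
}

## ---- Haar wavelet machinery (orthonormal pyramid, reflection padding) ----

haar_analysis <- function(x, levels) {
  n <- length(x)
  n2 <- 2^ceiling(log2(n))
  if (n2 > n) x <- c(x, x[(n - 1):(n - (n2 - n))])
  details <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    odd <- a[seq(1, length(a), by = 2)]
    even <- a[seq(2, length(a), by = 2)]
    details[[l]] <- (odd - even) / sqrt(2)
    a <- (odd + even) / sqrt(2)
  }
  list(approx = a, details = details, n = n)
}

haar_synthesis <- function(dec) {
  a <- dec$approx
  for (l in rev(seq_along(dec$details))) {
    d <- dec$details[[l]]
    odd <- (a + d) / sqrt(2)
    even <- (a - d) / sqrt(2)
    a <- as.vector(rbind(odd, even))
  }
  a[seq_len(dec$n)]
}

soft_threshold <- function(x, lambda) sign(x) * pmax(abs(x) - lambda, 0)

denoise_vec <- function(x, levels) {
  n <- length(x)
  if (n < 2^levels) {
    stop(sprintf("signal of length %d too short for %d wavelet levels", n, levels),
         call. = FALSE)
  }
  dec <- haar_analysis(x, levels)
  sigma <- stats::median(abs(dec$details[[1]])) / 0.6745
  lambda <- sigma * sqrt(2 * log(n))
  dec$details <- lapply(dec$details, soft_threshold, lambda = lambda)
  haar_synthesis(dec)
}

#' Haar-wavelet denoising
#'
#' Multi-level Haar decomposition with soft thresholding of all detail
#' coefficients at the universal threshold \eqn{\sigma\sqrt{2\ln N}}, where
#' \eqn{\sigma} is estimated from the finest-level detail coefficients by
#' MAD/0.6745. A noise-free smooth signal passes through essentially
#' unchanged because the estimated \eqn{\sigma} is then near zero.
#'
#' @param s A [raman_spectrum()], [spectral_dataset()] (rows denoised
#'   independently) or numeric vector.
#' @param levels Decomposition depth; the signal must have at least
#'   `2^levels` points.
#' @return Same shape as the input.
#' @export
wavelet_denoise <- function(s, levels = 6L) UseMethod("wavelet_denoise")

#' @export
wavelet_denoise.numeric <- function(s, levels = 6L) denoise_vec(s, levels)

#' @export
wavelet_denoise.raman_spectrum <- function(s, levels = 6L) {
  spectrum_with(s, intensity = denoise_vec(s$intensity, levels))
}

#' @export
wavelet_denoise.spectral_dataset <- function(s, levels = 6L) {
  m <- sd_matrix(s)
  dataset_with(s, matrix = t(apply(m, 1, denoise_vec, levels = levels)))
}

## ---- fluorescence baseline ----

poly_basis <- function(x, order) {
  if (order == 0L) matrix(1, length(x), 1L)
  else cbind(1, stats::poly(x, degree = order, raw = FALSE))
}

fit_baseline_vec <- function(y, basis, max_iter = 100L) {
  support <- seq_along(y)
  fit <- rep(NA_real_, length(y))
  for (i in seq_len(max_iter)) {
    cf <- stats::.lm.fit(basis[support, , drop = FALSE], y[support])$coefficients
    cf[is.na(cf)] <- 0
    fit <- drop(basis %*% cf)
    keep <- which(y <= fit)
    if (length(keep) < ncol(basis) + 1L || identical(keep, support)) break
    support <- keep
  }
  fit
}

#' Remove the fluorescence baseline, retaining it as a signal
#'
#' Fits a polynomial of the given order by least squares, iteratively
#' refitting on the points at or below the current fit (up to 100 rounds or
#' until the support stabilizes) so the curve tracks the baseline underneath
#' Raman peaks. The fit is subtracted to give the Raman component and is
#' itself returned as the autofluorescence estimate, which therefore has the
#' same number of variables as the Raman spectrum and can be fused with it
#' downstream.
#'
#' @param s A [raman_spectrum()] or [spectral_dataset()].
#' @param order Polynomial order; must be below the number of points.
#' @return A list with elements `raman` and `fluorescence`, matching the
#'   input type. Their sum reconstructs the input exactly.
#' @export
remove_fluorescence <- function(s, order = 5L) UseMethod("remove_fluorescence")

#' @export
remove_fluorescence.raman_spectrum <- function(s, order = 5L) {
  if (order >= nrow(s)) stop("polynomial order must be below the point count", call. = FALSE)
  fit <- fit_baseline_vec(s$intensity, poly_basis(s$wavenumber, order))
  list(raman = spectrum_with(s, intensity = s$intensity - fit),
       fluorescence = spectrum_with(s, intensity = fit,
                                    signal_kind = "autofluorescence"))
}

#' @export
remove_fluorescence.spectral_dataset <- function(s, order = 5L) {
  cm <- sd_colmeta(s)
  if (order >= nrow(cm)) stop("polynomial order must be below the variable count", call. = FALSE)
  m <- sd_matrix(s)
  fl <- matrix(0, nrow(m), ncol(m))
  # fit each channel block on its own axis
  for (ch in unique(cm$channel)) {
    idx <- which(cm$channel == ch)
    basis <- poly_basis(cm$wavenumber[idx], order)
    fl[, idx] <- t(apply(m[, idx, drop = FALSE], 1, fit_baseline_vec, basis = basis))
  }
  fl_cm <- cm
  fl_cm$channel <- paste0(fl_cm$channel, "-af")
  list(raman = dataset_with(s, matrix = m - fl),
       fluorescence = spectral_dataset(fl, sd_meta(s),
                                       col_meta = fl_cm[, c("channel", "wavenumber")],
                                       signal_kind = "autofluorescence"))
}

## ---- rubberband anchoring ----

lower_hull_idx <- function(x, y) {
  n <- length(x)
  h <- integer(0)
  for (i in seq_len(n)) {
    while (length(h) >= 2) {
      a <- h[length(h) - 1L]
      b <- h[length(h)]
      if ((x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a]) <= 0) {
        h <- h[-length(h)]
      } else break
    }
    h <- c(h, i)
  }
  h
}

rubberband_vec <- function(x, y) {
  h <- lower_hull_idx(x, y)
  base <- stats::approx(x[h], y[h], xout = x, method = "linear", ties = "ordered")$y
  out <- y - base
  out[c(1L, length(out))] <- 0
  out
}

#' Rubberband baseline anchoring
#'
#' Subtracts the piecewise-linear baseline through the lower convex hull of
#' the spectrum, anchoring both ends of the spectrum exactly to the axis.
#' The result is non-negative everywhere (up to floating-point error) and a
#' convex-downward spectrum maps to all zeros.
#'
#' @param s A [raman_spectrum()] or [spectral_dataset()] (applied per row and
#'   per channel block).
#' @return Same type as the input.
#' @export
rubberband_anchor <- function(s) UseMethod("rubberband_anchor")

#' @export
rubberband_anchor.raman_spectrum <- function(s) {
  if (nrow(s) < 3) stop("rubberband anchoring needs at least 3 points", call. = FALSE)
  spectrum_with(s, intensity = rubberband_vec(s$wavenumber, s$intensity))
}

#' @export
rubberband_anchor.spectral_dataset <- function(s) {
  cm <- sd_colmeta(s)
  m <- sd_matrix(s)
  for (ch in unique(cm$channel)) {
    idx <- which(cm$channel == ch)
    m[, idx] <- t(apply(m[, idx, drop = FALSE], 1, function(r) {
      rubberband_vec(cm$wavenumber[idx], r)
    }))
  }
  dataset_with(s, matrix = m)
}

## ---- normalization / standardization ----

#' Vector normalization
#'
#' Scales intensities to unit Euclidean norm. Scale-invariant:
#' `vector_normalize(k * s)` equals `vector_normalize(s)` for any `k > 0`.
#'
#' @param s A [raman_spectrum()], [spectral_dataset()] (per row) or numeric
#'   vector. An all-zero input is a degenerate-input error.
#' @return Same type as the input.
#' @export
vector_normalize <- function(s) UseMethod("vector_normalize")

normalize_vec <- function(x) {
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) stop("degenerate input: all-zero spectrum cannot be normalized", call. = FALSE)
  x / nrm
}

#' @export
vector_normalize.numeric <- function(s) normalize_vec(s)

#' @export
vector_normalize.raman_spectrum <- function(s) {
  spectrum_with(s, intensity = normalize_vec(s$intensity))
}

#' @export
vector_normalize.spectral_dataset <- function(s) {
  m <- sd_matrix(s)
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stop("degenerate input: all-zero spectrum cannot be normalized", call. = FALSE)
  dataset_with(s, matrix = m / nrm)
}

#' Standardize dataset columns
#'
#' Centers every variable to mean 0 and scales to sample standard deviation 1.
#' Zero-variance columns are set to 0 with a warning.
#'
#' @param d A [spectral_dataset()] with at least 2 rows.
#' @return A [spectral_dataset()].
#' @export
standardize_columns <- function(d) {
  if (nrow(d) < 2) stop("standardization needs at least 2 spectra", call. = FALSE)
  m <- sd_matrix(d)
  mu <- colMeans(m)
  sdev <- apply(m, 2, stats::sd)
  zero <- sdev == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance column(s) set to 0", call. = FALSE)
    sdev[zero] <- 1
  }
  m <- sweep(sweep(m, 2, mu), 2, sdev, "/")
  m[, zero] <- 0
  dataset_with(d, matrix = m)
}

## ---- blank subtraction & despiking ----

#' Subtract a blank (substrate) background
#'
#' Subtracts the element-wise mean of the blank spectra. Blanks are resampled
#' onto the target axis first; negative values in the result are permitted
#' (later baseline stages handle them).
#'
#' @param s A [raman_spectrum()] or [spectral_dataset()].
#' @param blanks Non-empty list of blank [raman_spectrum()] objects (for a
#'   multi-channel dataset, blanks are matched to channel blocks by their
#'   channel tag).
#' @return Same type as the input.
#' @export
subtract_background <- function(s, blanks) UseMethod("subtract_background")

mean_blank_on_axis <- function(blanks, axis) {
  rows <- vapply(blanks, function(b) resample_to_axis(b, axis)$intensity,
                 numeric(length(axis)))
  rowMeans(matrix(rows, nrow = length(axis)))
}

#' @export
subtract_background.raman_spectrum <- function(s, blanks) {
  if (!length(blanks)) stop("missing blanks: at least one blank spectrum required", call. = FALSE)
  spectrum_with(s, intensity = s$intensity - mean_blank_on_axis(blanks, s$wavenumber))
}

#' @export
subtract_background.spectral_dataset <- function(s, blanks) {
  if (!length(blanks)) stop("missing blanks: at least one blank spectrum required", call. = FALSE)
  cm <- sd_colmeta(s)
  m <- sd_matrix(s)
  tags <- vapply(blanks, function(b) {
    channel_tag(attr(b, "excitation_nm"), attr(b, "polarization"), attr(b, "signal_kind"))
  }, "")
  for (ch in unique(cm$channel)) {
    idx <- which(cm$channel == ch)
    sel <- if (length(unique(cm$channel)) == 1L) seq_along(blanks) else which(tags == ch)
    if (!length(sel)) stop("missing blanks for channel '", ch, "'", call. = FALSE)
    bl <- mean_blank_on_axis(blanks[sel], cm$wavenumber[idx])
    m[, idx] <- sweep(m[, idx, drop = FALSE], 2, bl)
  }
  dataset_with(s, matrix = m)
}

#' Automated cosmic-ray despiking across repeat acquisitions
#'
#' For each sample, points more than 5 MADs above the per-variable median of
#' that sample's repeat acquisitions are replaced by the median. Meant as a
#' reproducible substitute for manual cosmic-ray removal; off by default in
#' [preprocess_dataset()].
#'
#' @param d A [spectral_dataset()] with repeat acquisitions per sample.
#' @param k MAD multiplier (default 5).
#' @return A [spectral_dataset()].
#' @export
despike_acquisitions <- function(d, k = 5) {
  m <- sd_matrix(d)
  meta <- sd_meta(d)
  for (sid in unique(meta$sample_id)) {
    rows <- which(meta$sample_id == sid)
    if (length(rows) < 3) next
    med <- apply(m[rows, , drop = FALSE], 2, stats::median)
    madv <- apply(m[rows, , drop = FALSE], 2, stats::mad)
    sub <- m[rows, , drop = FALSE]
    hi <- sweep(sub, 2, med + k * madv, ">")
    sub[hi] <- matrix(med, nrow(sub), ncol(sub), byrow = TRUE)[hi]
    m[rows, ] <- sub
  }
  dataset_with(d, matrix = m)
}

#' Run the full preprocessing chain on a raw dataset
#'
#' Applies, in order: optional despiking, blank subtraction, Haar-wavelet
#' denoising, polynomial fluorescence removal (the fit is kept as the
#' autofluorescence signal), rubberband anchoring, and vector normalization.
#' The chain is deterministic, and it is not idempotent: a second pass refits
#' the baseline on an already-processed spectrum.
#'
#' @param d Raw [spectral_dataset()].
#' @param blanks List of blank [raman_spectrum()] objects.
#' @param config A [preprocess_config()].
#' @return A list with `fingerprint` (preprocessed Raman dataset) and
#'   `autofluorescence` (the fitted baselines, vector-normalized under the
#'   same `normalize` setting).
#' @export
preprocess_dataset <- function(d, blanks, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  nv_min <- min(table(sd_colmeta(d)$channel))
  if (config$wavelet_levels > floor(log2(nv_min))) {
    stop("invalid config: wavelet_levels too deep for ", nv_min, " variables",
         call. = FALSE)
  }
  if (config$poly_order >= nv_min) {
    stop("invalid config: poly_order must be below the variable count", call. = FALSE)
  }
  if (config$despike == "multi_acquisition_median") d <- despike_acquisitions(d)
  d <- subtract_background(d, blanks)
  d <- wavelet_denoise(d, config$wavelet_levels)
  parts <- remove_fluorescence(d, config$poly_order)
  fp <- rubberband_anchor(parts$raman)
  af <- parts$fluorescence
  if (config$normalize == "vector") {
    fp <- vector_normalize(fp)
    af <- vector_normalize(af)
  }
  if (config$standardize_for_pca) fp <- standardize_columns(fp)
  list(fingerprint = fp, autofluorescence = af)
}
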