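## Synthetic multi-channel Raman generator: Lorentzian peaks on broad
## autofluorescence baselines with patient-level random effects, plus
## ground-truth annotations for recovery tests.

lorentz <- function(x, center, fwhm) {
  h <- (fwhm / 2)^2
  h / ((x - center)^2 + h)
}

#' Specify a synthetic multi-channel design
#'
#' Describes a class-structured acquisition: shared backbone peaks, class-
#' specific peak changes tagged with the channel carrying them, per-sample
#' multiplicative (lognormal) amplitude effects emulating patient-level
#' variation, additive Gaussian detector noise, and a broad baseline
#' (low-order polynomial plus a wide Gaussian hump) with a random
#' per-spectrum scale standing in for autofluorescence.
#'
#' @param channels Named list of axes: `list(tag = list(from, to, n))`.
#' @param backbone Tibble of shared peaks: `center`, `fwhm`, one `amp_<tag>`
#'   column per channel, `rho` (depolarization ratio, used only for
#'   polarized output).
#' @param class_peaks Tibble of class-specific changes: `class`, `channel`,
#'   `center`, `fwhm`, `delta` (signed amplitude change; the planted
#'   direction is its sign), `rho`.
#' @param control_class Label of the unmodified class.
#' @param n_samples Samples per class.
#' @param n_spectra Spectra (repeat acquisitions) per sample; must be >= 4.
#' @param sample_sdlog SD of the per-(sample, peak) lognormal amplitude
#'   multiplier.
#' @param noise_sd SD of the additive Gaussian noise per point.
#' @param baseline List: `scale` (mean amplitude), `sdlog` (per-spectrum
#'   lognormal scale spread), `hump_center`, `hump_width`, `tilt`.
#' @param n_blanks Blank (baseline-only) spectra per channel.
#' @param seed Default seed for [generate_spectra()].
#' @return A list of class `mx_design`.
#' @export
synthetic_design <- function(channels, backbone, class_peaks,
                             control_class = "control",
                             n_samples = 3L, n_spectra = 30L,
                             sample_sdlog = 0.15, noise_sd = 0.02,
                             baseline = list(scale = 2, sdlog = 0.2,
                                             hump_center = 1200, hump_width = 400,
                                             tilt = 0.3),
                             n_blanks = 3L, seed = 20260926L) {
  stopifnot(n_spectra >= 4, n_samples >= 1)
  backbone <- tibble::as_tibble(backbone)
  class_peaks <- tibble::as_tibble(class_peaks)
  for (tag in names(channels)) {
    ax <- channels[[tag]]
    if (ax$n < 2^6) stop("each channel axis needs at least 64 points", call. = FALSE)
    if (!paste0("amp_", tag) %in% names(backbone)) {
      stop("backbone lacks an amp_ column for channel '", tag, "'", call. = FALSE)
    }
  }
  if (!all(class_peaks$channel %in% names(channels))) {
    stop("class_peaks reference unknown channels", call. = FALSE)
  }
  structure(list(channels = channels, backbone = backbone,
                 class_peaks = class_peaks, control_class = control_class,
                 classes = c(control_class, sort(unique(class_peaks$class))),
                 n_samples = as.integer(n_samples),
                 n_spectra = as.integer(n_spectra),
                 sample_sdlog = sample_sdlog, noise_sd = noise_sd,
                 baseline = baseline, n_blanks = as.integer(n_blanks),
                 seed = as.integer(seed)),
            class = "mx_design")
}

#' Reference two-channel five-class design
#'
#' The default study layout the package is validated on: a control class
#' and four disease-like classes measured on two excitation channels
#' ("532nm", "785nm"), 3 samples per class and 30 spectra per sample (450
#' spectra per channel). Backbone peaks sit at common tissue Raman bands;
#' the 532 nm channel carries resonantly enhanced metalloprotein-like bands
#' (747, 1367, 1587 cm^-1) that are weak at 785 nm. Class D1 differs from
#' control only on the 532 nm channel, D2 only on the 785 nm channel, and
#' D3/D4 carry small overlapping changes on both channels, making them the
#' hardest pair to distinguish.
#'
#' @param n_points Points per channel axis (default 1024, 600-1750 cm^-1).
#' @param n_samples,n_spectra Per-class sample count and per-sample
#'   spectrum count.
#' @param noise_sd Additive noise SD.
#' @param effect_scale Multiplier on all class-specific `delta` values
#'   (1 = default effects, about 5-17x the noise SD).
#' @param seed Default generation seed.
#' @return An `mx_design`.
#' @export
default_design <- function(n_points = 1024L, n_samples = 3L, n_spectra = 30L,
                           noise_sd = 0.02, effect_scale = 1, seed = 20260926L) {
  channels <- list(
    `532nm` = list(from = 600, to = 1750, n = n_points),
    `785nm` = list(from = 600, to = 1750, n = n_points)
  )
  backbone <- tibble::tribble(
    ~center, ~fwhm, ~amp_532nm, ~amp_785nm, ~rho,
    747,  12, 0.80, 0.10, 0.25,
    880,  14, 0.30, 0.70, 0.40,
    1003, 10, 0.60, 1.00, 0.10,
    1250, 20, 0.30, 0.60, 0.60,
    1367, 12, 0.50, 0.10, 0.30,
    1440, 18, 0.40, 0.80, 0.75,
    1587, 12, 0.70, 0.15, 0.30,
    1660, 22, 0.50, 1.00, 0.50
  )
  class_peaks <- tibble::tribble(
    ~class, ~channel, ~center, ~fwhm, ~delta, ~rho,
    "D1", "532nm",  747, 12,  0.35, 0.25,
    "D1", "532nm", 1587, 12,  0.30, 0.30,
    "D1", "532nm", 1367, 12, -0.15, 0.30,
    "D2", "785nm", 1130, 14,  0.35, 0.40,
    "D2", "785nm", 1320, 14,  0.25, 0.50,
    "D2", "785nm", 1660, 22, -0.15, 0.50,
    "D3", "532nm", 1003, 10,  0.15, 0.10,
    "D3", "785nm", 1450, 18,  0.15, 0.60,
    "D4", "532nm", 1003, 10,  0.12, 0.10,
    "D4", "785nm", 1450, 18,  0.12, 0.60,
    "D4", "785nm",  830, 14,  0.10, 0.40
  )
  class_peaks$delta <- class_peaks$delta * effect_scale
  synthetic_design(channels, backbone, class_peaks,
                   n_samples = n_samples, n_spectra = n_spectra,
                   noise_sd = noise_sd, seed = seed)
}

channel_axis <- function(ax) seq(ax$from, ax$to, length.out = ax$n)

design_peak_table <- function(design, tag) {
  bb <- design$backbone
  base <- tibble::tibble(center = bb$center, fwhm = bb$fwhm,
                         amp = bb[[paste0("amp_", tag)]], rho = bb$rho,
                         class = NA_character_)
  cp <- design$class_peaks[design$class_peaks$channel == tag, ]
  extra <- tibble::tibble(center = cp$center, fwhm = cp$fwhm, amp = cp$delta,
                          rho = cp$rho, class = cp$class)
  dplyr::bind_rows(base, extra)
}

#' Generate synthetic spectra from a design
#'
#' Every spectrum is a sum of Lorentzian peaks (backbone plus the class's
#' planted changes), each scaled by that sample's lognormal amplitude
#' multiplier, plus a broad per-spectrum-scaled baseline and white Gaussian
#' noise. Blanks are baseline-only acquisitions. With `polarized = TRUE`,
#' parallel and perpendicular variants scale each peak by
#' \eqn{1/(1+\rho)} and \eqn{\rho/(1+\rho)}. Identical seeds give
#' bit-identical output.
#'
#' @param design An `mx_design`.
#' @param seed Integer seed (defaults to the design's).
#' @param polarized Emit parallel/perpendicular dataset pairs per channel
#'   instead of unpolarized datasets.
#' @return A list: `channels` (named list of raw [spectral_dataset()]s, or
#'   of `list(parallel=, perpendicular=)` pairs), `blanks` (named list of
#'   blank [raman_spectrum()] lists per channel), `truth` (tibble of planted
#'   changes: `class`, `channel`, `center`, `direction`, `wn_lo`, `wn_hi`),
#'   and `design`.
#' @export
generate_spectra <- function(design, seed = design$seed, polarized = FALSE) {
  stopifnot(inherits(design, "mx_design"))
  set.seed(seed)
  classes <- design$classes
  n_cls <- length(classes)
  meta <- tidyr::expand_grid(class_label = classes,
                             sample_no = seq_len(design$n_samples),
                             acquisition_index = seq_len(design$n_spectra)) |>
    dplyr::mutate(sample_id = sprintf("S%s_%d", .data$class_label, .data$sample_no)) |>
    dplyr::select("class_label", "sample_id", "acquisition_index")
  samples <- unique(meta$sample_id)

  tags <- names(design$channels)
  peak_tabs <- lapply(tags, design_peak_table, design = design)
  names(peak_tabs) <- tags

  # patient-level effects: one multiplier per (sample, channel, peak)
  mult <- lapply(tags, function(tag) {
    matrix(stats::rlnorm(length(samples) * nrow(peak_tabs[[tag]]),
                         0, design$sample_sdlog),
           nrow = length(samples),
           dimnames = list(samples, NULL))
  })
  names(mult) <- tags

  bl <- design$baseline
  baseline_shape <- function(x) {
    t <- (x - min(x)) / diff(range(x))
    1 + bl$tilt * t - 0.5 * bl$tilt * t^2 +
      exp(-((x - bl$hump_center) / bl$hump_width)^2)
  }

  gen_channel <- function(tag, pol) {
    ax <- channel_axis(design$channels[[tag]])
    pk <- peak_tabs[[tag]]
    pol_f <- switch(pol, none = rep(1, nrow(pk)),
                    parallel = 1 / (1 + pk$rho),
                    perpendicular = pk$rho / (1 + pk$rho))
    shapes <- vapply(seq_len(nrow(pk)), function(i) {
      lorentz(ax, pk$center[i], pk$fwhm[i])
    }, numeric(length(ax)))                      # n_points x n_peaks
    bshape <- baseline_shape(ax)
    m <- matrix(0, nrow(meta), length(ax))
    for (r in seq_len(nrow(meta))) {
      cl <- meta$class_label[r]
      active <- is.na(pk$class) | pk$class == cl
      amps <- pk$amp * mult[[tag]][meta$sample_id[r], ] * pol_f
      amps[!active] <- 0
      bscale <- bl$scale * stats::rlnorm(1, 0, bl$sdlog)
      m[r, ] <- drop(shapes %*% amps) + bscale * bshape +
        stats::rnorm(length(ax), 0, design$noise_sd)
    }
    ch_tag <- if (pol == "none") tag else
      paste0(tag, c(parallel = "-par", perpendicular = "-perp")[pol])
    spectral_dataset(m, meta, channel = ch_tag, wavenumber = ax)
  }

  gen_blanks <- function(tag) {
    ax <- channel_axis(design$channels[[tag]])
    bshape <- baseline_shape(ax)
    lapply(seq_len(design$n_blanks), function(i) {
      bscale <- bl$scale * stats::rlnorm(1, 0, bl$sdlog)
      raman_spectrum(ax, bscale * bshape + stats::rnorm(length(ax), 0, design$noise_sd),
                     excitation_nm = suppressWarnings(as.numeric(sub("nm$", "", tag))),
                     sample_id = sprintf("blank_%s_%d", tag, i),
                     class_label = "blank", acquisition_index = i)
    })
  }

  channels <- lapply(tags, function(tag) {
    if (polarized) {
      list(parallel = gen_channel(tag, "parallel"),
           perpendicular = gen_channel(tag, "perpendicular"))
    } else {
      gen_channel(tag, "none")
    }
  })
  names(channels) <- tags
  blanks <- lapply(tags, gen_blanks)
  names(blanks) <- tags

  truth <- design$class_peaks |>
    dplyr::transmute(class = .data$class, channel = .data$channel,
                     center = .data$center,
                     direction = ifelse(.data$delta > 0, 1L, -1L),
                     wn_lo = .data$center - .data$fwhm,
                     wn_hi = .data$center + .data$fwhm)

  list(channels = channels, blanks = blanks, truth = truth, design = design)
}

#' Map planted ground truth onto a dataset's columns
#'
#' Resolves each planted peak of a truth table to the matching dataset
#' columns: the column nearest the peak center (`col_center`) and the run
#' of columns within one FWHM (`col_lo`, `col_hi`), per channel block.
#' Peaks on channels absent from the dataset are dropped.
#'
#' @param truth The `truth` tibble from [generate_spectra()].
#' @param d A [spectral_dataset()] (single-channel or MX).
#' @return The truth tibble with `col_lo`, `col_hi`, `col_center` added.
#' @export
truth_columns <- function(truth, d) {
  cm <- sd_colmeta(d)
  purrr::pmap_dfr(truth, function(class, channel, center, direction, wn_lo, wn_hi) {
    idx <- which(cm$channel == channel | startsWith(cm$channel, paste0(channel, "#")))
    if (!length(idx)) return(NULL)
    inside <- idx[cm$wavenumber[idx] >= wn_lo & cm$wavenumber[idx] <= wn_hi]
    tibble::tibble(class = class, channel = channel, center = center,
                   direction = direction, wn_lo = wn_lo, wn_hi = wn_hi,
                   col_lo = min(inside), col_hi = max(inside),
                   col_center = idx[which.min(abs(cm$wavenumber[idx] - center))])
  })
}
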