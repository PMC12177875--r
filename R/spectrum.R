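#' Construct a single Raman spectrum
#'
#' A `raman_spectrum` is a two-column tibble (`wavenumber`, `intensity`)
#' carrying acquisition metadata as attributes. The wavenumber axis is kept
#' strictly increasing; inputs stored in descending instrument order are
#' silently reordered.
#'
#' @param wavenumber Numeric vector of Raman shifts (cm^-1).
#' @param intensity Numeric vector of detector intensities, same length.
#' @param excitation_nm Excitation laser wavelength in nm (e.g. 532, 785), or
#'   `NA` for derived signals.
#' @param polarization One of `"unpolarized"`, `"parallel"`, `"perpendicular"`.
#' @param signal_kind One of `"raman"`, `"autofluorescence"`,
#'   `"depolarization_ratio"`.
#' @param sample_id,class_label,acquisition_index Per-acquisition metadata.
#'
#' @return A tibble of class `raman_spectrum`.
#' @export
#' @examples
#' s <- raman_spectrum(c(1000, 1001, 1002), c(5, 6, 5), excitation_nm = 532,
#'                     sample_id = "S1", class_label = "control")
#' s
raman_spectrum <- function(wavenumber, intensity,
                           excitation_nm = NA_real_,
                           polarization = c("unpolarized", "parallel", "perpendicular"),
                           signal_kind = c("raman", "autofluorescence", "depolarization_ratio"),
                           sample_id = NA_character_,
                           class_label = NA_character_,
                           acquisition_index = NA_integer_) {
  polarization <- match.arg(polarization)
  signal_kind <- match.arg(signal_kind)
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity)) {
    stop("`wavenumber` and `intensity` must have the same length", call. = FALSE)
  }
  if (length(wavenumber) < 2) {
    stop("a spectrum needs at least 2 points", call. = FALSE)
  }
  if (anyNA(wavenumber) || anyNA(intensity)) {
    stop("spectrum values must not contain NA", call. = FALSE)
  }
  if (is.unsorted(wavenumber, strictly = TRUE)) {
    o <- order(wavenumber)
    wavenumber <- wavenumber[o]
    intensity <- intensity[o]
    if (anyDuplicated(wavenumber)) {
      stop("wavenumber axis must be strictly increasing (duplicated values found)",
           call. = FALSE)
    }
  }
  out <- tibble::tibble(wavenumber = wavenumber, intensity = intensity)
  attr(out, "excitation_nm") <- as.numeric(excitation_nm)
  attr(out, "polarization") <- polarization
  attr(out, "signal_kind") <- signal_kind
  attr(out, "sample_id") <- as.character(sample_id)
  attr(out, "class_label") <- as.character(class_label)
  attr(out, "acquisition_index") <- as.integer(acquisition_index)
  class(out) <- c("raman_spectrum", class(out))
  out
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d points, %.1f-%.1f cm^-1 | %s | %s nm | %s\n",
              nrow(x), min(x$wavenumber), max(x$wavenumber),
              attr(x, "signal_kind"),
              format(attr(x, "excitation_nm")),
              attr(x, "polarization")))
  cat(sprintf("  sample=%s class=%s acq=%s\n",
              attr(x, "sample_id"), attr(x, "class_label"),
              format(attr(x, "acquisition_index"))))
  invisible(x)
}

spectrum_meta <- function(s) {
  list(excitation_nm = attr(s, "excitation_nm"),
       polarization = attr(s, "polarization"),
       signal_kind = attr(s, "signal_kind"),
       sample_id = attr(s, "sample_id"),
       class_label = attr(s, "class_label"),
       acquisition_index = attr(s, "acquisition_index"))
}

# rebuild a spectrum from an existing one, replacing values
spectrum_with <- function(s, wavenumber = s$wavenumber, intensity,
                          signal_kind = attr(s, "signal_kind")) {
  m <- spectrum_meta(s)
  raman_spectrum(wavenumber, intensity,
                 excitation_nm = m$excitation_nm,
                 polarization = m$polarization,
                 signal_kind = signal_kind,
                 sample_id = m$sample_id,
                 class_label = m$class_label,
                 acquisition_index = m$acquisition_index)
}

#' Read a two-column spectrum file
#'
#' Parses plain-text instrument exports with two numeric columns
#' (wavenumber, intensity). Tab, comma and whitespace delimiters are all
#' accepted, lines starting with `#` are comments, and descending-axis
#' exports are reordered to an ascending axis.
#'
#' @param path Path to the text file.
#' @param ... Metadata passed on to [raman_spectrum()] (`sample_id`,
#'   `class_label`, `excitation_nm`, ...).
#'
#' @return A [raman_spectrum()].
#' @export
read_spectrum <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) < 2) {
    stop("malformed spectrum file (fewer than 2 data points): ", path, call. = FALSE)
  }
  parts <- strsplit(trimws(lines[idx]), "[,\t ]+")
  bad <- which(lengths(parts) < 2)
  if (length(bad)) {
    stop(sprintf("parse error in %s at line %d: expected two numeric columns",
                 path, idx[bad[1]]), call. = FALSE)
  }
  wn <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  it <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  nan <- which(is.na(wn) | is.na(it))
  if (length(nan)) {
    stop(sprintf("parse error in %s at line %d: non-numeric value",
                 path, idx[nan[1]]), call. = FALSE)
  }
  raman_spectrum(wn, it, ...)
}

#' Write a spectrum to a two-column text file
#'
#' @param s A [raman_spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  utils::write.table(data.frame(s$wavenumber, s$intensity), path,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Resample a spectrum onto a target wavenumber axis
#'
#' Linear interpolation; the target axis must lie within the source axis
#' (extrapolation is refused). Points shared with the source axis are
#' reproduced exactly, and metadata is preserved.
#'
#' @param s A [raman_spectrum()].
#' @param target_axis Strictly increasing wavenumbers within the source range.
#' @return A [raman_spectrum()] on `target_axis`.
#' @export
resample_to_axis <- function(s, target_axis) {
  target_axis <- as.numeric(target_axis)
  if (min(target_axis) < min(s$wavenumber) || max(target_axis) > max(s$wavenumber)) {
    stop(sprintf("target axis [%g, %g] outside source range [%g, %g]",
                 min(target_axis), max(target_axis),
                 min(s$wavenumber), max(s$wavenumber)), call. = FALSE)
  }
  y <- stats::approx(s$wavenumber, s$intensity, xout = target_axis,
                     method = "linear", ties = "ordered")$y
  spectrum_with(s, wavenumber = target_axis, intensity = y)
}
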