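#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

meta_cols <- c("class_label", "sample_id", "acquisition_index")

make_var_names <- function(channel, wavenumber) {
  paste0(channel, "|", formatC(wavenumber, format = "g", digits = 10))
}

#' Construct a spectral dataset
#'
#' A `spectral_dataset` is a wide tibble: one row per spectrum, leading
#' metadata columns (`class_label`, `sample_id`, `acquisition_index`) and one
#' numeric column per spectral variable. The per-variable channel tag and
#' wavenumber live in the `col_meta` attribute (a tibble with columns
#' `column`, `channel`, `wavenumber`); within each channel block wavenumbers
#' are strictly increasing. This is the container every analysis function in
#' the package takes first and pipes onward.
#'
#' @param matrix Numeric matrix, `n_spectra x n_variables`.
#' @param row_meta Data frame with columns `class_label`, `sample_id`,
#'   `acquisition_index` and `nrow(matrix)` rows.
#' @param channel Single channel tag (e.g. `"532nm"`) when `col_meta` is not
#'   given.
#' @param wavenumber Wavenumber per column when `col_meta` is not given.
#' @param col_meta Tibble with columns `channel` and `wavenumber`, one row per
#'   matrix column; overrides `channel`/`wavenumber`.
#' @param signal_kind Signal type tag for the whole dataset.
#'
#' @return A tibble of class `spectral_dataset`.
#' @export
spectral_dataset <- function(matrix, row_meta, channel = "ch1",
                             wavenumber = NULL, col_meta = NULL,
                             signal_kind = "raman", .check_monotone = TRUE) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  row_meta <- tibble::as_tibble(row_meta)
  if (!all(meta_cols %in% names(row_meta))) {
    stop("row_meta needs columns: ", paste(meta_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(row_meta) != nrow(matrix)) {
    stop("row_meta and matrix row counts differ", call. = FALSE)
  }
  if (is.null(col_meta)) {
    if (is.null(wavenumber)) stop("supply `wavenumber` or `col_meta`", call. = FALSE)
    col_meta <- tibble::tibble(channel = channel, wavenumber = as.numeric(wavenumber))
  }
  col_meta <- tibble::as_tibble(col_meta)
  if (nrow(col_meta) != ncol(matrix)) {
    stop("col_meta rows must match matrix columns", call. = FALSE)
  }
  if (.check_monotone) {
    for (ch in unique(col_meta$channel)) {
      wn <- col_meta$wavenumber[col_meta$channel == ch]
      if (is.unsorted(wn, strictly = TRUE)) {
        stop("wavenumbers must be strictly increasing within channel block '",
             ch, "'", call. = FALSE)
      }
    }
  }
  # one class per sample
  map <- unique(row_meta[, c("sample_id", "class_label")])
  if (anyDuplicated(map$sample_id)) {
    dup <- map$sample_id[duplicated(map$sample_id)][1]
    stop("metadata conflict: sample '", dup,
         "' is assigned more than one class label", call. = FALSE)
  }
  col_meta$column <- make_var_names(col_meta$channel, col_meta$wavenumber)
  if (anyDuplicated(col_meta$column)) {
    stop("duplicate (channel, wavenumber) variables", call. = FALSE)
  }
  colnames(matrix) <- col_meta$column
  out <- dplyr::bind_cols(
    row_meta[, meta_cols],
    tibble::as_tibble(matrix, .name_repair = "minimal")
  )
  attr(out, "col_meta") <- col_meta[, c("column", "channel", "wavenumber")]
  attr(out, "signal_kind") <- signal_kind
  class(out) <- c("spectral_dataset", class(out))
  out
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cm <- sd_colmeta(x)
  blocks <- channel_blocks(x)
  cat(sprintf("<spectral_dataset> %d spectra x %d variables [%s]\n",
              nrow(x), nrow(cm), attr(x, "signal_kind")))
  for (i in seq_len(nrow(blocks))) {
    cat(sprintf("  block %s: %d variables, %.1f-%.1f cm^-1\n",
                blocks$channel[i], blocks$n_vars[i],
                blocks$wn_min[i], blocks$wn_max[i]))
  }
  cat(sprintf("  classes: %s\n",
              paste(sort(unique(x$class_label)), collapse = ", ")))
  invisible(x)
}

#' Accessors for spectral datasets
#'
#' `sd_matrix()` returns the intensity block as a numeric matrix,
#' `sd_meta()` the per-spectrum metadata tibble, `sd_colmeta()` the
#' per-variable map (column name, channel, wavenumber), and
#' `channel_blocks()` a one-row-per-channel summary of the block layout.
#'
#' @param d A [spectral_dataset()].
#' @return A matrix or tibble as described.
#' @export
sd_matrix <- function(d) {
  cm <- sd_colmeta(d)
  m <- as.matrix(as.data.frame(d, check.names = FALSE)[, cm$column, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' @rdname sd_matrix
#' @export
sd_meta <- function(d) {
  tibble::as_tibble(as.data.frame(d, check.names = FALSE)[, meta_cols])
}

#' @rdname sd_matrix
#' @export
sd_colmeta <- function(d) {
  cm <- attr(d, "col_meta")
  if (is.null(cm)) stop("not a spectral_dataset (missing col_meta)", call. = FALSE)
  cm
}

#' @rdname sd_matrix
#' @export
channel_blocks <- function(d) {
  cm <- sd_colmeta(d)
  cm |>
    dplyr::mutate(.block = cumsum(c(TRUE, .data$channel[-1] != .data$channel[-nrow(cm)]))) |>
    dplyr::group_by(.data$.block, .data$channel) |>
    dplyr::summarise(n_vars = dplyr::n(),
                     wn_min = min(.data$wavenumber),
                     wn_max = max(.data$wavenumber), .groups = "drop") |>
    dplyr::select(!".block")
}

# rebuild a dataset from a template with new values / column map
dataset_with <- function(d, matrix = sd_matrix(d), row_meta = sd_meta(d),
                         col_meta = sd_colmeta(d),
                         signal_kind = attr(d, "signal_kind")) {
  spectral_dataset(matrix, row_meta,
                   col_meta = col_meta[, c("channel", "wavenumber")],
                   signal_kind = signal_kind, .check_monotone = FALSE)
}

n_variables <- function(d) nrow(sd_colmeta(d))

channel_tag <- function(excitation_nm, polarization = "unpolarized",
                        signal_kind = "raman") {
  base <- if (is.na(excitation_nm)) signal_kind else paste0(format(excitation_nm), "nm")
  suffix <- switch(polarization, parallel = "-par", perpendicular = "-perp", "")
  kind <- switch(signal_kind, autofluorescence = "-af", depolarization_ratio = "-rho", "")
  paste0(base, suffix, kind)
}

#' Assemble aligned spectra into a dataset
#'
#' All spectra are resampled (linearly) onto the axis of the densest member
#' restricted to the common overlap range, then stacked into one matrix with
#' rows ordered by (class_label, sample_id, acquisition_index). All inputs
#' must share the same signal kind and acquisition configuration; a sample
#' carrying two different class labels is a metadata conflict.
#'
#' @param spectra List of [raman_spectrum()] objects.
#' @return A [spectral_dataset()].
#' @export
assemble_dataset <- function(spectra) {
  if (!length(spectra)) stop("no spectra to assemble", call. = FALSE)
  kinds <- unique(vapply(spectra, function(s) attr(s, "signal_kind"), ""))
  if (length(kinds) > 1) {
    stop("spectra mix signal kinds: ", paste(kinds, collapse = ", "), call. = FALSE)
  }
  tags <- unique(vapply(spectra, function(s) {
    channel_tag(attr(s, "excitation_nm"), attr(s, "polarization"), attr(s, "signal_kind"))
  }, ""))
  if (length(tags) > 1) {
    stop("spectra mix acquisition configurations: ",
         paste(tags, collapse = ", "), call. = FALSE)
  }
  lo <- max(vapply(spectra, function(s) min(s$wavenumber), 0))
  hi <- min(vapply(spectra, function(s) max(s$wavenumber), 0))
  if (lo >= hi) stop("spectra axes do not overlap", call. = FALSE)
  densest <- which.max(vapply(spectra, nrow, 0L))
  axis <- spectra[[densest]]$wavenumber
  axis <- axis[axis >= lo & axis <= hi]
  if (length(axis) < 2) stop("common axis has fewer than 2 points", call. = FALSE)
  rows <- lapply(spectra, function(s) resample_to_axis(s, axis)$intensity)
  meta <- dplyr::bind_rows(lapply(spectra, function(s) {
    tibble::tibble(class_label = attr(s, "class_label"),
                   sample_id = attr(s, "sample_id"),
                   acquisition_index = attr(s, "acquisition_index"))
  }))
  o <- order(meta$class_label, meta$sample_id, meta$acquisition_index)
  spectral_dataset(do.call(rbind, rows)[o, , drop = FALSE], meta[o, ],
                   channel = tags, wavenumber = axis, signal_kind = kinds)
}

#' Write / read a spectral dataset as CSV
#'
#' The on-disk format is a plain CSV with a two-row header: row 1 carries the
#' channel tag of each variable column, row 2 its wavenumber; the three
#' leading columns hold the row metadata. The round trip is lossless for
#' metadata and exact to double-precision printing for intensities.
#'
#' @param d A [spectral_dataset()].
#' @param path File path.
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns the [spectral_dataset()].
#' @export
write_dataset <- function(d, path) {
  cm <- sd_colmeta(d)
  h1 <- paste(c(meta_cols, cm$channel), collapse = ",")
  h2 <- paste(c("", "", "", formatC(cm$wavenumber, format = "g", digits = 17)),
              collapse = ",")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#signal_kind=", attr(d, "signal_kind")), h1, h2), con)
  m <- sd_matrix(d)
  meta <- sd_meta(d)
  if (nrow(d)) {
    body <- paste(meta$class_label, meta$sample_id, meta$acquisition_index,
                  apply(m, 1, function(r) {
                    paste(formatC(r, format = "g", digits = 17), collapse = ",")
                  }),
                  sep = ",")
    writeLines(body, con)
  }
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || !startsWith(lines[1], "#signal_kind=")) {
    stop("format error: not a spectral dataset CSV: ", path, call. = FALSE)
  }
  kind <- sub("^#signal_kind=", "", lines[1])
  h1 <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  h2 <- strsplit(lines[3], ",", fixed = TRUE)[[1]]
  if (length(h1) != length(h2) || length(h1) < length(meta_cols) + 1 ||
      !identical(h1[1:3], meta_cols)) {
    stop("format error: malformed dataset header in ", path, call. = FALSE)
  }
  nv <- length(h1) - 3L
  channel <- h1[-(1:3)]
  wn <- suppressWarnings(as.numeric(h2[-(1:3)]))
  if (anyNA(wn)) stop("format error: non-numeric wavenumber header", call. = FALSE)
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  if (!length(body)) {
    m <- matrix(numeric(), 0, nv)
    meta <- tibble::tibble(class_label = character(), sample_id = character(),
                           acquisition_index = integer())
  } else {
    parts <- strsplit(body, ",", fixed = TRUE)
    if (any(lengths(parts) != length(h1))) {
      bad <- which(lengths(parts) != length(h1))[1]
      stop(sprintf("format error: row %d has %d fields, expected %d",
                   bad, lengths(parts)[bad], length(h1)), call. = FALSE)
    }
    tab <- do.call(rbind, parts)
    m <- matrix(suppressWarnings(as.numeric(tab[, -(1:3), drop = FALSE])),
                nrow = nrow(tab))
    if (anyNA(m)) stop("format error: non-numeric intensity value", call. = FALSE)
    meta <- tibble::tibble(class_label = tab[, 1], sample_id = tab[, 2],
                           acquisition_index = as.integer(tab[, 3]))
  }
  spectral_dataset(m, meta,
                   col_meta = tibble::tibble(channel = channel, wavenumber = wn),
                   signal_kind = kind)
}
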