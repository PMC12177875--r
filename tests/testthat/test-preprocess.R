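mkspec <- function(y, x = seq_along(y)) raman_spectrum(x, y)

test_that("subtract_background removes the mean blank", {
  s <- mkspec(c(5, 5, 5))
  b1 <- mkspec(c(1, 1, 1)); b2 <- mkspec(c(3, 3, 3))
  expect_equal(subtract_background(s, list(b1, b2))$intensity, c(3, 3, 3))
  expect_equal(subtract_background(s, list(s))$intensity, c(0, 0, 0))
  expect_error(subtract_background(s, list()), "missing blank")
  far <- raman_spectrum(c(100, 200), c(1, 1))
  expect_error(subtract_background(s, list(far)), "outside")
})

test_that("wavelet denoising is a near-no-op on smooth signals and reduces noise on noisy ones", {
  n <- 1024
  x <- seq(0, 1, length.out = n)
  trend <- 5 + 3 * x - 2 * x^2 + x^3

  const <- wavelet_denoise(rep(4, 128), levels = 6)
  expect_equal(const, rep(4, 128), tolerance = 1e-12)

  # when the noise-sd estimate is zero (majority of finest-level detail
  # coefficients are zero) thresholding is an exact no-op
  flat_peak <- rep(2, n); flat_peak[500:520] <- 2 + seq(0, 4, length.out = 21)
  expect_equal(wavelet_denoise(flat_peak, levels = 6), flat_peak,
               tolerance = 1e-12)

  # on a smooth polynomial the estimated sigma is tiny but nonzero: the
  # universal threshold shrinks detail coefficients by O(sigma), so the
  # output tracks the input to ~0.1% of signal RMS
  smooth_out <- wavelet_denoise(trend, levels = 6)
  expect_lt(sqrt(mean((smooth_out - trend)^2)), 1e-3 * sqrt(mean(trend^2)))

  set.seed(7)
  noisy <- trend + rnorm(n, 0, 0.1)
  den <- wavelet_denoise(noisy, levels = 6)
  rms_in <- sqrt(mean((noisy - trend)^2))
  rms_out <- sqrt(mean((den - trend)^2))
  expect_lt(rms_out, rms_in)

  expect_error(wavelet_denoise(rep(1, 32), levels = 6), "too short")
})

test_that("fluorescence removal recovers a pure polynomial and tracks baselines under peaks", {
  x <- seq(600, 1750, length.out = 512)
  t <- (x - 600) / 1150
  poly5 <- 2 + t - 0.5 * t^2 + 0.2 * t^3 - 0.1 * t^4 + 0.05 * t^5
  s <- raman_spectrum(x, poly5)
  res <- remove_fluorescence(s, order = 5)
  expect_lt(max(abs(res$raman$intensity)), 1e-8 * max(abs(poly5)))
  expect_equal(res$fluorescence$intensity, poly5, tolerance = 1e-8)
  expect_identical(attr(res$fluorescence, "signal_kind"), "autofluorescence")

  # narrow peak excluded by iterative refit: baseline at the peak center
  # stays within 5% of the known polynomial value there
  peak_c <- 1100
  peak <- 3 * exp(-((x - peak_c) / 8)^2)
  res2 <- remove_fluorescence(raman_spectrum(x, poly5 + peak), order = 5)
  i <- which.min(abs(x - peak_c))
  expect_lt(abs(res2$fluorescence$intensity[i] - poly5[i]) / abs(poly5[i]), 0.05)

  # reconstruction is exact
  recon <- res2$raman$intensity + res2$fluorescence$intensity
  expect_equal(recon, poly5 + peak, tolerance = 1e-12)

  expect_error(remove_fluorescence(mkspec(c(1, 2, 3)), order = 3), "order")
})

test_that("rubberband anchoring zeroes endpoints, stays non-negative, zeroes convex bowls, keeps peak heights", {
  x <- seq_len(101)
  bowl <- (x - 51)^2 / 100
  out <- rubberband_anchor(raman_spectrum(x, bowl))
  expect_equal(out$intensity, rep(0, 101), tolerance = 1e-12)

  ramp <- 0.5 * x
  peak <- 7 * exp(-((x - 50) / 4)^2)
  out2 <- rubberband_anchor(raman_spectrum(x, ramp + peak))
  expect_identical(out2$intensity[c(1, 101)], c(0, 0))
  expect_gt(min(out2$intensity), -1e-12)
  expect_equal(max(out2$intensity), max(peak), tolerance = 1e-9)

  set.seed(1)
  rnd <- rubberband_anchor(mkspec(rnorm(64)))
  expect_identical(rnd$intensity[c(1, 64)], c(0, 0))
  expect_gt(min(rnd$intensity), -1e-12)
})

test_that("vector normalization yields unit norm, is idempotent and scale-invariant", {
  s <- mkspec(c(3, 4))
  expect_equal(vector_normalize(s)$intensity, c(0.6, 0.8))
  twice <- vector_normalize(vector_normalize(s))
  expect_equal(twice$intensity, c(0.6, 0.8), tolerance = 1e-12)
  set.seed(3)
  v <- rnorm(50)
  expect_equal(vector_normalize(v * 17), vector_normalize(v), tolerance = 1e-12)
  expect_equal(sqrt(sum(vector_normalize(v)^2)), 1, tolerance = 1e-12)
  expect_error(vector_normalize(mkspec(c(0, 0))), "degenerate")
})

test_that("column standardization gives mean 0 / sd 1 and zeroes constant columns with a warning", {
  m <- cbind(c(1, 2, 3), c(5, 5, 5), rnorm(3))
  d <- spectral_dataset(m, tibble::tibble(class_label = "c",
                                          sample_id = paste0("s", 1:3),
                                          acquisition_index = 1:3),
                        wavenumber = c(1, 2, 3))
  expect_warning(z <- standardize_columns(d), "zero-variance")
  zm <- sd_matrix(z)
  expect_equal(zm[, 1], c(-1, 0, 1))
  expect_equal(zm[, 2], c(0, 0, 0))
  expect_lt(max(abs(colMeans(zm))), 1e-12)
  expect_equal(apply(zm[, c(1, 3)], 2, sd), c(1, 1), tolerance = 1e-12, ignore_attr = TRUE)
  one <- spectral_dataset(m[1, , drop = FALSE],
                          tibble::tibble(class_label = "c", sample_id = "s1",
                                         acquisition_index = 1L),
                          wavenumber = c(1, 2, 3))
  expect_error(standardize_columns(one), "at least 2")
})

test_that("despiking replaces isolated cosmic-ray points with the acquisition median", {
  set.seed(11)
  m <- matrix(rnorm(10 * 64), 10, 64)
  m[3, 20] <- 50  # cosmic ray
  d <- spectral_dataset(m, tibble::tibble(class_label = "c", sample_id = "s1",
                                          acquisition_index = 1:10),
                        wavenumber = seq_len(64))
  out <- sd_matrix(despike_acquisitions(d))
  expect_lt(out[3, 20], 5)
  untouched <- abs(out - m) > 0
  expect_lt(mean(untouched), 0.02)  # only isolated points altered
})

test_that("the full pipeline yields unit-norm, end-anchored fingerprints and is deterministic but not idempotent", {
  sim <- generate_spectra(small_design(n_points = 128, n_spectra = 6), seed = 5)
  d <- sim$channels[["532nm"]]
  res <- preprocess_dataset(d, sim$blanks[["532nm"]],
                            preprocess_config(wavelet_levels = 5))
  fp <- sd_matrix(res$fingerprint)
  expect_equal(sqrt(rowSums(fp^2)), rep(1, nrow(fp)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(fp[, 1]), rep(0, nrow(fp)))
  expect_equal(unname(fp[, ncol(fp)]), rep(0, nrow(fp)))
  expect_equal(dim(sd_matrix(res$autofluorescence)), dim(fp))

  # determinism: bit-identical on repeat
  res2 <- preprocess_dataset(d, sim$blanks[["532nm"]],
                             preprocess_config(wavelet_levels = 5))
  expect_identical(sd_matrix(res2$fingerprint), fp)

  # no normalization when asked
  res3 <- preprocess_dataset(d, sim$blanks[["532nm"]],
                             preprocess_config(wavelet_levels = 5, normalize = "none"))
  expect_false(isTRUE(all.equal(sqrt(rowSums(sd_matrix(res3$fingerprint)^2)),
                                rep(1, nrow(fp)), check.attributes = FALSE)))

  # a second pass changes values (baseline refit on peaked input)
  second <- preprocess_dataset(res$fingerprint, list(
    raman_spectrum(sd_colmeta(d)$wavenumber, rep(0, 128))),
    preprocess_config(wavelet_levels = 5))
  expect_false(identical(sd_matrix(second$fingerprint), fp))

  expect_error(preprocess_dataset(d, sim$blanks[["532nm"]],
                                  preprocess_config(wavelet_levels = 10)),
               "invalid config")
})
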