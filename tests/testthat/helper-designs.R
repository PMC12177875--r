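# Shared fixtures: all synthetic, built in code at test time.

# fast reduced-scale variant of the reference design (shorter axis, fewer
# spectra per sample) used where a test's property does not depend on the
# full problem size
small_design <- function(n_points = 256L, n_spectra = 10L, ...) {
  default_design(n_points = n_points, n_spectra = n_spectra, ...)
}

# recovery fixture: one or two strong planted peaks per class at distinct
# centers away from backbone bands (every effect far above both the point
# noise and the sample-level amplitude spread), full study size
recovery_design <- function(n_points = 1024L, n_spectra = 30L) {
  channels <- list(`532nm` = list(from = 600, to = 1750, n = n_points),
                   `785nm` = list(from = 600, to = 1750, n = n_points))
  backbone <- tibble::tribble(
    ~center, ~fwhm, ~amp_532nm, ~amp_785nm, ~rho,
    880,  14, 0.30, 0.70, 0.40,
    1003, 10, 0.60, 1.00, 0.10,
    1250, 20, 0.30, 0.60, 0.60,
    1440, 18, 0.40, 0.80, 0.75,
    1660, 22, 0.50, 1.00, 0.50)
  class_peaks <- tibble::tribble(
    ~class, ~channel, ~center, ~fwhm, ~delta, ~rho,
    "R1", "532nm",  700, 12, 0.35, 0.3,
    "R1", "532nm", 1500, 12, 0.30, 0.3,
    "R1", "532nm",  850, 12, 0.30, 0.3,
    "R2", "785nm",  940, 12, 0.35, 0.3,
    "R2", "785nm", 1600, 12, 0.30, 0.3,
    "R3", "532nm", 1100, 12, 0.35, 0.3,
    "R3", "785nm",  750, 12, 0.30, 0.3,
    "R4", "532nm", 1330, 12, 0.30, 0.3,
    "R4", "785nm", 1180, 12, 0.35, 0.3)
  synthetic_design(channels, backbone, class_peaks, n_spectra = n_spectra)
}

# run the standard per-channel preprocessing and MX fusion for a design
sim_fingerprints <- function(design, seed) {
  sim <- generate_spectra(design, seed = seed)
  pp <- lapply(names(sim$channels), function(tag) {
    preprocess_dataset(sim$channels[[tag]], sim$blanks[[tag]])
  })
  names(pp) <- names(sim$channels)
  fp <- lapply(pp, `[[`, "fingerprint")
  list(sim = sim, fp = fp,
       af = lapply(pp, `[[`, "autofluorescence"),
       mx = mx_concatenate(unname(fp)))
}

# simple two-class dataset with one planted discriminative column,
# for unit tests that need labels but no spectroscopic structure
toy_dataset <- function(n_per_class = 10, n_vars = 8, effect = 3, seed = 42,
                        classes = c("a", "b")) {
  set.seed(seed)
  n <- n_per_class * length(classes)
  m <- matrix(rnorm(n * n_vars), n, n_vars)
  lab <- rep(classes, each = n_per_class)
  m[lab == classes[2], 1] <- m[lab == classes[2], 1] + effect
  spectral_dataset(m, tibble::tibble(
    class_label = lab,
    sample_id = paste0("s", seq_len(n)),
    acquisition_index = 1L
  ), channel = "ch1", wavenumber = seq_len(n_vars) * 10 + 500)
}

# brute-force exact two-sided rank-sum p-value by enumerating every
# assignment of the pooled observations to the two groups
exact_utest_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  na <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(n, na)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  mu <- na * (length(y)) / 2
  if (u_obs <= mu) {
    p <- 2 * mean(u_all <= u_obs)
  } else {
    p <- 2 * mean(u_all >= u_obs)
  }
  min(1, p)
}
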