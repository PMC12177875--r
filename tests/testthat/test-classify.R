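make_labeled <- function(m, y, samples = paste0("s", seq_len(nrow(m))),
                         acq = 1L) {
  spectral_dataset(m, tibble::tibble(class_label = y, sample_id = samples,
                                     acquisition_index = acq),
                   wavenumber = seq_len(ncol(m)) * 10)
}

test_that("first/middle/final splits partition every repeat at the 9:1 ratio", {
  fx <- generate_spectra(default_design(n_points = 128), seed = 2)
  d <- fx$channels[["532nm"]]
  sp <- make_splits(d)
  for (r in 1:3) {
    tr <- sp$row[sp$repeat_id == r & sp$set == "train"]
    te <- sp$row[sp$repeat_id == r & sp$set == "test"]
    expect_length(te, 45)   # 15 samples x 3 test spectra
    expect_length(tr, 405)
    expect_length(intersect(tr, te), 0)
    expect_setequal(c(tr, te), seq_len(450))
    # every sample contributes to both sets
    meta <- sd_meta(d)
    expect_setequal(meta$sample_id[te], unique(meta$sample_id))
    expect_setequal(meta$sample_id[tr], unique(meta$sample_id))
  }
  # the three repeats select first, middle, final acquisitions
  meta <- sd_meta(d)
  acq_sets <- lapply(1:3, function(r) {
    sort(unique(meta$acquisition_index[sp$row[sp$repeat_id == r & sp$set == "test"]]))
  })
  expect_equal(acq_sets[[1]], 1:3)
  expect_equal(acq_sets[[2]], 15:17)  # floor(30/2) - 1 .. + 1, 1-based
  expect_equal(acq_sets[[3]], 28:30)

  tiny <- make_labeled(matrix(rnorm(12), 3, 4), rep("a", 3),
                       samples = "s1", acq = 1:3)
  expect_error(make_splits(tiny), "more than 3")
  uneq <- make_labeled(matrix(rnorm(36), 9, 4), rep("a", 9),
                       samples = c(rep("s1", 5), rep("s2", 4)),
                       acq = c(1:5, 1:4))
  expect_error(make_splits(uneq), "unequal")
})

test_that("LDA separates well-separated Gaussians and matches MASS::lda on full-rank problems", {
  set.seed(17)
  n <- 100
  m <- rbind(matrix(rnorm(n * 4), n, 4),
             matrix(rnorm(n * 4, 10), n, 4))
  y <- rep(c("a", "b"), each = n)
  d <- make_labeled(m, y)
  fit <- train_lda(d, folds = 5, seed = 3)
  expect_equal(fit$cv_accuracy, 100)

  # pseudo-inverse LDA reduces to classical LDA when covariance is nonsingular
  skip_if_not_installed("MASS")
  set.seed(18)
  m2 <- rbind(matrix(rnorm(30 * 3), 30, 3),
              matrix(rnorm(30 * 3, 1.2), 30, 3),
              matrix(rnorm(30 * 3, -1), 30, 3))
  y2 <- rep(c("a", "b", "c"), each = 30)
  d2 <- make_labeled(m2, y2)
  fit2 <- train_lda(d2, folds = 5, seed = 3)
  mass_pred <- predict(MASS::lda(m2, grouping = y2), m2)$class
  expect_identical(as.character(predict(fit2, d2)), as.character(mass_pred))
})

test_that("label shuffling drops accuracy to the binomial chance band", {
  set.seed(23)
  n <- 250
  k <- 5
  m <- matrix(rnorm(n * 12), n, 12)
  y <- sample(rep(letters[1:k], each = n / k))
  d <- make_labeled(m, y)
  fit <- train_lda(d, folds = 5, seed = 2)
  p0 <- 1 / k
  band <- 3 * sqrt(p0 * (1 - p0) / n) * 100
  expect_lt(abs(fit$cv_accuracy - 100 * p0), band)
})

test_that("evaluation reports per-class accuracies and confusion rows summing to test counts", {
  set.seed(29)
  n <- 60
  m <- rbind(matrix(rnorm(n * 3), n, 3), matrix(rnorm(n * 3, 8), n, 3))
  y <- rep(c("a", "b"), each = n)
  d <- make_labeled(m, y)
  fit <- train_lda(d, folds = 5, seed = 1)
  ev <- evaluate_model(fit, d)
  expect_equal(ev$class_accuracy$accuracy, c(100, 100))
  expect_equal(unname(diag(ev$confusion)), c(n, n))
  expect_equal(unname(rowSums(ev$confusion)), c(n, n))
  # schema mismatch is refused
  d_bad <- make_labeled(m[, 1:2], y)
  expect_error(predict(fit, d_bad), "schema error")
})

test_that("duplicated-block (self-concatenated) data classifies like the original", {
  accs <- vapply(1:6, function(seed) {
    set.seed(seed + 100)
    n <- 90
    m <- cbind(matrix(rnorm(n * 6), n, 6))
    y <- rep(c("a", "b", "c"), each = n / 3)
    m[y == "b", 1] <- m[y == "b", 1] + 1.5
    m[y == "c", 4] <- m[y == "c", 4] + 1.5
    d <- make_labeled(m, y)
    dup <- make_labeled(cbind(m, m), y)
    c(train_lda(d, folds = 5, seed = seed)$cv_accuracy,
      train_lda(dup, folds = 5, seed = seed)$cv_accuracy)
  }, numeric(2))
  expect_lt(abs(mean(accs[2, ] - accs[1, ])), 2)  # within 2 percentage points
})

test_that("run_protocol compares configurations and Kruskal-Wallis post-hoc behaves correctly", {
  fx <- sim_fingerprints(small_design(n_points = 128, n_spectra = 8), seed = 6)
  pr <- run_protocol(list(ch1 = fx$fp[["532nm"]], mx = fx$mx), seed = 2)
  expect_equal(nrow(pr$accuracy), 2 * 3 * 5)  # config x repeat x class
  expect_true(all(pr$accuracy$test_accuracy >= 0 & pr$accuracy$test_accuracy <= 100))
  expect_setequal(pr$summary$config, c("ch1", "mx"))
  # determinism: identical configuration entered twice gives identical entries
  pr2 <- run_protocol(list(a = fx$mx, b = fx$mx), seed = 2)
  a <- pr2$accuracy[pr2$accuracy$config == "a", -1]
  b <- pr2$accuracy[pr2$accuracy$config == "b", -1]
  expect_equal(as.data.frame(a), as.data.frame(b))
  expect_equal(pr2$omnibus_p, 1)  # identical sets: H = 0

  # rank-sum oracle: disjoint sets give tiny raw p; Bonferroni caps at 1
  cmp <- compare_configs(list(lo = rnorm(15, 0), hi = rnorm(15, 100)))
  expect_lt(cmp$pairwise$p_raw[1], 0.001)
  cmp2 <- compare_configs(list(a = 1:15, b = 1:15 + 0.01, c = 1:15 - 0.01))
  expect_true(all(cmp2$pairwise$p_bonferroni <= 1))
  expect_equal(cmp2$pairwise$p_bonferroni,
               pmin(1, cmp2$pairwise$p_raw * 3))
  expect_error(compare_configs(list(a = 1:4, b = 1:5)), "equal length")
})
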