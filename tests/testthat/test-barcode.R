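test_that("per-wavenumber U-test matches the exhaustive exact rank-sum oracle for small groups", {
  set.seed(21)
  for (sizes in list(c(4, 4), c(5, 7), c(8, 8), c(3, 8))) {
    na <- sizes[1]; nb <- sizes[2]
    m <- matrix(rnorm((na + nb) * 5), na + nb, 5)
    m[(na + 1):(na + nb), 2] <- m[(na + 1):(na + nb), 2] + 2.5
    d <- spectral_dataset(m, tibble::tibble(
      class_label = rep(c("a", "b"), c(na, nb)),
      sample_id = paste0("s", seq_len(na + nb)),
      acquisition_index = 1L), wavenumber = 1:5 * 10)
    r <- rank_utest(d, "a", "b")
    for (j in 1:5) {
      p_oracle <- exact_utest_oracle(m[1:na, j], m[(na + 1):(na + nb), j])
      expect_equal(r$p_value[j], p_oracle, tolerance = 1e-9)
    }
    # agreement with the standard implementation as a second route
    for (j in c(1, 2)) {
      expect_equal(r$p_value[j],
                   wilcox.test(m[1:na, j], m[(na + 1):(na + nb), j],
                               exact = TRUE)$p.value, tolerance = 1e-12)
    }
  }
})

test_that("complete separation gives the exact minimal p and rank 1; identical columns give p = 1", {
  n <- 10
  m <- cbind(rep(0:1, each = n), rnorm(2 * n), rep(5, 2 * n))
  m[, 3] <- c(rnorm(n), rnorm(n))  # same distribution both classes
  m[, 3] <- rep(m[1:n, 3], 2)      # literally identical values across classes
  d <- spectral_dataset(m, tibble::tibble(
    class_label = rep(c("ctl", "dis"), each = n),
    sample_id = paste0("s", 1:(2 * n)), acquisition_index = 1L),
    wavenumber = c(10, 20, 30))
  r <- rank_utest(d, "ctl", "dis")
  # complete separation: two-sided exact p = 2 / choose(20, 10)
  expect_equal(r$p_value[1], 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(r$rank[1], 1L)
  expect_equal(r$p_value[3], 1)
  expect_equal(r$direction, ifelse(r$median_diff > 0, 1L, -1L))
  expect_setequal(r$rank, 1:3)
  expect_error(rank_utest(d, "ctl", "nope"), "label error")
})

test_that("region selection returns maximal disjoint significant runs seeded by rank", {
  # significance mask 0,1,1,1,0,1,0 with the top variable at position 3 and
  # the runner-up at position 6 -> regions [2..4] and [6..6]
  ranking <- tibble::tibble(
    col_index = 1:7, column = paste0("c", 1:7), channel = "ch1",
    wavenumber = 1:7 * 10,
    p_value = c(0.5, 0.04, 0.001, 0.03, 0.9, 0.01, 0.2),
    median_diff = c(0, 1, 2, 1, 0, 1.5, 0),
    direction = 1L)
  ranking$rank <- order(order(ranking$p_value))
  expect_warning(regs <- select_regions(ranking, n_regions = 3), "only 2 of 3")
  expect_equal(nrow(regs), 2)  # only two disjoint significant runs exist
  expect_equal(regs$start_col, c(2, 6))
  expect_equal(regs$end_col, c(4, 6))
  expect_equal(regs$seed_col, c(3, 6))

  # two top variables in one run: run chosen once, next region seeded outside
  ranking2 <- ranking
  ranking2$p_value <- c(0.5, 0.001, 0.002, 0.03, 0.9, 0.01, 0.2)
  ranking2$rank <- order(order(ranking2$p_value))
  regs2 <- select_regions(ranking2, n_regions = 2)
  expect_equal(regs2$seed_col, c(2, 6))
  expect_equal(regs2$start_col, c(2, 6))

  # runs never cross channel-block boundaries
  ranking3 <- ranking
  ranking3$channel <- c(rep("ch1", 3), rep("ch2", 4))
  ranking3$rank <- order(order(ranking3$p_value))
  regs3 <- select_regions(ranking3, n_regions = 3)
  expect_true(all(regs3$end_col != 4 | regs3$start_col == 4))

  # nothing significant -> empty with warning
  ranking$p_value[] <- 0.5
  expect_warning(r0 <- select_regions(ranking, n_regions = 1), "0 of 1")
  expect_equal(nrow(r0), 0)
})

test_that("mRMR is deterministic, avoids duplicated columns, and honors k", {
  set.seed(13)
  n <- 60
  y <- rep(c("a", "b", "c"), each = n / 3)
  informative <- rnorm(n) + (y == "b") * 3
  other <- rnorm(n) + (y == "c") * 2
  m <- cbind(informative, informative, other, rnorm(n))
  d <- spectral_dataset(m, tibble::tibble(class_label = y,
                                          sample_id = paste0("s", 1:n),
                                          acquisition_index = 1L),
                        wavenumber = 1:4 * 10)
  sel <- mrmr_select(d, 1:4, 2)
  # a duplicate of an already-picked column is never taken while an
  # informative alternative remains
  expect_equal(sort(sel), c(1, 3))
  expect_identical(mrmr_select(d, 1:4, 2), sel)  # deterministic
  expect_equal(mrmr_select(d, 2, 1), 2)
  expect_equal(length(mrmr_select(d, 1:4, 4)), 4)
  expect_error(mrmr_select(d, 1:3, 5), "invalid config")
})

test_that("universal barcodes have the exact requested sizes and no duplicates", {
  fx <- sim_fingerprints(small_design(n_points = 128, n_spectra = 6), seed = 4)
  for (size in c(30, 10)) {
    b <- universal_barcode(fx$mx, size)
    expect_equal(nrow(b), size)
    expect_false(anyDuplicated(b$column) > 0)
  }
  b_full <- universal_barcode(fx$mx, "full")
  expect_equal(nrow(b_full), 256)
  expect_identical(b_full$col_index, 1:256)
  b_half <- universal_barcode(fx$mx, "half")
  expect_equal(nrow(b_half), 128)
  # identity barcode leaves the dataset unchanged
  expect_equal(sd_matrix(apply_barcode(fx$mx, b_full)), sd_matrix(fx$mx))
})

test_that("single-channel planted classes yield single-channel disease barcodes with planted directions", {
  fx <- sim_fingerprints(recovery_design(), seed = 1)
  b <- disease_barcode(fx$mx, "control", "R1")
  expect_gt(nrow(b), 0)
  expect_true(all(b$channel == "532nm"))
  # planted increases are flagged as increases (black bars)
  for (ctr in c(700, 850, 1500)) {
    near <- b[abs(b$wavenumber - ctr) < 6 & b$channel == "532nm", ]
    expect_gt(nrow(near), 0)
    expect_true(all(near$direction == 1L))
  }
  # disease == control: empty barcode (warns about missing regions)
  small <- sim_fingerprints(small_design(n_points = 128, n_spectra = 6), seed = 4)
  b0 <- suppressWarnings(disease_barcode(small$mx, "control", "control"))
  expect_equal(nrow(b0), 0)
})

test_that("lowest-ANOVA barcode picks the least class-associated variables", {
  set.seed(5)
  n <- 40
  y <- rep(c("a", "b", "c", "d"), each = 10)
  m <- cbind(matrix(rnorm(n * 6), n, 6), (y == "a") * 5 + rnorm(n, 0, 0.1),
             rep(2, n))
  d <- spectral_dataset(m, tibble::tibble(class_label = y,
                                          sample_id = paste0("s", 1:n),
                                          acquisition_index = 1L),
                        wavenumber = 1:8 * 10)
  b <- lowest_ranked_anova(d, k = 3)
  expect_equal(nrow(b), 3)
  expect_false(7 %in% b$col_index)   # strongly discriminative column excluded
  expect_true(8 %in% b$col_index)    # constant column gets p = 1, selected
  expect_true(all(is.na(b$direction)))
  expect_equal(nrow(lowest_ranked_anova(d, k = 8)), 8)
})

test_that("apply_barcode subsets columns in barcode order and validates variables", {
  d <- toy_dataset(n_vars = 6)
  b <- universal_barcode(d, 3)
  sub <- apply_barcode(d, b)
  expect_equal(nrow(sd_colmeta(sub)), 3)
  expect_identical(sd_colmeta(sub)$column, b$column)
  expect_identical(sd_meta(sub), sd_meta(d))
  bad <- b
  bad$column[1] <- "nope|123"
  expect_error(apply_barcode(d, bad), "mapping error")
  expect_error(apply_barcode(d, b[0, ]), "mapping error")
})

test_that("barcode JSON round trip preserves variables, order and name", {
  d <- toy_dataset(n_vars = 6)
  b <- universal_barcode(d, 4)
  f <- withr::local_tempfile(fileext = ".json")
  write_barcode(b, f)
  b2 <- read_barcode(f)
  expect_equal(as.data.frame(b2), as.data.frame(b))
  expect_identical(attr(b2, "name"), attr(b, "name"))
})
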