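## Spectral barcoding: per-wavenumber Mann-Whitney ranking, contiguous
## region selection, disease-specific and universal barcodes, mRMR
## reduction, and the lowest-ranked ANOVA negative control.

tie_term <- function(r) {
  t <- tabulate(match(r, unique(r)))
  sum(t^3 - t)
}

# vectorized two-sided Mann-Whitney over matrix columns; group_a rows vs
# group_b rows. Exact null (via pwilcox) for tie-free columns when both
# groups have <= 20 members, otherwise the normal approximation with tie
# and continuity corrections.
utest_columns <- function(m, rows_a, rows_b, exact_max = 20L) {
  na <- length(rows_a); nb <- length(rows_b)
  sub <- m[c(rows_a, rows_b), , drop = FALSE]
  ranks <- apply(sub, 2, rank)
  u_a <- colSums(ranks[seq_len(na), , drop = FALSE]) - na * (na + 1) / 2
  ties <- apply(sub, 2, function(x) tie_term(x))
  use_exact <- (ties == 0) & (na <= exact_max) & (nb <= exact_max)
  p <- numeric(ncol(m))
  if (any(use_exact)) {
    u <- u_a[use_exact]
    lo <- stats::pwilcox(u, na, nb)
    hi <- 1 - stats::pwilcox(u - 1, na, nb)
    p[use_exact] <- pmin(1, 2 * pmin(lo, hi))
  }
  # small tied samples: exact permutation null by enumeration
  use_enum <- !use_exact & (na + nb <= 20L)
  if (any(use_enum)) {
    combs <- utils::combn(na + nb, na)
    for (j in which(use_enum)) {
      r <- ranks[, j]
      u_all <- colSums(matrix(r[combs], nrow = na)) - na * (na + 1) / 2
      mu <- na * nb / 2
      pj <- if (u_a[j] <= mu) 2 * mean(u_all <= u_a[j]) else 2 * mean(u_all >= u_a[j])
      p[j] <- min(1, pj)
    }
  }
  rest <- !use_exact & !use_enum
  if (any(rest)) {
    u <- u_a[rest]
    tt <- ties[rest]
    n <- na + nb
    z <- u - na * nb / 2
    sigma <- sqrt((na * nb / 12) * ((n + 1) - tt / (n * (n - 1))))
    z <- ifelse(sigma > 0, (z - sign(z) * 0.5) / sigma, 0)
    pa <- pmin(1, 2 * stats::pnorm(-abs(z)))
    pa[sigma == 0] <- 1  # fully tied column carries no information
    p[rest] <- pa
  }
  med_a <- apply(m[rows_a, , drop = FALSE], 2, stats::median)
  med_b <- apply(m[rows_b, , drop = FALSE], 2, stats::median)
  list(u = u_a, p = p, median_diff = med_b - med_a)
}

#' Per-wavenumber Mann-Whitney ranking of two classes
#'
#' Runs a two-sided Mann-Whitney U test on every spectral variable between
#' two classes and ranks variables by significance (rank 1 = smallest
#' p-value; ties broken by larger absolute median difference, then lower
#' column index). The direction flag is +1 when the second class's median
#' exceeds the first's (an increase in `class_b`), -1 otherwise.
#'
#' @param d A [spectral_dataset()].
#' @param class_a,class_b Class labels to compare; by convention `class_a`
#'   is the control/reference.
#' @return A tibble of class `mx_ranking` with one row per variable:
#'   `col_index`, `column`, `channel`, `wavenumber`, `statistic` (U of
#'   `class_a`), `p_value`, `median_diff`, `direction`, `rank`.
#' @export
rank_utest <- function(d, class_a, class_b) {
  meta <- sd_meta(d)
  rows_a <- which(meta$class_label == class_a)
  rows_b <- which(meta$class_label == class_b)
  if (length(rows_a) < 2 || length(rows_b) < 2) {
    stop("label error: both classes need at least 2 spectra ('",
         class_a, "', '", class_b, "')", call. = FALSE)
  }
  res <- utest_columns(sd_matrix(d), rows_a, rows_b)
  cm <- sd_colmeta(d)
  out <- tibble::tibble(
    col_index = seq_len(nrow(cm)),
    column = cm$column,
    channel = cm$channel,
    wavenumber = cm$wavenumber,
    statistic = res$u,
    p_value = res$p,
    median_diff = res$median_diff,
    direction = ifelse(res$median_diff > 0, 1L, -1L)
  )
  ord <- order(out$p_value, -abs(out$median_diff), out$col_index)
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  attr(out, "class_a") <- class_a
  attr(out, "class_b") <- class_b
  class(out) <- c("mx_ranking", class(out))
  out
}

#' Select independent significant spectral regions
#'
#' A spectral region is a maximal unbroken run of variables with
#' `p < alpha`, never crossing a channel-block boundary. Regions are chosen
#' greedily: the first region is the run containing the top-ranked variable,
#' the next the run containing the best-ranked variable outside any chosen
#' region, and so on. All variables of each chosen run are retained,
#' independent of the run's length.
#'
#' @param ranking An `mx_ranking` from [rank_utest()].
#' @param n_regions Number of regions to select (default 3).
#' @param alpha Per-variable significance level delimiting runs
#'   (default 0.05, uncorrected).
#' @return A tibble with one row per region: `region`, `channel`,
#'   `start_col`, `end_col`, `seed_col`, `n_vars`. If fewer disjoint
#'   significant runs exist, returns as many as exist with a warning.
#' @export
select_regions <- function(ranking, n_regions = 3L, alpha = 0.05) {
  stopifnot(n_regions >= 1)
  r <- ranking[order(ranking$col_index), ]
  sig <- r$p_value < alpha
  new_run <- c(TRUE, r$channel[-1] != r$channel[-nrow(r)] | !sig[-1] | !sig[-nrow(r)])
  run_id <- cumsum(new_run)
  run_id[!sig] <- NA_integer_
  chosen <- integer(0)
  seeds <- integer(0)
  by_rank <- r$col_index[order(r$rank)]
  for (ci in by_rank) {
    rid <- run_id[ci]
    if (is.na(rid) || rid %in% chosen) next
    chosen <- c(chosen, rid)
    seeds <- c(seeds, ci)
    if (length(chosen) >= n_regions) break
  }
  if (length(chosen) < n_regions) {
    warning(sprintf("only %d of %d requested significant regions exist",
                    length(chosen), n_regions), call. = FALSE)
  }
  out <- purrr::map2_dfr(chosen, seeds, function(rid, seed) {
    members <- which(!is.na(run_id) & run_id == rid)
    tibble::tibble(channel = r$channel[members[1]],
                   start_col = min(members), end_col = max(members),
                   seed_col = seed, n_vars = length(members))
  })
  out <- dplyr::mutate(out, region = dplyr::row_number(), .before = 1)
  class(out) <- c("mx_regions", class(out))
  out
}

new_barcode <- function(rows, name) {
  rows <- tibble::as_tibble(rows)
  if (anyDuplicated(rows$column)) stop("barcode contains duplicate variables", call. = FALSE)
  attr(rows, "name") <- name
  attr(rows, "size") <- nrow(rows)
  class(rows) <- c("mx_barcode", class(rows))
  rows
}

#' @export
print.mx_barcode <- function(x, ...) {
  cat(sprintf("<mx_barcode> '%s': %d variables (%d increase / %d decrease)\n",
              attr(x, "name"), nrow(x),
              sum(x$direction == 1, na.rm = TRUE),
              sum(x$direction == -1, na.rm = TRUE)))
  NextMethod()
}

#' Disease-specific spectral barcode
#'
#' Ranks every variable by a Mann-Whitney test of one disease class against
#' the control class, selects the top `n_regions` independent significant
#' spectral regions, and returns every variable of those regions as a
#' barcode. Direction flags mark variables increased (+1, "black") or
#' decreased (-1, "gray") in the disease class relative to control.
#'
#' @param d A (typically MX) [spectral_dataset()].
#' @param control,disease Class labels.
#' @inheritParams select_regions
#' @return A tibble of class `mx_barcode`: `col_index`, `column`, `channel`,
#'   `wavenumber`, `direction`, `provenance`.
#' @export
disease_barcode <- function(d, control, disease, n_regions = 3L, alpha = 0.05) {
  ranking <- rank_utest(d, control, disease)
  regions <- select_regions(ranking, n_regions = n_regions, alpha = alpha)
  if (!nrow(regions)) {
    warning("no significant regions; empty barcode", call. = FALSE)
    return(new_barcode(ranking[0, c("col_index", "column", "channel",
                                    "wavenumber", "direction")], disease))
  }
  rows <- purrr::pmap_dfr(regions, function(region, channel, start_col, end_col, ...) {
    idx <- start_col:end_col
    dplyr::mutate(
      ranking[idx, c("col_index", "column", "channel", "wavenumber", "direction")],
      provenance = sprintf("%s_vs_%s region %d", control, disease, region))
  })
  new_barcode(rows, disease)
}

## ---- mutual information / mRMR ----

decile_bin <- function(x, n_bins = 10L) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

mutual_info <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Greedy minimum-redundancy maximum-relevance selection
#'
#' mRMR with the difference (MID) criterion: relevance is the mutual
#' information between a variable (discretized into deciles over the whole
#' dataset) and the class label; redundancy is the mean mutual information
#' with the already-selected variables. The first pick maximizes relevance;
#' each subsequent pick maximizes relevance minus mean redundancy. Ties
#' break deterministically toward the lower column index, so the selection
#' is reproducible for a given dataset.
#'
#' @param d A [spectral_dataset()].
#' @param candidates Vector of column indices to choose from.
#' @param k Number of variables to select (`k <= length(candidates)`).
#' @return Integer vector of column indices in selection order.
#' @export
mrmr_select <- function(d, candidates, k) {
  candidates <- as.integer(candidates)
  if (k > length(candidates)) {
    stop("invalid config: k exceeds the number of candidates", call. = FALSE)
  }
  m <- sd_matrix(d)
  y <- sd_meta(d)$class_label
  bins <- lapply(candidates, function(j) decile_bin(m[, j]))
  rel <- vapply(bins, mutual_info, 0, y = y)
  selected <- integer(0)
  red_sum <- numeric(length(candidates))
  avail <- rep(TRUE, length(candidates))
  for (step in seq_len(k)) {
    score <- if (!length(selected)) rel else rel - red_sum / length(selected)
    score[!avail] <- -Inf
    best <- which(score == max(score))
    best <- best[which.min(candidates[best])]
    selected <- c(selected, best)
    avail[best] <- FALSE
    if (step < k) {
      upd <- which(avail)
      red_sum[upd] <- red_sum[upd] + vapply(upd, function(i) {
        mutual_info(bins[[i]], bins[[best]])
      }, 0)
    }
  }
  candidates[selected]
}

## ---- universal barcode ----

#' Universal multi-class spectral barcode
#'
#' Runs a Mann-Whitney ranking for every pair of classes (k classes give
#' k(k-1)/2 tests; 10 for five classes) and assembles fixed-size barcodes:
#'
#' * `size = 100`: each test contributes its 10 highest-ranked variables;
#'   duplicates across tests are backfilled from that test's next-ranked
#'   variables so the barcode has exactly 100 members.
#' * `size = 30`: each test's top-10 variables are mRMR-reduced to 3
#'   (dedup-backfilled along the test's mRMR ordering).
#' * `size = 10`: the single best mRMR variable per test.
#' * `size = "half"`: the top half of all variables by best (minimum)
#'   pairwise p-value.
#' * `size = "full"`: all variables in their original order.
#'
#' Each variable's direction flag comes from the test that contributed it.
#'
#' @param d A [spectral_dataset()] with at least 2 classes (the reference
#'   protocol uses 5).
#' @param size `"full"`, `"half"`, or a count such as 100, 30 or 10.
#' @return A tibble of class `mx_barcode`.
#' @export
universal_barcode <- function(d, size = 30) {
  meta <- sd_meta(d)
  classes <- sort(unique(meta$class_label))
  if (length(classes) < 2) stop("label error: need at least 2 classes", call. = FALSE)
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  rankings <- lapply(pairs, function(p) rank_utest(d, p[1], p[2]))
  names(rankings) <- vapply(pairs, paste, "", collapse = "_vs_")
  cm <- sd_colmeta(d)
  V <- nrow(cm)

  best_p <- do.call(pmin, lapply(rankings, function(r) r$p_value[order(r$col_index)]))
  best_test <- apply(do.call(cbind, lapply(rankings, function(r) {
    r$p_value[order(r$col_index)]
  })), 1, which.min)

  barcode_rows <- function(cols, prov) {
    tibble::tibble(
      col_index = cols, column = cm$column[cols], channel = cm$channel[cols],
      wavenumber = cm$wavenumber[cols],
      direction = vapply(seq_along(cols), function(i) {
        r <- rankings[[best_test[cols[i]]]]
        r$direction[r$col_index == cols[i]]
      }, 0L),
      provenance = prov)
  }

  if (identical(size, "full")) {
    return(new_barcode(barcode_rows(seq_len(V), "all variables"), "universal_full"))
  }
  if (identical(size, "half")) {
    kk <- floor(V / 2)
    cols <- order(best_p, seq_len(V))[seq_len(kk)]
    return(new_barcode(barcode_rows(cols, "top half by best pairwise p"),
                       "universal_half"))
  }
  size <- as.integer(size)
  n_tests <- length(rankings)
  quota <- rep(size %/% n_tests, n_tests)
  extra <- size %% n_tests
  if (extra) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L
  top10 <- lapply(rankings, function(r) r$col_index[order(r$rank)][seq_len(min(10L, V))])

  # per-test candidate queue, best first
  queues <- lapply(seq_along(rankings), function(i) {
    full_rank <- rankings[[i]]$col_index[order(rankings[[i]]$rank)]
    if (quota[i] < 10L && size < 100L) {
      mr <- mrmr_select(d, top10[[i]], length(top10[[i]]))
      c(mr, setdiff(full_rank, mr))
    } else {
      full_rank
    }
  })

  sel_cols <- integer(0)
  sel_prov <- character(0)
  take_from <- function(i, n_take) {
    q <- setdiff(queues[[i]], sel_cols)
    q[seq_len(min(n_take, length(q)))]
  }
  for (i in seq_along(queues)) {
    got <- take_from(i, quota[i])
    sel_cols <- c(sel_cols, got)
    sel_prov <- c(sel_prov, rep(names(rankings)[i], length(got)))
  }
  i <- 1L
  while (length(sel_cols) < size) { # round-robin backfill if any queue ran dry
    got <- take_from(i, 1L)
    if (length(got)) {
      sel_cols <- c(sel_cols, got)
      sel_prov <- c(sel_prov, names(rankings)[i])
    }
    i <- i %% length(queues) + 1L
    if (length(unique(sel_cols)) >= V) break
  }
  rows <- barcode_rows(sel_cols, sel_prov)
  # direction/provenance from the contributing test where known
  for (j in seq_len(nrow(rows))) {
    ri <- match(sel_prov[j], names(rankings))
    r <- rankings[[ri]]
    rows$direction[j] <- r$direction[r$col_index == sel_cols[j]]
  }
  new_barcode(rows, paste0("universal_", size))
}

#' Lowest-ranked ANOVA barcode (negative control)
#'
#' Computes a one-way ANOVA F statistic per variable across all classes and
#' returns the `k` variables with the largest p-values, i.e. the variables
#' least associated with class. This is a negative control: applying it
#' should destroy class structure. Constant columns have an undefined F and
#' are assigned p = 1 (eligible for selection).
#'
#' @param d A [spectral_dataset()] with at least 2 classes.
#' @param k Number of variables (default 10).
#' @return A tibble of class `mx_barcode` (directions are `NA`).
#' @export
lowest_ranked_anova <- function(d, k = 10L) {
  meta <- sd_meta(d)
  classes <- unique(meta$class_label)
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  m <- sd_matrix(d)
  n <- nrow(m)
  g <- factor(meta$class_label)
  ng <- as.vector(table(g))
  gm <- rowsum(m, g) / ng
  grand <- colMeans(m)
  ssb <- colSums(gm^2 * ng) - n * grand^2
  sst <- colSums(m^2) - n * grand^2
  ssw <- sst - ssb
  df1 <- length(classes) - 1L
  df2 <- n - length(classes)
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  constant <- sst <= .Machine$double.eps * n * pmax(1, abs(grand))^2
  p[constant | is.nan(f)] <- 1
  cm <- sd_colmeta(d)
  cols <- order(-p, seq_along(p))[seq_len(min(k, ncol(m)))]
  new_barcode(tibble::tibble(
    col_index = cols, column = cm$column[cols], channel = cm$channel[cols],
    wavenumber = cm$wavenumber[cols], direction = NA_integer_,
    provenance = sprintf("anova p=%.3g", p[cols])), "lowest_anova")
}

#' Subset a dataset to a barcode
#'
#' Keeps only the barcode's variables, in barcode order; row metadata is
#' unchanged. Refuses an empty barcode and unknown variables.
#'
#' @param d A [spectral_dataset()].
#' @param barcode An `mx_barcode`.
#' @return A [spectral_dataset()] with `length(barcode)` columns.
#' @export
apply_barcode <- function(d, barcode) {
  if (!nrow(barcode)) stop("mapping error: empty barcode", call. = FALSE)
  cm <- sd_colmeta(d)
  idx <- match(barcode$column, cm$column)
  if (anyNA(idx)) {
    stop("mapping error: barcode variable '",
         barcode$column[which(is.na(idx))[1]], "' not in dataset", call. = FALSE)
  }
  spectral_dataset(sd_matrix(d)[, idx, drop = FALSE], sd_meta(d),
                   col_meta = cm[idx, c("channel", "wavenumber")],
                   signal_kind = attr(d, "signal_kind"),
                   .check_monotone = FALSE)
}

#' Write / read a barcode as JSON
#'
#' @param barcode An `mx_barcode`.
#' @param path File path.
#' @return `write_barcode()` returns `path` invisibly; `read_barcode()` the
#'   barcode.
#' @export
write_barcode <- function(barcode, path) {
  jsonlite::write_json(
    list(name = attr(barcode, "name"),
         variables = as.data.frame(barcode)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_barcode
#' @export
read_barcode <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_barcode(tibble::as_tibble(obj$variables), obj$name)
}
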