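## Supervised evaluation: structured first/middle/final splits, LDA with
## pseudo-inverse pooled covariance and stratified k-fold CV, per-class
## accuracies, and Kruskal-Wallis + Bonferroni comparison of configurations.

#' First/middle/final split scheme
#'
#' Builds the three train/test repeats used to compare configurations:
#' for repeat r in {1, 2, 3}, the test set holds the first 3, middle 3 and
#' final 3 spectra of every sample respectively (0-based positions
#' `{0,1,2}`, `{floor(m/2)-1, floor(m/2), floor(m/2)+1}`, `{m-3, m-2, m-1}`
#' within each sample's acquisition order); the remainder trains. With 30
#' spectra per sample and 15 samples this gives the 9:1 ratio of 405
#' training to 45 testing spectra per repeat. Repeats may overlap at small
#' `m`; the splits are sample-correlated by construction, so results serve
#' configuration comparison, not predictive validation.
#'
#' @param d A [spectral_dataset()] where every sample has the same number
#'   `m >= 4` of spectra.
#' @return A tibble of class `mx_splits`: `repeat_id`, `row`, `set`
#'   (`"train"`/`"test"`).
#' @export
make_splits <- function(d) {
  meta <- sd_meta(d)
  counts <- table(meta$sample_id)
  m <- unique(as.vector(counts))
  if (length(m) != 1) {
    stop("invalid input: samples have unequal spectrum counts", call. = FALSE)
  }
  if (m < 4) {
    stop("invalid config: need more than 3 spectra per sample so training sets are non-empty",
         call. = FALSE)
  }
  pos <- stats::ave(rank(meta$acquisition_index, ties.method = "first"),
                    meta$sample_id,
                    FUN = function(x) rank(x, ties.method = "first") - 1)
  test_pos <- list(`1` = c(0, 1, 2),
                   `2` = c(floor(m / 2) - 1, floor(m / 2), floor(m / 2) + 1),
                   `3` = c(m - 3, m - 2, m - 1))
  out <- purrr::map_dfr(1:3, function(r) {
    test <- pos %in% test_pos[[r]]
    tibble::tibble(repeat_id = r, row = seq_len(nrow(meta)),
                   set = ifelse(test, "test", "train"))
  })
  class(out) <- c("mx_splits", class(out))
  out
}

split_rows <- function(splits, r, set) {
  splits$row[splits$repeat_id == r & splits$set == set]
}

## ---- pseudo-inverse LDA core ----

fit_plda <- function(x, y, prior = NULL) {
  y <- factor(y)
  classes <- levels(y)
  k <- length(classes)
  n <- nrow(x)
  counts <- as.vector(table(y))
  if (is.null(prior)) prior <- counts / n
  mns <- rowsum(x, y) / counts
  xc <- x - mns[as.integer(y), , drop = FALSE]
  sv <- svd(xc, nu = 0)
  tol <- max(dim(x)) * .Machine$double.eps * max(sv$d, 0)
  r <- sum(sv$d > tol)
  if (r == 0) {
    w <- matrix(0, ncol(x), k)
  } else {
    v <- sv$v[, seq_len(r), drop = FALSE]
    inv <- (n - k) / sv$d[seq_len(r)]^2    # pseudo-inverse of pooled covariance
    g <- t(mns %*% v)                       # r x k
    w <- v %*% (g * inv)
  }
  b <- -0.5 * colSums(t(mns) * w) + log(prior)
  list(classes = classes, w = w, b = b, columns = colnames(x))
}

predict_plda <- function(fit, x) {
  scores <- x %*% fit$w
  scores <- sweep(scores, 2, fit$b, "+")
  factor(fit$classes[max.col(scores, ties.method = "first")], levels = fit$classes)
}

stratified_folds <- function(y, folds, seed) {
  idx <- integer(length(y))
  rng <- local({set.seed(seed); function(n) sample.int(n)})
  for (cl in unique(y)) {
    rows <- which(y == cl)
    idx[rows[rng(length(rows))]] <- rep_len(seq_len(folds), length(rows))
  }
  idx
}

#' Train an LDA classifier with stratified cross-validation
#'
#' Multiclass linear discriminant with pooled within-class covariance; when
#' the variable count reaches or exceeds the training count, the covariance
#' inverse is the Moore-Penrose pseudo-inverse ("pseudo-linear" behavior),
#' which reduces to classical LDA on full-rank problems. Stratified k-fold
#' cross-validation accuracy is reported per class and overall, and the
#' final model is refit on all training rows.
#'
#' @param train A [spectral_dataset()].
#' @param folds Number of CV folds (default 5). Every class needs at least
#'   `folds` spectra.
#' @param seed Seed for the stratified fold assignment (recorded in the
#'   result).
#' @return An object of class `mx_lda` with elements `fit`, `classes`,
#'   `cv_accuracy` (overall %), `cv_class_accuracy` (tibble), `folds`,
#'   `seed`.
#' @export
train_lda <- function(train, folds = 5L, seed = 1L) {
  x <- sd_matrix(train)
  y <- factor(sd_meta(train)$class_label)
  if (any(table(y) < folds)) {
    stop("invalid config: every class needs at least `folds` spectra", call. = FALSE)
  }
  fold_id <- stratified_folds(y, folds, seed)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in seq_len(folds)) {
    hold <- fold_id == f
    fit_f <- fit_plda(x[!hold, , drop = FALSE], y[!hold])
    pred[hold] <- predict_plda(fit_f, x[hold, , drop = FALSE])
  }
  per_class <- purrr::map_dfr(levels(y), function(cl) {
    sel <- y == cl
    tibble::tibble(class = cl, cv_accuracy = 100 * mean(pred[sel] == cl))
  })
  structure(list(
    fit = fit_plda(x, y),
    classes = levels(y),
    cv_accuracy = 100 * mean(pred == y),
    cv_class_accuracy = per_class,
    folds = folds,
    seed = seed
  ), class = "mx_lda")
}

#' @export
print.mx_lda <- function(x, ...) {
  cat(sprintf("<mx_lda> %d classes, %d variables | %d-fold CV accuracy %.1f%%\n",
              length(x$classes), nrow(x$fit$w), x$folds, x$cv_accuracy))
  invisible(x)
}

#' @export
predict.mx_lda <- function(object, newdata, ...) {
  m <- sd_matrix(newdata)
  if (!identical(colnames(m), object$fit$columns)) {
    stop("schema error: test column map differs from the training column map",
         call. = FALSE)
  }
  predict_plda(object$fit, m)
}

#' Evaluate a trained model on a test dataset
#'
#' @param model An `mx_lda` from [train_lda()].
#' @param test A [spectral_dataset()] with the same column map as the
#'   training data.
#' @return A list: `class_accuracy` (tibble of per-class accuracies in
#'   percent), `overall` (%), `confusion` (true x predicted counts; each row
#'   sums to that class's test count).
#' @export
evaluate_model <- function(model, test) {
  truth <- factor(sd_meta(test)$class_label, levels = model$classes)
  pred <- predict(model, test)
  conf <- table(truth = truth, predicted = pred)
  per_class <- purrr::map_dfr(model$classes, function(cl) {
    sel <- truth == cl
    tibble::tibble(class = cl,
                   accuracy = if (any(sel)) 100 * mean(pred[sel] == cl) else NA_real_)
  })
  list(class_accuracy = per_class,
       overall = 100 * mean(pred == truth),
       confusion = conf)
}

#' Run the full configuration-comparison protocol
#'
#' For every named configuration (a dataset built from the same samples and
#' spectra): build the first/middle/final splits, train LDA with stratified
#' 5-fold CV on each repeat's training rows, evaluate on the repeat's test
#' rows, and collect the per-class accuracies — 15 values per configuration
#' for 5 classes x 3 repeats, summarized as mean +/- sd. Configurations are
#' then compared by a Kruskal-Wallis omnibus test with Dunn-style pairwise
#' post-hoc comparisons and Bonferroni correction. Splits are
#' sample-correlated, so this is a configuration comparison, not predictive
#' validation.
#'
#' @param configs Named list of [spectral_dataset()] objects sharing row
#'   metadata.
#' @param folds CV folds (default 5).
#' @param seed Seed for fold assignment.
#' @return An object of class `mx_protocol`: `accuracy` (tibble: config,
#'   repeat_id, class, cv_accuracy, test_accuracy), `summary` (tibble:
#'   config, mean_accuracy, sd_accuracy), `omnibus_p`, `pairwise` (tibble),
#'   `confusion` (nested list).
#' @export
run_protocol <- function(configs, folds = 5L, seed = 1L) {
  stopifnot(length(configs) >= 1, !is.null(names(configs)))
  ref <- dplyr::arrange(sd_meta(configs[[1]]), .data$class_label,
                        .data$sample_id, .data$acquisition_index)
  for (d in configs[-1]) {
    m <- dplyr::arrange(sd_meta(d), .data$class_label, .data$sample_id,
                        .data$acquisition_index)
    if (!identical(ref, m)) {
      stop("configurations must share identical row metadata", call. = FALSE)
    }
  }
  confusion <- list()
  accuracy <- purrr::imap_dfr(configs, function(d, nm) {
    splits <- make_splits(d)
    purrr::map_dfr(1:3, function(r) {
      tr <- split_rows(splits, r, "train")
      te <- split_rows(splits, r, "test")
      model <- train_lda(subset_rows(d, tr), folds = folds, seed = seed + r)
      ev <- evaluate_model(model, subset_rows(d, te))
      confusion[[nm]][[r]] <<- ev$confusion
      dplyr::left_join(model$cv_class_accuracy,
                       ev$class_accuracy, by = "class") |>
        dplyr::transmute(config = nm, repeat_id = r, class = .data$class,
                         cv_accuracy = .data$cv_accuracy,
                         test_accuracy = .data$accuracy)
    })
  })
  summary <- accuracy |>
    dplyr::group_by(config = .data$config) |>
    dplyr::summarise(mean_accuracy = mean(.data$test_accuracy),
                     sd_accuracy = stats::sd(.data$test_accuracy),
                     .groups = "drop")
  cmp <- if (length(configs) >= 2) {
    compare_configs(split(accuracy$test_accuracy, accuracy$config))
  } else {
    list(omnibus_p = NA_real_, pairwise = tibble::tibble())
  }
  structure(list(accuracy = accuracy, summary = summary,
                 omnibus_p = cmp$omnibus_p, pairwise = cmp$pairwise,
                 confusion = confusion, seed = seed,
                 note = "configuration comparison, not predictive validation"),
            class = "mx_protocol")
}

subset_rows <- function(d, rows) {
  cm <- sd_colmeta(d)
  spectral_dataset(sd_matrix(d)[rows, , drop = FALSE],
                   sd_meta(d)[rows, ],
                   col_meta = cm[, c("channel", "wavenumber")],
                   signal_kind = attr(d, "signal_kind"),
                   .check_monotone = FALSE)
}

#' @export
print.mx_protocol <- function(x, ...) {
  cat("<mx_protocol> per-configuration test accuracy (mean +/- sd over class x repeat):\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %.1f%% +/- %.1f%%\n", s$config[i],
                s$mean_accuracy[i], s$sd_accuracy[i]))
  }
  if (!is.na(x$omnibus_p)) {
    cat(sprintf("  Kruskal-Wallis omnibus p = %.3g (%s)\n", x$omnibus_p, x$note))
  }
  invisible(x)
}

#' Compare configuration accuracy sets
#'
#' Kruskal-Wallis omnibus test across the per-configuration accuracy sets
#' (15 class-by-repeat values each in the reference protocol) followed by
#' Dunn-style pairwise rank comparisons with Bonferroni multiplication
#' (capped at 1). Identical sets give H = 0 and omnibus p = 1.
#'
#' @param accuracy_sets Named list of equal-length numeric vectors.
#' @return A list: `omnibus_p`, `pairwise` (tibble with `config_a`,
#'   `config_b`, `z`, `p_raw`, `p_bonferroni`).
#' @export
compare_configs <- function(accuracy_sets) {
  stopifnot(length(accuracy_sets) >= 2)
  if (length(unique(lengths(accuracy_sets))) != 1) {
    stop("invalid input: accuracy sets must have equal length", call. = FALSE)
  }
  values <- unlist(accuracy_sets, use.names = FALSE)
  grp <- factor(rep(names(accuracy_sets), lengths(accuracy_sets)),
                levels = names(accuracy_sets))
  omnibus <- if (stats::var(values) == 0) 1 else
    stats::kruskal.test(values, grp)$p.value
  # Dunn post-hoc on the joint ranks, with tie correction
  rk <- rank(values)
  n <- length(values)
  ties <- tie_term(values)
  mean_rk <- tapply(rk, grp, mean)
  ns <- tapply(rk, grp, length)
  pairs <- utils::combn(names(accuracy_sets), 2, simplify = FALSE)
  n_pairs <- length(pairs)
  pairwise <- purrr::map_dfr(pairs, function(p) {
    sig <- sqrt((n * (n + 1) / 12 - ties / (12 * (n - 1))) *
                  (1 / ns[[p[1]]] + 1 / ns[[p[2]]]))
    z <- if (sig == 0) 0 else (mean_rk[[p[1]]] - mean_rk[[p[2]]]) / sig
    p_raw <- 2 * stats::pnorm(-abs(z))
    tibble::tibble(config_a = p[1], config_b = p[2], z = z,
                   p_raw = p_raw, p_bonferroni = min(1, p_raw * n_pairs))
  })
  list(omnibus_p = omnibus, pairwise = pairwise)
}
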