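## Unsupervised structure evaluation: PCA projection, per-cluster
## Mahalanobis spread, Gaussian Bhattacharyya distances, optionally after
## an LDA transformation of the retained PC scores.

ridge_if_singular <- function(sigma) {
  ok <- tryCatch({solve(sigma); TRUE}, error = function(e) FALSE)
  if (ok && is.finite(determinant(sigma)$modulus) &&
      rcond(sigma) > 1e-10) return(sigma)
  eps <- 1e-8 * sum(diag(sigma)) / nrow(sigma)
  if (eps <= 0) eps <- 1e-12
  sigma + diag(eps, nrow(sigma))
}

#' Principal component projection
#'
#' PCA of the column-centered intensity matrix via singular value
#' decomposition. Standardize columns upstream (see
#' [standardize_columns()]) when variables should enter on equal footing.
#' The sign of each component is fixed deterministically: the
#' largest-magnitude element of every loading vector is made positive, so
#' repeated runs are bit-identical.
#'
#' @param d A [spectral_dataset()].
#' @param n_components Number of components to retain (default 3).
#' @return An object of class `mx_projection`: `scores` (tibble of row
#'   metadata plus `PC1..PCk`), `loadings` (variables x components),
#'   `explained_variance` (fractions of total variance, non-increasing),
#'   `center`, and `kind = "PC"`.
#' @export
pca_project <- function(d, n_components = 3L) {
  m <- sd_matrix(d)
  if (n_components > min(dim(m))) {
    stop("invalid config: n_components exceeds min(n_rows, n_cols)", call. = FALSE)
  }
  ctr <- colMeans(m)
  mc <- sweep(m, 2, ctr)
  sv <- svd(mc)
  flip <- vapply(seq_len(n_components), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, 0)
  flip[flip == 0] <- 1
  loadings <- sweep(sv$v[, seq_len(n_components), drop = FALSE], 2, flip, "*")
  scores <- sweep(sv$u[, seq_len(n_components), drop = FALSE] %*%
                    diag(sv$d[seq_len(n_components)], n_components), 2, flip, "*")
  colnames(scores) <- paste0("PC", seq_len(n_components))
  rownames(loadings) <- sd_colmeta(d)$column
  colnames(loadings) <- colnames(scores)
  structure(list(
    scores = dplyr::bind_cols(sd_meta(d), tibble::as_tibble(scores)),
    loadings = loadings,
    explained_variance = (sv$d^2 / sum(sv$d^2))[seq_len(n_components)],
    center = ctr,
    kind = "PC"
  ), class = "mx_projection")
}

#' @export
print.mx_projection <- function(x, ...) {
  cat(sprintf("<mx_projection> %d x %d (%s), explained variance: %s\n",
              nrow(x$scores), length(x$explained_variance), x$kind,
              paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", ")))
  invisible(x)
}

score_matrix <- function(p) {
  as.matrix(p$scores[, grep("^(PC|LD)", names(p$scores)), drop = FALSE])
}

#' Per-class Mahalanobis spread
#'
#' For each class, the mean Mahalanobis distance of its points to the class
#' centroid, measured in the PC1-PC2 plane against the class's own sample
#' covariance: an anisotropy-aware intraclass-variance measure. Tight
#' clusters score low; the measure is invariant under invertible affine
#' transforms of a class's points. Singular covariances are ridge-
#' regularized (epsilon = 1e-8 trace/dim).
#'
#' @param scores An `mx_projection` (first two components are used) or a
#'   numeric matrix of coordinates.
#' @param labels Class labels; taken from the projection when omitted.
#' @return A tibble with `class` and `spread`.
#' @export
mahalanobis_spread <- function(scores, labels = NULL) {
  if (inherits(scores, "mx_projection")) {
    if (is.null(labels)) labels <- scores$scores$class_label
    scores <- score_matrix(scores)
  }
  scores <- as.matrix(scores)[, 1:2, drop = FALSE]
  stopifnot(length(labels) == nrow(scores))
  purrr::map_dfr(sort(unique(labels)), function(cl) {
    pts <- scores[labels == cl, , drop = FALSE]
    mu <- colMeans(pts)
    sigma <- ridge_if_singular(stats::cov(pts))
    d2 <- stats::mahalanobis(pts, mu, sigma)
    tibble::tibble(class = cl, spread = mean(sqrt(pmax(d2, 0))))
  })
}

#' Gaussian Bhattacharyya distance between two point clouds
#'
#' \deqn{D_B = \frac{1}{8}(\mu_1-\mu_2)^\top \bar\Sigma^{-1}(\mu_1-\mu_2)
#'   + \frac{1}{2}\ln\frac{\det\bar\Sigma}{\sqrt{\det\Sigma_1\det\Sigma_2}}}
#' with \eqn{\bar\Sigma = (\Sigma_1+\Sigma_2)/2} and sample means and
#' covariances. Symmetric, zero for identical clouds, and invariant under a
#' common invertible affine transform of both groups. Larger values mean
#' less overlap between the two class ellipsoids.
#'
#' @param a,b Numeric matrices (points x dimensions), at least 3 points each.
#' @return A non-negative scalar.
#' @export
bhattacharyya_pair <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == ncol(b), nrow(a) >= 3, nrow(b) >= 3)
  mu <- colMeans(a) - colMeans(b)
  s1 <- ridge_if_singular(stats::cov(a))
  s2 <- ridge_if_singular(stats::cov(b))
  sbar <- ridge_if_singular((s1 + s2) / 2)
  term1 <- drop(crossprod(mu, solve(sbar, mu))) / 8
  ld <- function(s) determinant(s, logarithm = TRUE)$modulus
  term2 <- 0.5 * (ld(sbar) - 0.5 * (ld(s1) + ld(s2)))
  max(0, term1 + as.numeric(term2))
}

## Fisher discriminant directions in a low-dimensional score space
lda_directions <- function(scores, labels, n_keep = NULL) {
  x <- as.matrix(scores)
  classes <- sort(unique(labels))
  k <- length(classes)
  n <- nrow(x)
  grand <- colMeans(x)
  sw <- matrix(0, ncol(x), ncol(x))
  sb <- matrix(0, ncol(x), ncol(x))
  for (cl in classes) {
    xi <- x[labels == cl, , drop = FALSE]
    mu <- colMeans(xi)
    sw <- sw + crossprod(sweep(xi, 2, mu))
    sb <- sb + nrow(xi) * tcrossprod(mu - grand)
  }
  sw <- ridge_if_singular(sw / (n - k))
  es <- eigen(sw, symmetric = TRUE)
  whal <- es$vectors %*% diag(1 / sqrt(pmax(es$values, 1e-300)), ncol(x)) %*% t(es$vectors)
  em <- eigen(whal %*% sb %*% whal, symmetric = TRUE)
  n_ld <- min(k - 1L, ncol(x))
  if (is.null(n_keep)) n_keep <- n_ld
  n_keep <- min(n_keep, n_ld)
  dirs <- whal %*% em$vectors[, seq_len(n_keep), drop = FALSE]
  # deterministic sign: largest-magnitude element positive
  for (j in seq_len(ncol(dirs))) {
    s <- sign(dirs[which.max(abs(dirs[, j])), j])
    if (s < 0) dirs[, j] <- -dirs[, j]
  }
  dirs
}

#' Cluster-separation report
#'
#' The standard unsupervised evaluation chain: optionally subset to a
#' barcode, standardize columns, project onto the first `n_components`
#' principal components, optionally transform those scores by LDA (k - 1
#' discriminants for k classes, at most `n_components` retained), then
#' report the per-class Mahalanobis spread (PC1-PC2 plane, or LD1-LD2) and
#' the pairwise and average Gaussian Bhattacharyya distances between class
#' clouds in the retained space.
#'
#' @param d A [spectral_dataset()].
#' @param barcode Optional `mx_barcode` to apply first.
#' @param use_lda Transform the retained PC scores by LDA before measuring.
#' @param n_components Retained components (default 3).
#' @return An object of class `mx_separation`: `spread` (tibble),
#'   `pairwise` (tibble of class pairs and `d_b`), `average_bhattacharyya`,
#'   `kind` (`"PC"` or `"LD"`), `projection`.
#' @export
separation_report <- function(d, barcode = NULL, use_lda = FALSE,
                              n_components = 3L) {
  if (!is.null(barcode)) d <- apply_barcode(d, barcode)
  d <- suppressWarnings(standardize_columns(d))
  proj <- pca_project(d, n_components = min(n_components, min(dim(sd_matrix(d)))))
  labels <- proj$scores$class_label
  sc <- score_matrix(proj)
  kind <- "PC"
  if (use_lda) {
    dirs <- lda_directions(sc, labels, n_keep = n_components)
    sc <- sc %*% dirs
    colnames(sc) <- paste0("LD", seq_len(ncol(sc)))
    proj$scores <- dplyr::bind_cols(sd_meta(d), tibble::as_tibble(sc))
    proj$kind <- kind <- "LD"
  }
  classes <- sort(unique(labels))
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(p) {
    tibble::tibble(class_a = p[1], class_b = p[2],
                   d_b = bhattacharyya_pair(sc[labels == p[1], , drop = FALSE],
                                            sc[labels == p[2], , drop = FALSE]))
  })
  structure(list(
    spread = mahalanobis_spread(sc, labels),
    pairwise = pairwise,
    average_bhattacharyya = mean(pairwise$d_b),
    kind = kind,
    projection = proj
  ), class = "mx_separation")
}

#' @export
print.mx_separation <- function(x, ...) {
  cat(sprintf("<mx_separation> (%s space) average Bhattacharyya distance: %.3f\n",
              x$kind, x$average_bhattacharyya))
  cat("per-class Mahalanobis spread:\n")
  print(as.data.frame(x$spread), row.names = FALSE)
  invisible(x)
}
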