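#' Principal component analysis of a reference genotype panel
#'
#' Genotype dosages (0/1/2, samples x variants) are standardized per variant
#' by centering at `2 p` and dividing by `sqrt(2 p (1 - p))`, with `p` the
#' reference allele frequency; zero-variance variants are dropped. The top
#' `k` principal components are extracted by singular value decomposition,
#' with each component's sign fixed so that its largest-magnitude loading is
#' positive (a reproducibility convention).
#'
#' @param genotypes numeric matrix, samples x variants; rownames are sample
#'   ids. Missing dosages are imputed to the variant mean.
#' @param k number of components to keep.
#' @return list with `space` (a `pc_space`: `loadings` (variants x k),
#'   `center`, `scale`, `keep` index of retained variants, `evals`,
#'   `explained`, `k`) and `coords` (a data.frame of reference sample
#'   coordinates with a `source = "reference"` flag).
#' @export
reference_pca <- function(genotypes, k = 3L) {
  G <- as.matrix(genotypes)
  n <- nrow(G)
  if (n < k + 1L) stop("need at least k + 1 samples")
  p <- colMeans(G, na.rm = TRUE) / 2
  keep <- which(is.finite(p) & p > 0 & p < 1)
  if (length(keep) == 0L) stop("no polymorphic variants")
  center <- 2 * p[keep]
  scl <- sqrt(2 * p[keep] * (1 - p[keep]))
  X <- sweep(sweep(G[, keep, drop = FALSE], 2, center), 2, scl, "/")
  X[is.na(X)] <- 0
  sv <- svd(X)
  r <- sum(sv$d > max(sv$d) * 1e-12)
  if (k > r) stop("k exceeds the rank of the standardized genotype matrix")
  evals <- sv$d^2 / (n - 1)
  explained <- evals / sum(evals)
  V <- sv$v[, seq_len(k), drop = FALSE]
  # sign convention: dominant loading positive
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  scores <- X %*% V
  colnames(scores) <- paste0("PC", seq_len(k))
  ids <- rownames(G)
  if (is.null(ids)) ids <- sprintf("ref%04d", seq_len(n))
  coords <- data.frame(sample = ids, scores, source = "reference",
                       row.names = NULL, check.names = FALSE)
  space <- structure(list(loadings = V, center = center, scale = scl,
                          keep = keep, evals = evals[seq_len(k)],
                          explained = explained[seq_len(k)], k = as.integer(k),
                          n_variants = ncol(G)),
                     class = "pc_space")
  list(space = space, coords = coords)
}

#' @export
print.pc_space <- function(x, ...) {
  cat(sprintf("PC space: top %d PCs over %d variants (%d retained)\n",
              x$k, x$n_variants, length(x$keep)))
  cat("  explained variance fractions:",
      paste(sprintf("%.3f", x$explained), collapse = ", "), "\n")
  invisible(x)
}

#' Project study samples into a reference PC space
#'
#' Coordinates are the standardized genotypes (reference mean and scale)
#' multiplied by the reference loadings. Missing genotypes are imputed to
#' the reference mean, i.e. to zero in the standardized space; an
#' all-missing sample therefore projects to the origin.
#'
#' @param space a `pc_space` from [reference_pca()].
#' @param genotypes samples x variants dosage matrix over the same variant
#'   set and ordering used to build the space.
#' @return data.frame of coordinates with `source = "projected"`.
#' @export
project_samples <- function(space, genotypes) {
  G <- as.matrix(genotypes)
  if (ncol(G) != space$n_variants)
    stop("variant set/ordering does not match the PC space")
  X <- sweep(sweep(G[, space$keep, drop = FALSE], 2, space$center),
             2, space$scale, "/")
  X[is.na(X)] <- 0
  scores <- X %*% space$loadings
  colnames(scores) <- paste0("PC", seq_len(space$k))
  ids <- rownames(G)
  if (is.null(ids)) ids <- sprintf("proj%04d", seq_len(nrow(G)))
  data.frame(sample = ids, scores, source = "projected",
             row.names = NULL, check.names = FALSE)
}

coord_matrix <- function(x) {
  if (is.data.frame(x)) {
    as.matrix(x[, grep("^PC", names(x)), drop = FALSE])
  } else as.matrix(x)
}

#' Procrustes similarity between two point configurations
#'
#' The similarity statistic t0 after optimal translation, isotropic scaling
#' and rotation/reflection of one configuration onto the other:
#' `t0 = tr(Lambda) / sqrt(tr(Xc' Xc) tr(Yc' Yc))`, where `Lambda` holds the
#' singular values of `Xc' Yc` for the centered configurations. t0 is 1 for
#' identical shapes and symmetric in its arguments.
#'
#' @param X,Y matrices (or coordinate data.frames with `PC*` columns) of the
#'   same samples in two spaces; same row order, same dimension.
#' @return similarity t0 in `[0, 1]`.
#' @export
procrustes_similarity <- function(X, Y) {
  Xm <- coord_matrix(X); Ym <- coord_matrix(Y)
  if (!all(dim(Xm) == dim(Ym))) stop("configurations must match in dimension")
  if (nrow(Xm) < 3L) stop("need at least 3 samples")
  Xc <- scale(Xm, scale = FALSE)
  Yc <- scale(Ym, scale = FALSE)
  lambda <- svd(crossprod(Xc, Yc))$d
  sum(lambda) / sqrt(sum(Xc^2) * sum(Yc^2))
}

#' Bivariate Gaussian concentration ellipse
#'
#' Fits a bivariate Gaussian to 2-D coordinates and returns the ellipse
#' containing `level` probability mass: the set of points whose squared
#' Mahalanobis distance from the mean is at most the chi-square quantile
#' with 2 degrees of freedom at `level`.
#'
#' @param points two-column matrix (or coordinate data.frame).
#' @param level probability mass (default 0.95).
#' @return list with `center`, `shape` (covariance), `threshold` (Mahalanobis
#'   squared cut-off), and `inside` logical mask over the input points.
#' @export
concentration_ellipse <- function(points, level = 0.95) {
  P <- coord_matrix(points)
  if (ncol(P) < 2L) stop("points must have at least 2 columns")
  P <- P[, 1:2, drop = FALSE]
  if (nrow(P) < 3L) stop("need at least 3 points")
  ctr <- colMeans(P)
  S <- cov(P)
  if (!is.finite(determinant(S)$modulus) || det(S) <= 0)
    stop("singular covariance: points are degenerate")
  thr <- qchisq(level, df = 2)
  d2 <- mahalanobis(P, ctr, S)
  list(center = ctr, shape = S, threshold = thr, inside = d2 <= thr,
       level = level)
}

#' Iterative per-PC outlier removal
#'
#' Repeatedly computes the mean and SD of each of the top `k` PCs over the
#' currently kept samples and removes any sample more than `n_sd` SDs from
#' the mean on any PC, until no sample is removed. The procedure is
#' deterministic and its result is a fixed point (re-running on the kept set
#' removes nothing).
#'
#' @param coords coordinate data.frame (with `sample` and `PC*` columns) or
#'   matrix.
#' @param n_sd SD multiple defining an outlier (default 3).
#' @param k number of leading PCs examined (default 3).
#' @return list with `kept` ids, `removed` ids, and `iterations`.
#' @export
iterative_outlier_removal <- function(coords, n_sd = 3, k = 3L) {
  M <- coord_matrix(coords)
  if (k > ncol(M)) stop("k exceeds the number of available PCs")
  M <- M[, seq_len(k), drop = FALSE]
  ids <- if (is.data.frame(coords) && "sample" %in% names(coords))
    coords$sample else rownames(M) %||% as.character(seq_len(nrow(M)))
  keep <- rep(TRUE, nrow(M))
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    mu <- colMeans(M[keep, , drop = FALSE])
    sdv <- apply(M[keep, , drop = FALSE], 2, sd)
    z <- abs(sweep(sweep(M, 2, mu), 2, pmax(sdv, .Machine$double.eps), "/"))
    out <- keep & apply(z > n_sd, 1, any)
    if (!any(out)) break
    keep <- keep & !out
    if (!any(keep)) stop("all samples removed as outliers")
  }
  list(kept = ids[keep], removed = ids[!keep], iterations = iterations)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Density of samples along the axis between two population centroids
#'
#' Projects coordinates onto the unit vector pointing from `centroid_a` to
#' `centroid_b` (so points at `centroid_a` project to 0), returns the scalar
#' projections, a Gaussian-kernel density estimate, and, when two groups are
#' named, a Welch t-test for a mean shift along the axis.
#'
#' @param coords coordinate data.frame or matrix.
#' @param centroid_a,centroid_b centroid coordinate vectors (distinct).
#' @param groups optional factor/character vector (per row of `coords`);
#'   with `test_groups`, requests the mean-shift test.
#' @param test_groups length-2 character vector naming the groups to
#'   compare.
#' @param bw kernel bandwidth passed to [stats::density()] (default
#'   Silverman's rule, `"nrd0"`).
#' @return list with `projection`, `density`, and (when requested) `test`
#'   (Welch `htest`).
#' @export
axis_density <- function(coords, centroid_a, centroid_b, groups = NULL,
                         test_groups = NULL, bw = "nrd0") {
  M <- coord_matrix(coords)
  u <- as.numeric(centroid_b) - as.numeric(centroid_a)
  len <- sqrt(sum(u^2))
  if (len == 0) stop("centroids are identical")
  u <- u / len
  d <- ncol(M)
  proj <- as.vector(sweep(M[, seq_along(u), drop = FALSE], 2,
                          as.numeric(centroid_a)) %*% u)
  dens <- density(proj, bw = bw)
  test <- NULL
  if (!is.null(groups) && !is.null(test_groups)) {
    stopifnot(length(test_groups) == 2L)
    test <- t.test(proj[groups == test_groups[1]],
                   proj[groups == test_groups[2]])
  }
  list(projection = proj, density = dens, test = test, axis = u,
       axis_length = len)
}
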