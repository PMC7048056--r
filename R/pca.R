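#' Multi-group (animal-centred) PCA of log10 proportions
#'
#' Principal component analysis isolating within-animal (between-niche)
#' variation: proportions are log10-transformed after adding a pseudocount,
#' each dog's mean profile is subtracted and the grand mean restored, and the
#' column-centred matrix is decomposed by SVD.
#'
#' @param prop_table proportion matrix (OTUs x samples) from
#'   [to_proportions()].
#' @param samples sample metadata covering the table's columns (`sample_id`,
#'   `dog_id`, `niche`).
#' @param pseudocount value added before the log; `NULL` (default) uses half
#'   the smallest nonzero proportion in the table.
#' @param group_center centre on each dog's mean profile (`TRUE`, the
#'   multi-group variant) or perform plain PCA (`FALSE`).
#' @return an object of class `"mgpca"` with `scores` (samples x components),
#'   `loadings`, `sdev`, `explained_variance_pct`, `niche` (per sample),
#'   `dog`, and `pseudocount`.
#' @export
multigroup_pca <- function(prop_table, samples, pseudocount = NULL,
                           group_center = TRUE) {
  m <- as.matrix(prop_table)
  sam <- samples[match(colnames(m), samples$sample_id), , drop = FALSE]
  if (anyNA(sam$sample_id)) stop("sample metadata missing for some table columns")
  if (is.null(pseudocount)) {
    nz <- m[m > 0]
    if (!length(nz)) stop("proportion table is all zero")
    pseudocount <- min(nz) / 2
  }
  X <- t(log10(m + pseudocount))          # samples x OTUs
  if (group_center) {
    dog <- factor(sam$dog_id)
    singletons <- names(which(table(dog) == 1L))
    if (length(singletons))
      warning("dog(s) with a single sample contribute nothing after centring: ",
              paste(singletons, collapse = ", "))
    dog_means <- rowsum(X, dog) / as.vector(table(dog))
    grand <- colMeans(X)
    X <- X - dog_means[as.integer(dog), , drop = FALSE] +
      rep(grand, each = nrow(X))
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  ncomp <- sum(sv$d > max(sv$d) * 1e-12)
  scores <- sv$u[, seq_len(ncomp), drop = FALSE] %*%
    diag(sv$d[seq_len(ncomp)], ncomp)
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("PC", seq_len(ncomp))
  loadings <- sv$v[, seq_len(ncomp), drop = FALSE]
  rownames(loadings) <- colnames(X)
  colnames(loadings) <- colnames(scores)
  ev <- sv$d^2 / sum(sv$d^2) * 100
  structure(list(scores = scores, loadings = loadings,
                 sdev = sv$d[seq_len(ncomp)] / sqrt(max(1, nrow(X) - 1)),
                 explained_variance_pct = ev[seq_len(ncomp)],
                 niche = sam$niche, dog = sam$dog_id,
                 pseudocount = pseudocount, group_center = group_center),
            class = "mgpca")
}

#' @export
print.mgpca <- function(x, ...) {
  cat(sprintf("%s PCA of log10 proportions: %d samples, %d components\n",
              if (x$group_center) "Multi-group (dog-centred)" else "Plain",
              nrow(x$scores), ncol(x$scores)))
  ev <- x$explained_variance_pct[seq_len(min(4, length(x$explained_variance_pct)))]
  cat("  variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_along(ev), ev), collapse = ", "), "\n")
  invisible(x)
}

#' Bivariate confidence ellipse
#'
#' Normal-theory confidence region for a 2-d score cloud: centre at the mean,
#' shape from the sample covariance scaled by the chi-square quantile with
#' 2 degrees of freedom at the given level.
#'
#' @param scores_2d numeric matrix with two columns (>= 3 rows).
#' @param level coverage level in `[0, 1)`; `level = 0` degenerates to the
#'   centre point.
#' @return an object of class `"conf_ellipse"`: `center`, `cov`, `radii`
#'   (semi-axes), `angle` (radians, first axis), `level`.
#' @export
confidence_ellipse <- function(scores_2d, level = 0.95) {
  x <- as.matrix(scores_2d)
  if (ncol(x) != 2L) stop("scores_2d must have exactly two columns")
  if (nrow(x) < 3L) stop("at least three points are required")
  if (level < 0 || level >= 1) stop("level must lie in [0, 1)")
  ctr <- colMeans(x)
  S <- cov(x)
  if (!all(is.finite(S)) || det(S) <= 0)
    stop("degenerate covariance: ellipse undefined")
  e <- eigen(S, symmetric = TRUE)
  q <- qchisq(level, df = 2)
  structure(list(center = ctr, cov = S,
                 radii = sqrt(pmax(e$values, 0) * q),
                 angle = atan2(e$vectors[2, 1], e$vectors[1, 1]),
                 level = level, n = nrow(x)),
            class = "conf_ellipse")
}

#' Points on the boundary of a confidence ellipse
#'
#' @param e a [confidence_ellipse()].
#' @param n number of boundary points.
#' @return an `n x 2` matrix tracing the ellipse.
#' @export
ellipse_points <- function(e, n = 361) {
  th <- seq(0, 2 * pi, length.out = n)
  R <- matrix(c(cos(e$angle), sin(e$angle), -sin(e$angle), cos(e$angle)), 2)
  t(e$center + R %*% rbind(e$radii[1] * cos(th), e$radii[2] * sin(th)))
}

#' Test whether points fall inside a confidence ellipse
#'
#' @param e a [confidence_ellipse()].
#' @param pts matrix with two columns.
#' @return logical vector: Mahalanobis distance within the level's
#'   chi-square radius.
#' @export
in_ellipse <- function(e, pts) {
  pts <- as.matrix(pts)
  d <- sweep(pts, 2L, e$center)
  md <- rowSums((d %*% solve(e$cov)) * d)
  md <= qchisq(e$level, df = 2)
}

#' Area of overlap of two confidence ellipses
#'
#' Deterministic grid approximation: the joint bounding box is rasterised and
#' the area of cells falling inside both ellipses summed.
#'
#' @param e1,e2 [confidence_ellipse()] objects.
#' @param n grid resolution per axis.
#' @return the intersection area (same units as the scores, squared).
#' @export
ellipse_overlap <- function(e1, e2, n = 400) {
  b1 <- ellipse_points(e1, 181)
  b2 <- ellipse_points(e2, 181)
  xr <- range(b1[, 1], b2[, 1])
  yr <- range(b1[, 2], b2[, 2])
  gx <- seq(xr[1], xr[2], length.out = n)
  gy <- seq(yr[1], yr[2], length.out = n)
  grid <- cbind(rep(gx, times = n), rep(gy, each = n))
  inside <- in_ellipse(e1, grid) & in_ellipse(e2, grid)
  cell <- diff(gx[1:2]) * diff(gy[1:2])
  sum(inside) * cell
}

#' Score plot with per-niche confidence ellipses
#'
#' @param x an [multigroup_pca()] object.
#' @param level ellipse coverage level.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the list of per-niche ellipses.
#' @importFrom graphics plot points lines legend
#' @export
plot.mgpca <- function(x, level = 0.95, ...) {
  sc <- x$scores[, 1:2, drop = FALSE]
  cols <- setNames(c("#2e7d32", "#f9a825", "#c2185b", "#6a1b9a"), NICHES)
  niche <- x$niche
  plot(sc, type = "n",
       xlab = sprintf("PC1 (%.1f%%)", x$explained_variance_pct[1]),
       ylab = sprintf("PC2 (%.1f%%)", x$explained_variance_pct[2]), ...)
  ells <- list()
  for (nn in unique(niche)) {
    pts <- sc[niche == nn, , drop = FALSE]
    points(pts, col = cols[[nn]], pch = 19, cex = 0.6)
    if (nrow(pts) >= 3) {
      e <- confidence_ellipse(pts, level = level)
      lines(ellipse_points(e), col = cols[[nn]], lwd = 2)
      ells[[nn]] <- e
    }
  }
  legend("topright", legend = names(cols[unique(niche)]),
         col = cols[unique(niche)], pch = 19, bty = "n")
  invisible(ells)
}
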