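#' Centroid size of a landmark configuration
#'
#' The standard geometric-morphometric size measure: the square root of the
#' summed squared distances of the landmarks from their centroid.
#'
#' @param config a `k x 2` numeric matrix of landmarks (or a
#'   [landmark_dataset()], in which case a vector of sizes is returned).
#' @return positive numeric scalar (or vector, one per specimen).
#' @export
centroid_size <- function(config) {
  if (inherits(config, "landmark_dataset"))
    return(vapply(seq_len(config$n),
                  function(i) centroid_size(config$coords[, , i]), 0))
  m <- as.matrix(config)
  if (nrow(m) < 2L) stop("need at least 2 landmarks")
  cs <- sqrt(sum(sweep(m, 2L, colMeans(m))^2))
  if (cs < sqrt(.Machine$double.eps))
    stop("degenerate shape: all landmarks coincide")
  cs
}

## Optimal proper rotation (det +1) of X onto target M, both centered k x 2.
.fit_rotation <- function(X, M) {
  s <- svd(crossprod(X, M))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, d)) %*% t(s$v)
}

#' Generalized Procrustes alignment
#'
#' Iteratively superimposes landmark configurations: each is centred,
#' scaled to unit centroid size, and rotated (proper rotations only) onto
#' the current consensus; the consensus is re-estimated until it moves less
#' than `tol`. Aligned shapes are then projected orthogonally onto the
#' tangent plane at the consensus, where Euclidean geometry applies and
#' principal-component (relative warp) analysis is valid.
#'
#' @param dataset a [landmark_dataset()] with at least 2 specimens.
#' @param tol convergence tolerance on the consensus displacement.
#' @param max_iter maximum number of alignment sweeps.
#' @return an object of class `gpa_fit`: `tangent` (n x 2k matrix of tangent
#'   coordinates, columns x1..xk then y1..yk), `aligned` (k x 2 x n array),
#'   `centroid_sizes` (pre-scaling sizes), `mean_shape` (2k vector, unit
#'   centroid size), `iterations`, `converged`, `k`, `specimen_ids`,
#'   `groups`.
#' @export
gpa <- function(dataset, tol = 1e-10, max_iter = 100L) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  n <- dataset$n
  if (n < 2L) stop("Procrustes alignment needs at least 2 specimens")
  k <- dataset$k
  sizes <- numeric(n)
  X <- array(0, dim = c(k, 2L, n))
  for (i in seq_len(n)) {
    m <- dataset$coords[, , i]
    m <- sweep(m, 2L, colMeans(m))
    sizes[i] <- centroid_size(m)
    X[, , i] <- m / sizes[i]
  }
  consensus <- X[, , 1L]
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n))
      X[, , i] <- X[, , i] %*% .fit_rotation(X[, , i], consensus)
    new_mean <- apply(X, c(1L, 2L), mean)
    new_mean <- sweep(new_mean, 2L, colMeans(new_mean))
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    delta <- sqrt(sum((new_mean - consensus)^2))
    consensus <- new_mean
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("Procrustes alignment did not converge in ", max_iter,
            " iterations")
  ## orthogonal projection onto the tangent plane {y : <y, m> = 1} at the
  ## unit-norm consensus m
  m_vec <- as.vector(consensus)
  flat <- t(apply(X, 3L, as.vector))
  tangent <- flat - (flat %*% m_vec - 1) %*% t(m_vec)
  dimnames(tangent) <- list(dataset$specimen_ids, NULL)
  structure(
    list(tangent = tangent, aligned = X, centroid_sizes = sizes,
         mean_shape = m_vec, iterations = iter, converged = converged,
         k = k, specimen_ids = dataset$specimen_ids,
         groups = dataset$groups),
    class = "gpa_fit")
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat("Generalized Procrustes fit:", nrow(x$tangent), "specimens,",
      x$k, "landmarks;", x$iterations, "iterations",
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  invisible(x)
}

#' Pairwise Procrustes distances between aligned specimens
#'
#' @param fit a `gpa_fit`.
#' @return a `dist` object of Euclidean distances in tangent space.
#' @export
procrustes_distances <- function(fit) {
  stopifnot(inherits(fit, "gpa_fit"))
  stats::dist(fit$tangent)
}

#' Relative warp (shape principal component) decomposition
#'
#' Principal-component analysis of the centred Procrustes tangent
#' coordinates. With the warp-weighting exponent set to zero and the
#' uniform component retained (the tpsRelw default configuration) relative
#' warps coincide with this decomposition, so no thin-plate-spline
#' machinery is required. Axes are ordered by decreasing variance and each
#' axis is oriented so its largest-magnitude loading is positive.
#'
#' @param fit a `gpa_fit` from [gpa()].
#' @return an object of class `shape_space`: `axes` (2k x m orthonormal
#'   loadings), `scores` (n x m, zero-mean columns), `variance_fraction`
#'   (length m, sums to 1), `center` (column means of the tangent
#'   coordinates), plus specimen metadata.
#' @export
relative_warps <- function(fit) {
  stopifnot(inherits(fit, "gpa_fit"))
  n <- nrow(fit$tangent)
  if (n < 3L) stop("relative warp analysis needs at least 3 specimens")
  ctr <- colMeans(fit$tangent)
  Xc <- sweep(fit$tangent, 2L, ctr)
  s <- svd(Xc)
  m <- min(n - 1L, ncol(Xc))
  axes <- s$v[, seq_len(m), drop = FALSE]
  scores <- Xc %*% axes
  ## deterministic sign: largest |loading| positive on every axis
  for (j in seq_len(m)) {
    peak <- which.max(abs(axes[, j]))
    if (axes[peak, j] < 0) {
      axes[, j] <- -axes[, j]
      scores[, j] <- -scores[, j]
    }
  }
  v <- s$d[seq_len(m)]^2 / (n - 1L)
  colnames(scores) <- colnames(axes) <- paste0("RW", seq_len(m))
  rownames(scores) <- fit$specimen_ids
  structure(
    list(axes = axes, scores = scores,
         variance_fraction = stats::setNames(v / sum(v), colnames(axes)),
         center = ctr, specimen_ids = fit$specimen_ids,
         groups = fit$groups, k = fit$k),
    class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  cat("Shape space:", nrow(x$scores), "specimens,", ncol(x$scores),
      "relative warp axes\n")
  vf <- round(100 * x$variance_fraction[seq_len(min(6L, ncol(x$scores)))], 1)
  cat("Variance captured (%):", paste(names(vf), vf, sep = "=",
                                      collapse = ", "), "\n")
  invisible(x)
}

#' Centroid-size allometry correction of shape scores
#'
#' Every relative warp axis is regressed on centroid size by ordinary
#' least squares and the residuals are carried forward, removing the
#' (typically small) allometric component of shape so that range
#' comparisons between groups are not confounded by size. Optionally the
#' regression is fitted within groups (separate intercepts and slopes);
#' the default pools all specimens.
#'
#' @param space a `shape_space` from [relative_warps()].
#' @param centroid_sizes numeric vector of centroid sizes, one per specimen
#'   (e.g. `fit$centroid_sizes`).
#' @param by_group optional character vector of group labels; when supplied
#'   with `pool = FALSE` the size regression is fitted per group.
#' @param pool logical; pool specimens in a single regression (default).
#' @return object of class `size_corrected`: `residuals` (n x m),
#'   `r_squared`, `slopes` (per axis), `centroid_sizes`, metadata.
#' @export
allometry_residuals <- function(space, centroid_sizes, by_group = NULL,
                                pool = TRUE) {
  stopifnot(inherits(space, "shape_space"))
  cs <- as.numeric(centroid_sizes)
  if (length(cs) != nrow(space$scores))
    stop("need one centroid size per specimen")
  if (stats::sd(cs) == 0)
    stop("centroid sizes are all equal: size regression undefined")
  sc <- space$scores
  res <- sc
  r2 <- slopes <- numeric(ncol(sc))
  fit_one <- function(y, x) {
    f <- stats::lm.fit(cbind(1, x), y)
    list(res = f$residuals, slope = f$coefficients[2L])
  }
  if (pool || is.null(by_group)) {
    for (j in seq_len(ncol(sc))) {
      f <- fit_one(sc[, j], cs)
      res[, j] <- f$res
      slopes[j] <- f$slope
      tss <- sum((sc[, j] - mean(sc[, j]))^2)
      r2[j] <- if (tss > 0) 1 - sum(f$res^2) / tss else 0
    }
  } else {
    g <- as.character(by_group)
    for (j in seq_len(ncol(sc))) {
      for (lev in unique(g)) {
        idx <- g == lev
        if (stats::sd(cs[idx]) == 0)
          stop("group ", lev, ": centroid sizes all equal")
        res[idx, j] <- fit_one(sc[idx, j], cs[idx])$res
      }
      tss <- sum((sc[, j] - mean(sc[, j]))^2)
      r2[j] <- if (tss > 0) 1 - sum(res[, j]^2) / tss else 0
      slopes[j] <- NA_real_
    }
  }
  names(r2) <- names(slopes) <- colnames(sc)
  structure(
    list(residuals = res, r_squared = r2, slopes = slopes,
         centroid_sizes = cs, specimen_ids = space$specimen_ids,
         groups = space$groups),
    class = "size_corrected")
}

#' @export
print.size_corrected <- function(x, ...) {
  cat("Size-corrected shape scores:", nrow(x$residuals), "specimens,",
      ncol(x$residuals), "axes\n")
  cat("Size R-squared:",
      paste(names(x$r_squared)[1:min(6, length(x$r_squared))],
            round(x$r_squared[1:min(6, length(x$r_squared))], 3),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Export shape scores as a delimited table
#'
#' @param corrected a `size_corrected` object.
#' @param path output path (tab-separated).
#' @param groups optional named character vector of group labels.
#' @export
write_scores <- function(corrected, path, groups = NULL) {
  stopifnot(inherits(corrected, "size_corrected"))
  if (is.null(groups)) groups <- corrected$groups
  ids <- corrected$specimen_ids
  tab <- data.frame(specimen_id = ids,
                    group = if (is.null(groups)) NA_character_
                            else unname(groups[ids]),
                    CS = corrected$centroid_sizes,
                    corrected$residuals, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
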