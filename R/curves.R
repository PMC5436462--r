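#' Function-valued observations over genomic positions
#'
#' A `position_curve` holds one curve per sample: a strictly increasing vector
#' of genomic positions and a numeric matrix with one row per sample and one
#' column per position.  The region `[start, end]` is the interval the curve
#' lives on; positions are mapped affinely to `[0, 1]` before any functional
#' operation.
#'
#' @param values numeric matrix, samples in rows, positions in columns.
#' @param positions strictly increasing numeric vector, one per column.
#' @param chrom chromosome label (metadata only).
#' @param start,end region bounds; default to the position range.
#' @return an object of class `position_curve`.
#' @export
position_curve <- function(values, positions, chrom = ".",
                           start = min(positions), end = max(positions)) {
  values <- as.matrix(values)
  if (!is.numeric(values) || !all(is.finite(values)))
    stop("curve values must be finite numerics")
  positions <- as.numeric(positions)
  if (ncol(values) != length(positions))
    stop("one position per value column required")
  if (length(positions) > 1 && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (any(positions < start) || any(positions > end))
    stop("positions outside [start, end]")
  structure(list(values = values, positions = positions,
                 chrom = chrom, start = start, end = end),
            class = "position_curve")
}

#' @export
print.position_curve <- function(x, ...) {
  cat(sprintf("<position_curve> %d samples x %d positions, %s:[%s, %s]\n",
              nrow(x$values), length(x$positions), x$chrom,
              format(x$start), format(x$end)))
  invisible(x)
}

#' Uniform grid on the unit interval
#'
#' `m + 1` equally spaced points `0, 1/m, ..., 1` used as the common support
#' after regridding.  Grids with fewer than 4 sub-intervals are refused since
#' trapezoid quadrature on them is meaningless.
#'
#' @param m number of sub-intervals (>= 4).
#' @return object of class `common_grid` with elements `m` and `points`.
#' @export
common_grid <- function(m) {
  m <- as.integer(m)
  if (is.na(m) || m < 4L) stop("common_grid needs m >= 4 sub-intervals")
  structure(list(m = m, points = seq(0, 1, length.out = m + 1L)),
            class = "common_grid")
}

## Trapezoid quadrature weights for arbitrary strictly increasing nodes.
## A single node gets weight 1 (point mass), so inner products degenerate to
## plain products rather than zero.
trapezoid_weights <- function(points) {
  p <- length(points)
  if (p == 1L) return(1)
  d <- diff(points)
  c(d[1] / 2, (d[-1] + d[-(p - 1)]) / 2, d[p - 1] / 2)
}

## Affine map of positions onto [0,1] using the region bounds.
unit_positions <- function(curve) {
  span <- curve$end - curve$start
  if (span <= 0) stop("degenerate region: end <= start")
  (curve$positions - curve$start) / span
}

#' Regrid curves to a common grid by local polynomial (LOESS) smoothing
#'
#' Each sample's curve is smoothed with a tricube-weighted local polynomial
#' fit and evaluated at the grid points.  Positions are first mapped affinely
#' to `[0, 1]` via `(pos - start) / (end - start)`.  Because all samples share
#' the same positions, the smoother is a single matrix applied to every row,
#' and reproduces `stats::loess(..., surface = "direct")` exactly for the same
#' span and degree.
#'
#' @param curve a [position_curve()].
#' @param grid a [common_grid()].
#' @param span neighbourhood fraction in (0, 1]; the local fit at a grid point
#'   uses the `floor(span * p)` nearest positions.
#' @param degree local polynomial degree (1 or 2).
#' @return a `position_curve` on the grid points (region `[0, 1]`).
#' @export
regrid_loess <- function(curve, grid, span = 0.3, degree = 2) {
  stopifnot(inherits(curve, "position_curve"), inherits(grid, "common_grid"))
  if (!(span > 0 && span <= 1)) stop("span must be in (0, 1]")
  degree <- as.integer(degree)
  if (!degree %in% 1:2) stop("degree must be 1 or 2")
  x <- unit_positions(curve)
  p <- length(x)
  if (p < degree + 2L)
    stop("insufficient support: need at least degree + 2 distinct positions")
  q <- floor(span * p)
  if (q < degree + 2L)
    stop("insufficient support: span * p below degree + 2; increase span")
  L <- loess_matrix(x, grid$points, q, degree)
  position_curve(curve$values %*% t(L), grid$points,
                 chrom = curve$chrom, start = 0, end = 1)
}

## Smoothing matrix of the tricube local polynomial: row g gives the weights
## that map observed values at x to the fitted value at x0[g].
loess_matrix <- function(x, x0, q, degree) {
  L <- matrix(0, length(x0), length(x))
  for (g in seq_along(x0)) {
    d <- abs(x - x0[g])
    h <- sort(d, partial = q)[q]
    if (h <= 0) h <- max(d[d > 0][1], .Machine$double.eps)
    w <- (1 - pmin(d / h, 1)^3)^3
    keep <- which(w > 0)
    X <- outer(x[keep] - x0[g], 0:degree, `^`)
    XtW <- t(X * w[keep])
    beta_row <- solve(XtW %*% X, XtW)[1L, ]
    L[g, keep] <- beta_row
  }
  L
}

#' Functional principal component analysis on a common grid
#'
#' Eigendecomposition of the quadrature-weighted sample covariance operator.
#' With nodes `t_1 < ... < t_p` and trapezoid weights `w`, the discretized
#' operator is `W^{1/2} C W^{1/2}` for the pointwise sample covariance `C`;
#' its eigenvectors are rescaled to eigenfunctions orthonormal under the
#' quadrature rule, and scores are quadrature inner products of the centered
#' rows with the eigenfunctions, so `var(score_j) ~ eigenvalue_j`.
#'
#' Eigenfunction signs are fixed so the element of largest absolute value is
#' positive (first such element on ties), making the output deterministic.
#'
#' @param curve a [position_curve()] whose columns all live on the same nodes
#'   (a regridded curve, or any position-indexed matrix wrapped as one).
#' @param n_components number of components to retain; if it exceeds the rank
#'   of the data the basis is truncated and flagged, not an error.
#' @param var_threshold alternatively, retain the smallest number of
#'   components whose cumulative variance fraction reaches this value.
#' @return list with `basis` (class `eigen_basis`: nodes, quadrature weights,
#'   `mean_fn`, retained `eigenfunctions` (component x node), all
#'   `eigenvalues`, cumulative `var_explained` for retained components,
#'   `n_retained`, `rank`, `truncated`) and `scores` (n x J matrix).
#' @export
fit_fpca <- function(curve, n_components = NULL, var_threshold = NULL) {
  stopifnot(inherits(curve, "position_curve"))
  X <- curve$values
  n <- nrow(X)
  if (n < 2L) stop("FPCA needs at least 2 samples")
  pts <- unit_positions(curve)
  w <- trapezoid_weights(pts)
  mean_fn <- colMeans(X)
  Xc <- sweep(X, 2L, mean_fn)
  sw <- sqrt(w)
  B <- sweep(Xc, 2L, sw, `*`)
  C <- crossprod(B) / (n - 1)
  eig <- eigen(C, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  total <- sum(lambda)
  rank <- sum(lambda > max(lambda[1], .Machine$double.eps) * 1e-12)
  phi_all <- t(eig$vectors) / rep(sw, each = ncol(C))  # component x node

  J <- select_components(lambda, rank, n_components, var_threshold)
  truncated <- !is.null(n_components) && n_components > rank
  phi <- phi_all[seq_len(J), , drop = FALSE]
  ## deterministic sign: largest-|.| element of each eigenfunction positive
  for (j in seq_len(J)) {
    i <- which.max(abs(phi[j, ]))
    if (phi[j, i] < 0) phi[j, ] <- -phi[j, ]
  }
  scores <- Xc %*% t(sweep(phi, 2L, w, `*`))
  var_explained <- if (total > 0) cumsum(lambda[seq_len(J)]) / total
                   else rep(NA_real_, J)
  basis <- structure(list(points = pts, weights = w, mean_fn = mean_fn,
                          eigenfunctions = phi, eigenvalues = lambda,
                          var_explained = var_explained, n_retained = J,
                          rank = rank, truncated = truncated),
                     class = "eigen_basis")
  list(basis = basis, scores = scores)
}

select_components <- function(lambda, rank, n_components, var_threshold) {
  if (rank == 0L) return(1L)  # degenerate data: keep one (zero) component
  if (!is.null(n_components)) return(min(as.integer(n_components), rank))
  if (!is.null(var_threshold)) {
    frac <- cumsum(lambda) / sum(lambda)
    return(min(which(frac >= var_threshold - 1e-12)[1], rank))
  }
  rank
}

#' @export
print.eigen_basis <- function(x, ...) {
  cat(sprintf("<eigen_basis> %d components on %d nodes (rank %d%s)\n",
              x$n_retained, length(x$points), x$rank,
              if (x$truncated) ", truncated" else ""))
  invisible(x)
}

#' Expansion coefficients of curves in an eigenbasis
#'
#' Quadrature (trapezoid) approximation of the inner products
#' `int (x_i(t) - mean(t)) phi_j(t) dt`.  With `center = FALSE` the basis mean
#' function is ignored and the raw inner products are returned.
#'
#' @param curve a [position_curve()] on the same nodes as `basis`.
#' @param basis an `eigen_basis` from [fit_fpca()].
#' @param center subtract the basis mean function first (default `TRUE`,
#'   which reproduces the scores returned by [fit_fpca()]).
#' @return n x J score matrix.
#' @export
expand_coefficients <- function(curve, basis, center = TRUE) {
  stopifnot(inherits(curve, "position_curve"), inherits(basis, "eigen_basis"))
  pts <- unit_positions(curve)
  if (length(pts) != length(basis$points) ||
      max(abs(pts - basis$points)) > 1e-10)
    stop("grid mismatch between curve and basis")
  X <- curve$values
  if (center) X <- sweep(X, 2L, basis$mean_fn)
  X %*% t(sweep(basis$eigenfunctions, 2L, basis$weights, `*`))
}

#' Read / write per-position count tables
#'
#' The on-disk format is a TSV with header `chrom pos sample_1 ... sample_n`,
#' positions 1-based inclusive, one row per genomic position.  The writer
#' mirrors the reader so a round trip is bit-exact for integer counts.
#'
#' @param path file path.
#' @return [position_curve()] with samples as rows.
#' @export
read_position_counts <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("expected columns: chrom, pos, then samples")
  vals <- t(as.matrix(tab[, -(1:2), drop = FALSE]))
  storage.mode(vals) <- "double"
  rownames(vals) <- colnames(tab)[-(1:2)]
  position_curve(vals, tab[[2]], chrom = as.character(tab[[1]][1]))
}

#' @param curve a [position_curve()].
#' @rdname read_position_counts
#' @export
write_position_counts <- function(curve, path) {
  tab <- data.frame(chrom = curve$chrom, pos = curve$positions,
                    t(curve$values), check.names = FALSE)
  names(tab)[-(1:2)] <- rownames(curve$values) %||%
    paste0("sample_", seq_len(nrow(curve$values)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
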