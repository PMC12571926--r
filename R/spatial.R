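# The combinatorial barcode grid: pixel coordinates, affine registration onto
# a bright-field image frame, and neighbour-based smoothing.

#' Build a pixel grid
#'
#' Maps barcode index pairs to grid coordinates: barcode A index is the row,
#' barcode B index the column, both 1-based, so `(A1, B1)` is pixel `(1, 1)`.
#'
#' @param n_a,n_b number of A and B barcodes.
#' @param pixel_size_um physical pixel pitch in micrometres.
#' @return object of class `pixel_grid` with `rows`, `cols`, `pixel_size_um`,
#'   `pixels` (data.frame pixel/a/b/row/col) and an optional affine transform
#'   (set by [register_affine()]).
#' @export
make_grid <- function(n_a, n_b, pixel_size_um = 50) {
  if (n_a < 1L || n_b < 1L) stop("grid dimensions must be >= 1")
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  cells <- expand.grid(b = seq_len(n_b), a = seq_len(n_a))
  pixels <- data.frame(pixel = .pixel_id(cells$a, cells$b),
                       a = cells$a, b = cells$b,
                       row = cells$a, col = cells$b,
                       stringsAsFactors = FALSE)
  pixels <- pixels[order(pixels$row, pixels$col), ]
  rownames(pixels) <- NULL
  structure(list(rows = as.integer(n_a), cols = as.integer(n_b),
                 pixel_size_um = pixel_size_um, pixels = pixels,
                 transform = NULL),
            class = "pixel_grid")
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat(sprintf("pixel_grid: %d x %d = %d pixels, %.3g um pitch%s\n",
              x$rows, x$cols, x$rows * x$cols, x$pixel_size_um,
              if (is.null(x$transform)) "" else ", registered"))
  invisible(x)
}

#' Least-squares affine registration of grid to image coordinates
#'
#' Fits `(x, y) = A %*% (row, col) + b` by ordinary least squares from at
#' least three non-collinear correspondences (e.g. fiducial pixels located on
#' the bright-field image). Exact for an exactly affine correspondence set.
#'
#' @param grid_points numeric matrix/data.frame of `(row, col)` grid
#'   coordinates.
#' @param image_points matching `(x, y)` image coordinates (x right, y down).
#' @return object of class `affine2d`: list with `A` (2 x 2), `b` (length 2),
#'   `residuals` (n x 2) and `rmse`.
#' @export
register_affine <- function(grid_points, image_points) {
  G <- as.matrix(grid_points)
  P <- as.matrix(image_points)
  if (nrow(G) < 3L || nrow(G) != nrow(P) || ncol(G) != 2L || ncol(P) != 2L) {
    stop("need >= 3 matching (row, col) and (x, y) points")
  }
  X <- cbind(1, G)
  if (qr(X)$rank < 3L) stop("correspondence points are collinear")
  beta <- qr.solve(X, P)              # 3 x 2: intercept then row/col coefs
  fitted <- X %*% beta
  res <- P - fitted
  structure(list(A = unname(t(beta[2:3, , drop = FALSE])),
                 b = as.numeric(beta[1L, ]),
                 residuals = res, rmse = sqrt(mean(res^2))),
            class = "affine2d")
}

#' Apply an affine transform to grid coordinates
#'
#' @param transform an `affine2d` from [register_affine()].
#' @param points matrix/data.frame of `(row, col)` coordinates.
#' @return numeric matrix of `(x, y)` image coordinates.
#' @export
apply_affine <- function(transform, points) {
  stopifnot(inherits(transform, "affine2d"))
  P <- as.matrix(points)
  if (is.null(dim(P)) || ncol(P) != 2L) P <- matrix(P, ncol = 2L)
  out <- P %*% t(transform$A) +
    matrix(transform$b, nrow(P), 2L, byrow = TRUE)
  colnames(out) <- c("x", "y")
  out
}

#' @export
print.affine2d <- function(x, ...) {
  cat("affine2d transform:\n  A =", sprintf("[%.4g %.4g; %.4g %.4g]",
      x$A[1, 1], x$A[1, 2], x$A[2, 1], x$A[2, 2]),
      sprintf(" b = (%.4g, %.4g), rmse %.3g\n", x$b[1], x$b[2], x$rmse))
  invisible(x)
}

#' k-nearest-neighbour smoothing on the pixel grid
#'
#' Replaces each pixel's value by the uniform mean over its `k` nearest
#' pixels by Euclidean grid distance (plus itself when `include_self`).
#' Missing neighbours are excluded from the mean; a neighbourhood that is
#' entirely missing stays missing. Distance ties are broken by `(row, col)`
#' lexicographic order for determinism.
#'
#' @param values numeric vector named by pixel id, or ordered like
#'   `grid$pixels`.
#' @param grid a [make_grid()] object.
#' @param k number of neighbours (>= 1).
#' @param include_self include the pixel's own value in the mean.
#' @param wrap treat the grid as a torus (used to test mean preservation on a
#'   boundary-free lattice).
#' @return smoothed numeric vector, named by pixel id.
#' @export
nn_smooth <- function(values, grid, k = 4L, include_self = FALSE,
                      wrap = FALSE) {
  px <- grid$pixels
  n <- nrow(px)
  if (k < 0L || (k == 0L && !include_self)) {
    stop("k must be >= 1 (or 0 with include_self = TRUE)")
  }
  if (k > n - 1L) stop("k larger than the number of other pixels")
  if (!is.null(names(values))) {
    v <- values[px$pixel]
  } else {
    if (length(values) != n) stop("values length does not match grid")
    v <- values
  }
  dr <- abs(outer(px$row, px$row, "-"))
  dc <- abs(outer(px$col, px$col, "-"))
  if (wrap) {
    dr <- pmin(dr, grid$rows - dr)
    dc <- pmin(dc, grid$cols - dc)
  }
  d2 <- dr^2 + dc^2
  ord_key <- order(px$row, px$col)      # lexicographic tie-break rank
  rank_lex <- match(seq_len(n), ord_key)
  out <- numeric(n)
  for (i in seq_len(n)) {
    o <- order(d2[i, ], rank_lex)
    o <- o[o != i][seq_len(k)]
    if (include_self) o <- c(i, o)
    vals <- v[o]
    vals <- vals[!is.na(vals)]
    out[i] <- if (length(vals)) mean(vals) else NA_real_
  }
  names(out) <- px$pixel
  out
}
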