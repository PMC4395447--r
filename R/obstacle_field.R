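#' Rasterize obstacle polygons onto a grid
#'
#' Marks a cell occupied iff its center lies inside any polygon (even-odd
#' rule). This is the level-set discretization underlying the
#' contiguous-free-space field.
#'
#' @param polygons list of simple polygons, each an n x 2 matrix of vertices
#'   (closed implicitly; the last vertex connects back to the first).
#' @param cell_size grid cell size c_b (m).
#' @param bounds numeric length-4 `c(xmin, xmax, ymin, ymax)`.
#' @return A logical matrix (nx x ny, TRUE = occupied) with attributes
#'   `origin` (grid origin, the lower-left corner) and `cell_size`.
#' @examples
#' sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
#' occ <- rasterize_polygons(list(sq), 0.5, c(0, 1, 0, 1))
#' sum(occ)  # 4
#' @export
rasterize_polygons <- function(polygons, cell_size, bounds) {
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("cell_size must be positive")
  stopifnot(length(bounds) == 4, bounds[2] > bounds[1], bounds[4] > bounds[3])
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2) stop("each polygon must be an n x 2 matrix")
    if (nrow(p) >= 2 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    p
  })
  area <- vapply(polygons, polygon_area, numeric(1))
  if (length(polygons) && any(area == 0))
    warning("zero-area polygon: no cells marked for it")
  nx <- max(1L, ceiling((bounds[2] - bounds[1]) / cell_size))
  ny <- max(1L, ceiling((bounds[4] - bounds[3]) / cell_size))
  cx <- bounds[1] + (seq_len(nx) - 0.5) * cell_size
  cy <- bounds[3] + (seq_len(ny) - 0.5) * cell_size
  pts <- expand.grid(x = cx, y = cy)
  keep <- polygons[vapply(polygons, nrow, integer(1)) >= 3 & area > 0]
  occ <- if (length(keep)) {
    matrix(cpp_points_in_polygons(pts$x, pts$y, keep), nx, ny)
  } else {
    matrix(FALSE, nx, ny)
  }
  attr(occ, "origin") <- c(bounds[1], bounds[3])
  attr(occ, "cell_size") <- cell_size
  occ
}

polygon_area <- function(p) {
  p <- as.matrix(p)
  n <- nrow(p)
  if (n < 3) return(0)
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# truncated, renormalized isotropic Gaussian stencil over a disk of
# support_radius; in open space the reachable mass is the full kernel, so FS
# is exactly 1 there
fs_kernel <- function(support_radius, cell_size, kernel_sigma = support_radius / 2) {
  R <- max(1L, as.integer(ceiling(support_radius / cell_size)))
  off <- (-R):R
  d2 <- outer(off^2, off^2, "+") * cell_size^2
  k <- exp(-d2 / (2 * kernel_sigma^2))
  k[sqrt(d2) > support_radius + 1e-12] <- 0
  k / sum(k)
}

#' Compute the contiguous-free-space lattice
#'
#' For each free cell, FS is the mass of a normalized Gaussian stencil summed
#' over the support cells that are 4-connected-reachable from the cell
#' through free cells inside the support ("contiguous": pockets of free space
#' sealed off by walls do not count). Occupied cells carry `NA`.
#'
#' @param occupancy logical occupancy lattice from [rasterize_polygons()].
#' @param kernel normalized weight stencil (square, odd side, zero outside
#'   the circular support), e.g. from the internal builder used by
#'   [obstacle_field()].
#' @return Numeric matrix of FS values in `[0, 1]` (NA on occupied cells).
#' @export
compute_fs_field <- function(occupancy, kernel) {
  if (abs(sum(kernel) - 1) > 1e-8)
    stop("kernel must be normalized to sum to 1 over its support")
  cpp_fs_field(occupancy, kernel)
}

#' Build an obstacle field with a precomputed free-space lattice
#'
#' Discretizes the obstacle polygons at cell size `cell_size` and computes
#' the contiguous-free-space (FS) field once, offline; simulation queries are
#' then bilinear interpolations.
#'
#' @inheritParams rasterize_polygons
#' @param support_radius compact support radius (m) of the FS kernel.
#' @param kernel_sigma Gaussian width (m) of the FS kernel (default half the
#'   support radius).
#' @return An object of class `ped_obstacle_field` with fields `origin`,
#'   `cell_size`, `occupancy`, `fs`, `kernel`, `bounds`, `polygons`.
#' @export
obstacle_field <- function(polygons, bounds, cell_size = 0.1,
                           support_radius = 1.0,
                           kernel_sigma = support_radius / 2) {
  occ <- rasterize_polygons(polygons, cell_size, bounds)
  kern <- fs_kernel(support_radius, cell_size, kernel_sigma)
  fs <- compute_fs_field(occ, kern)
  structure(
    list(origin = attr(occ, "origin"), cell_size = cell_size,
         occupancy = occ, fs = fs, kernel = kern, bounds = as.numeric(bounds),
         support_radius = support_radius, polygons = polygons),
    class = "ped_obstacle_field")
}

#' Query the free-space field at a point
#'
#' Bilinear interpolation of FS over the four surrounding cell centers.
#' Occupied corners are dropped (weights renormalized); a query falling where
#' all four corners are occupied returns the minimum positive FS of nearby
#' free cells, since probe points may legally graze obstacle cells.
#'
#' @param field a `ped_obstacle_field`.
#' @param q numeric length-2 position, or an n x 2 matrix of positions.
#' @return FS value(s) in `(0, 1]`.
#' @export
fs_at <- function(field, q) {
  q <- if (is.matrix(q)) q else matrix(q, ncol = 2)
  b <- field$bounds
  if (any(q[, 1] < b[1] - 1e-9 | q[, 1] > b[2] + 1e-9 |
          q[, 2] < b[3] - 1e-9 | q[, 2] > b[4] + 1e-9))
    stop("query point outside the obstacle-field bounds")
  cpp_fs_bilinear(field$fs, field$origin[1], field$origin[2],
                  field$cell_size, q[, 1], q[, 2])
}

#' @export
print.ped_obstacle_field <- function(x, ...) {
  cat("<ped_obstacle_field> ", nrow(x$occupancy), "x", ncol(x$occupancy),
      " cells (c_b=", x$cell_size, " m), ", sum(x$occupancy),
      " occupied, support=", x$support_radius, " m\n", sep = "")
  invisible(x)
}
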