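## Polar re-encoding of anatomical masks about the blood-pool centroid.

#' Blood-pool centroid of an anatomical mask
#'
#' The blood pool is the background region fully enclosed by the myocardium
#' foreground.  It is found by filling the holes of the foreground
#' (EBImage); its pixel centroid is returned in the mask's mm frame.  For
#' apical cap discs with no cavity the foreground centroid is used and a
#' warning is emitted.
#'
#' @param mask an `anatomical_mask`.
#' @return numeric length-2 mm point `(x, y)`; attribute `pixel` holds the
#'   (row, col) centroid and `fallback` whether the disc fallback fired.
#' @export
blood_pool_centroid <- function(mask) {
  g <- mask$grid
  if (sum(g) == 0L) stop("empty mask: no foreground")
  filled <- EBImage::fillHull(g)
  cavity <- which(filled == 1L & g == 0L, arr.ind = TRUE)
  fallback <- FALSE
  if (nrow(cavity) == 0L) {
    warning("mask has no enclosed cavity; using foreground centroid")
    cavity <- which(g == 1L, arr.ind = TRUE)
    fallback <- TRUE
  }
  rc <- colMeans(cavity)
  pt <- c(mask$origin[1L] + (rc[2L] - 1) * mask$resolution,
          mask$origin[2L] + (rc[1L] - 1) * mask$resolution)
  structure(pt, pixel = rc, fallback = fallback)
}

#' Convert an anatomical mask to polar coordinates
#'
#' Output pixel (row r, column k) samples the Cartesian mask at
#' `center + (r-1) * radial_res * (cos theta, sin theta)` with
#' `theta = (k-1) * 360/size` degrees, nearest-neighbor, zero outside the
#' grid.  Row 1 is radius 0; the angular origin is along +x of the mask
#' frame, counter-clockwise.
#'
#' @param mask an `anatomical_mask`.
#' @param center 2D mm point; defaults to [blood_pool_centroid()].
#' @param size output side (default 256): radial rows at 1 mm, angular
#'   columns at 360/size degrees.
#' @return A `polar_mask`: integer grid plus `radial_resolution`,
#'   `angular_resolution` (degrees/column) and `center_used`.
#' @export
to_polar <- function(mask, center = NULL, size = 256L) {
  if (is.null(center)) center <- blood_pool_centroid(mask)
  res <- mask$resolution
  nr <- nrow(mask$grid); nc <- ncol(mask$grid)
  cx <- (center[1L] - mask$origin[1L]) / res + 1
  cy <- (center[2L] - mask$origin[2L]) / res + 1
  if (cx < 1 || cx > nc || cy < 1 || cy > nr)
    stop("polar center lies outside the mask grid")
  radii <- (seq_len(size) - 1L) * 1.0 / res          # in pixels (1 mm rows)
  theta <- (seq_len(size) - 1L) * 2 * pi / size
  xs <- round(outer(radii, cos(theta)) + cx)         # column indices
  ys <- round(outer(radii, sin(theta)) + cy)         # row indices
  ok <- xs >= 1 & xs <= nc & ys >= 1 & ys <= nr
  grid <- matrix(0L, size, size)
  grid[ok] <- mask$grid[cbind(ys[ok], xs[ok])]
  structure(list(grid = grid, radial_resolution = 1.0,
                 angular_resolution = 360 / size,
                 center_used = as.numeric(center),
                 patient_id = mask$patient_id,
                 slice_index = mask$slice_index,
                 normalized_position = mask$normalized_position),
            class = "polar_mask")
}

#' Pad a polar mask at the large-radius end
#'
#' Appends zero rows at the outer-radius end to bring the grid back to
#' `size x size`, compensating for centroids near the Cartesian edge that
#' shorten the sampled radial extent.
#'
#' @param mask a `polar_mask` (rows <= `size`).
#' @param size target side length (default 256).
#' @return a `polar_mask` with exactly `size` rows.
#' @export
pad_polar <- function(mask, size = 256L) {
  nr <- nrow(mask$grid)
  if (nr > size) stop(sprintf("polar mask has %d rows; cannot pad to %d", nr, size))
  if (nr < size)
    mask$grid <- rbind(mask$grid,
                       matrix(0L, size - nr, ncol(mask$grid)))
  mask
}

#' @export
print.polar_mask <- function(x, ...) {
  cat(sprintf("polar mask %dx%d (%.0f mm radial, %.3f deg angular), %d foreground px\n",
              nrow(x$grid), ncol(x$grid), x$radial_resolution,
              x$angular_resolution, sum(x$grid)))
  invisible(x)
}

#' @export
print.anatomical_mask <- function(x, ...) {
  cat(sprintf("anatomical mask %dx%d @ %.0f mm/px, %d foreground px\n",
              nrow(x$grid), ncol(x$grid), x$resolution, sum(x$grid)))
  invisible(x)
}

#' Minimum radial wall thickness of a polar mask
#'
#' For every angular column with any foreground, the wall thickness is the
#' number of foreground rows (mm at 1 mm radial resolution); the minimum
#' over columns is the slice's thinnest wall.
#'
#' @param polar a `polar_mask`.
#' @return minimum thickness in mm (Inf for an empty mask).
#' @export
min_wall_thickness <- function(polar) {
  cs <- colSums(polar$grid)
  cs <- cs[cs > 0L]
  if (length(cs) == 0L) return(Inf)
  min(cs) * polar$radial_resolution
}
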