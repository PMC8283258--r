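#' Triangulated surface mesh
#'
#' Light container for a triangulated surface: an `n x 3` matrix of vertex
#' coordinates in millimetres and an `m x 3` integer matrix of 1-based
#' vertex indices per triangular face.
#'
#' @param vertices numeric `n x 3` matrix, mm.
#' @param faces integer `m x 3` matrix of vertex indices.
#' @return A list of class `surface_mesh` with elements `vertices`, `faces`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' Boundary edges of a triangulated surface
#'
#' An edge of a closed (watertight) manifold surface belongs to exactly two
#' faces.  Returns the edges that do not, as a two-column index matrix
#' (zero rows for a closed surface).
#'
#' @param mesh a [surface_mesh()].
#' @return integer matrix of boundary (or over-shared) edges.
#' @export
boundary_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  tab <- table(key)
  bad <- names(tab)[tab != 2L]
  if (length(bad) == 0L) return(matrix(integer(0), 0L, 2L))
  m <- do.call(rbind, strsplit(bad, " "))
  matrix(as.integer(m), ncol = 2L)
}

#' Test whether a surface mesh is closed
#' @param mesh a [surface_mesh()].
#' @return logical.
#' @export
is_closed <- function(mesh) nrow(boundary_edges(mesh)) == 0L

#' Enclosed volume of a closed surface mesh
#'
#' Divergence-theorem volume from signed tetrahedra against the origin.
#' Orientation-independent (absolute value).
#'
#' @param mesh a [surface_mesh()].
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  d <- v[f[, 3L], , drop = FALSE]
  det6 <- a[, 1L] * (b[, 2L] * d[, 3L] - b[, 3L] * d[, 2L]) -
          a[, 2L] * (b[, 1L] * d[, 3L] - b[, 3L] * d[, 1L]) +
          a[, 3L] * (b[, 1L] * d[, 2L] - b[, 2L] * d[, 1L])
  abs(sum(det6)) / 6
}

#' Left-ventricle mesh pair
#'
#' The root input of the pipeline: a closed epicardial surface, a closed
#' endocardial surface strictly inside it, an optional closed scar sub-mesh
#' lying within the myocardial shell, and optional valve annulus marker
#' points on the basal rim.
#'
#' @param patient_id opaque identifier (character).
#' @param epi,endo epicardial / endocardial [surface_mesh()] objects, mm.
#' @param scar optional scar [surface_mesh()].
#' @param valve_points optional `k x 3` matrix of valve annulus markers, mm.
#' @param validate run the structural invariant checks (closedness, nesting
#'   proxy, finiteness).  Disable only for meshes already validated.
#' @return A list of class `lv_mesh`.
#' @export
lv_mesh <- function(patient_id, epi, endo, scar = NULL, valve_points = NULL,
                    validate = TRUE) {
  if (!inherits(epi, "surface_mesh")) epi <- do.call(surface_mesh, epi)
  if (!inherits(endo, "surface_mesh")) endo <- do.call(surface_mesh, endo)
  if (!is.null(scar) && !inherits(scar, "surface_mesh"))
    scar <- do.call(surface_mesh, scar)
  if (!is.null(valve_points)) {
    valve_points <- as.matrix(valve_points)
    if (ncol(valve_points) != 3L) stop("valve_points must be k x 3")
  }
  m <- structure(list(patient_id = as.character(patient_id),
                      epi = epi, endo = endo, scar = scar,
                      valve_points = valve_points),
                 class = "lv_mesh")
  if (validate) validate_lv_mesh(m)
  m
}

#' Validate the structural invariants of an LV mesh
#'
#' Checks that both surfaces are closed, that the endocardial volume is
#' strictly smaller than the epicardial one (nesting proxy), that all
#' coordinates are finite, and that a scar mesh, if present, is closed and
#' contained in the epicardial bounding box expanded by `tol`.
#'
#' @param mesh an [lv_mesh()].
#' @param tol containment tolerance in mm for the scar sub-mesh.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_lv_mesh <- function(mesh, tol = 1.0) {
  if (!is_closed(mesh$epi)) stop("epicardial surface is not closed")
  if (!is_closed(mesh$endo)) stop("endocardial surface is not closed")
  if (mesh_volume(mesh$endo) >= mesh_volume(mesh$epi))
    stop("endocardial surface not inside epicardial surface (volume check)")
  if (!is.null(mesh$scar)) {
    be <- boundary_edges(mesh$scar)
    if (nrow(be) > 0L)
      stop(sprintf("scar mesh is open: %d boundary edges (first: %d-%d)",
                   nrow(be), be[1L, 1L], be[1L, 2L]))
    lo <- apply(mesh$epi$vertices, 2L, min) - tol
    hi <- apply(mesh$epi$vertices, 2L, max) + tol
    sv <- mesh$scar$vertices
    if (any(sweep(sv, 2L, lo) < 0) || any(sweep(sv, 2L, hi) > 0))
      stop("scar mesh extends outside the epicardial extent")
  }
  invisible(TRUE)
}

#' @export
print.lv_mesh <- function(x, ...) {
  cat(sprintf("LV mesh '%s': epi %d vertices / %d faces, endo %d/%d%s%s\n",
              x$patient_id,
              nrow(x$epi$vertices), nrow(x$epi$faces),
              nrow(x$endo$vertices), nrow(x$endo$faces),
              if (is.null(x$scar)) "" else
                sprintf(", scar %d/%d", nrow(x$scar$vertices), nrow(x$scar$faces)),
              if (is.null(x$valve_points)) "" else
                sprintf(", %d valve markers", nrow(x$valve_points))))
  invisible(x)
}

#' Long/short axis frame of an LV mesh
#'
#' The long axis is the first principal component of the epicardial vertex
#' cloud, oriented apex-to-base.  The base side is the one nearer the valve
#' markers when present; otherwise the end whose endocardial cross-section
#' is wider (mean radial distance of endocardial vertices in the outer 20%
#' of the axis, a monotone proxy for cavity area).
#'
#' @param mesh an [lv_mesh()].
#' @return A list of class `axis_frame` with `apex_point`, `base_point`,
#'   `long_axis` (unit vector), `length` (mm).
#' @export
compute_axes <- function(mesh) {
  v <- mesh$epi$vertices
  if (nrow(v) < 4L) stop("need at least 4 epicardial vertices")
  ctr <- colMeans(v)
  vc <- sweep(v, 2L, ctr)
  ee <- eigen(crossprod(vc) / nrow(vc), symmetric = TRUE)
  ev <- ee$values
  if (ev[2L] <= 1e-10 * max(ev[1L], 1))
    stop("degenerate epicardial vertex cloud: rank 1 (collinear points)")
  if (ev[3L] <= 1e-10 * max(ev[1L], 1))
    stop("degenerate epicardial vertex cloud: rank 2 (coplanar points)")
  if ((ev[1L] - ev[2L]) <= 1e-6 * ev[1L])
    warning("near-spherical vertex cloud: principal axis is ambiguous; ",
            "using deterministic eigenvector ordering")
  ax <- ee$vectors[, 1L]
  # deterministic sign before anatomical orientation
  k <- which.max(abs(ax))
  if (ax[k] < 0) ax <- -ax
  t_epi <- drop(vc %*% ax)
  if (!is.null(mesh$valve_points)) {
    tv <- mean(sweep(mesh$valve_points, 2L, ctr) %*% ax)
    if (tv < mean(range(t_epi))) ax <- -ax
  } else {
    # wider endocardial cross-section marks the base
    te <- drop(sweep(mesh$endo$vertices, 2L, ctr) %*% ax)
    rad <- sqrt(rowSums((sweep(mesh$endo$vertices, 2L, ctr) -
                           outer(te, ax))^2))
    rng <- range(te)
    band <- 0.2 * diff(rng)
    hi <- te >= rng[2L] - band
    lo <- te <= rng[1L] + band
    r_hi <- if (any(hi)) mean(rad[hi]) else 0
    r_lo <- if (any(lo)) mean(rad[lo]) else 0
    if (r_lo > r_hi) ax <- -ax
  }
  t_epi <- drop(vc %*% ax)
  tmin <- min(t_epi); tmax <- max(t_epi)
  structure(list(apex_point = ctr + tmin * ax,
                 base_point = ctr + tmax * ax,
                 long_axis = ax,
                 length = tmax - tmin),
            class = "axis_frame")
}

#' @export
print.axis_frame <- function(x, ...) {
  cat(sprintf("LV axis frame: length %.1f mm, long axis (%.3f, %.3f, %.3f)\n",
              x$length, x$long_axis[1L], x$long_axis[2L], x$long_axis[3L]))
  invisible(x)
}
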