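## Short-axis slicing of LV surface meshes and binary rasterization.

plane_basis <- function(normal) {
  n <- normal / sqrt(sum(normal^2))
  ref <- if (abs(n[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2L] * e1[3L] - n[3L] * e1[2L],
          n[3L] * e1[1L] - n[1L] * e1[3L],
          n[1L] * e1[2L] - n[2L] * e1[1L])
  list(e1 = e1, e2 = e2, n = n)
}

#' Intersect a triangulated surface with a plane
#'
#' Extracts the intersection of a closed surface with a plane as closed 2D
#' polylines in the plane's in-plane frame.  Intersection points are
#' computed once per crossing mesh edge, and contours are chained by exact
#' edge identity, so chaining is robust to floating-point noise.  Vertices
#' lying numerically on the plane are perturbed by 1e-9 mm.
#'
#' @param mesh a [surface_mesh()].
#' @param origin point on the plane (3-vector, mm).
#' @param normal plane normal (3-vector).
#' @return list of closed polylines; each an `n x 2` matrix (first row
#'   repeated as last).  Attribute `closed_ok` is FALSE when any chain
#'   failed to close (non-manifold input).
#' @export
mesh_plane_contours <- function(mesh, origin, normal) {
  bas <- plane_basis(normal)
  v <- mesh$vertices
  f <- mesh$faces
  d <- drop(v %*% bas$n) - sum(origin * bas$n)
  d[abs(d) < 1e-9] <- 1e-9
  dmat <- matrix(d[f], nrow(f), 3L)
  crossing <- (pmin(dmat[, 1L], dmat[, 2L], dmat[, 3L]) < 0) &
    (pmax(dmat[, 1L], dmat[, 2L], dmat[, 3L]) > 0)
  if (!any(crossing)) return(structure(list(), closed_ok = TRUE))
  fc <- f[crossing, , drop = FALSE]

  edge_id <- function(a, b) paste(pmin(a, b), pmax(a, b))
  pairs <- rbind(cbind(fc[, 1L], fc[, 2L]),
                 cbind(fc[, 2L], fc[, 3L]),
                 cbind(fc[, 3L], fc[, 1L]))
  keys <- edge_id(pairs[, 1L], pairs[, 2L])
  cross_e <- d[pairs[, 1L]] * d[pairs[, 2L]] < 0
  ukeys <- unique(keys[cross_e])
  eidx <- match(keys, ukeys)                 # NA for non-crossing edges

  # one intersection point per unique crossing edge (canonical vertex order)
  usplit <- matrix(as.integer(do.call(rbind, strsplit(ukeys, " "))), ncol = 2L)
  i1 <- usplit[, 1L]; i2 <- usplit[, 2L]
  tt <- d[i1] / (d[i1] - d[i2])
  pts3 <- v[i1, , drop = FALSE] + tt * (v[i2, , drop = FALSE] - v[i1, , drop = FALSE])
  rel <- sweep(pts3, 2L, origin)
  pts2 <- cbind(drop(rel %*% bas$e1), drop(rel %*% bas$e2))

  # per crossing face: the two crossing edges form one segment (a triangle
  # with vertices on both sides crosses on exactly two of its edges)
  nfc <- nrow(fc)
  em <- matrix(eidx, nfc, 3L)
  first <- ifelse(is.na(em[, 1L]), em[, 2L], em[, 1L])
  second <- ifelse(is.na(em[, 3L]), em[, 2L], em[, 3L])
  seg <- cbind(first, second)
  seg <- seg[!is.na(first) & !is.na(second), , drop = FALSE]

  # adjacency: each edge-node should appear in exactly two segments
  nnode <- length(ukeys)
  nb1 <- integer(nnode); nb2 <- integer(nnode)
  for (s in seq_len(nrow(seg))) {
    a <- seg[s, 1L]; b <- seg[s, 2L]
    if (nb1[a] == 0L) nb1[a] <- b else nb2[a] <- b
    if (nb1[b] == 0L) nb1[b] <- a else nb2[b] <- a
  }
  visited <- logical(nnode)
  contours <- list()
  closed_ok <- TRUE
  for (s0 in seq_len(nnode)) {
    if (visited[s0] || nb1[s0] == 0L) next
    path <- integer(0)
    cur <- s0; prev <- 0L
    repeat {
      visited[cur] <- TRUE
      path <- c(path, cur)
      nxt <- if (nb1[cur] != prev && nb1[cur] != 0L) nb1[cur] else nb2[cur]
      if (nxt == 0L) { closed_ok <- FALSE; break }
      if (nxt == s0) break
      if (visited[nxt]) { closed_ok <- FALSE; break }
      prev <- cur; cur <- nxt
    }
    if (length(path) >= 3L)
      contours[[length(contours) + 1L]] <-
        rbind(pts2[path, , drop = FALSE], pts2[path[1L], , drop = FALSE])
  }
  structure(contours, closed_ok = closed_ok)
}

polyline_self_intersects <- function(poly) {
  # segment-pair crossing test, O(n^2); `poly` closed (first row == last)
  p <- poly[-nrow(poly), , drop = FALSE]
  n <- nrow(p)
  if (n < 4L) return(FALSE)
  a <- p
  b <- p[c(2:n, 1L), , drop = FALSE]
  cross2 <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    j <- (i + 2L):n
    j <- j[!(i == 1L & j == n)]          # skip segments adjacent to i
    if (length(j) == 0L) next
    d1 <- cross2(a[i, 1L], a[i, 2L], b[i, 1L], b[i, 2L], a[j, 1L], a[j, 2L])
    d2 <- cross2(a[i, 1L], a[i, 2L], b[i, 1L], b[i, 2L], b[j, 1L], b[j, 2L])
    d3 <- cross2(a[j, 1L], a[j, 2L], b[j, 1L], b[j, 2L], a[i, 1L], a[i, 2L])
    d4 <- cross2(a[j, 1L], a[j, 2L], b[j, 1L], b[j, 2L], b[i, 1L], b[i, 2L])
    hit <- (d1 * d2 < 0) & (d3 * d4 < 0)
    if (any(hit)) return(TRUE)
  }
  FALSE
}

#' Short-axis slicing of an LV mesh
#'
#' Generates `n_slices` planes normal to the long axis, evenly spaced from
#' `apex_offset` of the apex-to-base length up to the base (both endpoints
#' included), and intersects the epicardial and endocardial surfaces with
#' each.  A plane is flagged `hits_valve` when it passes within `valve_tol`
#' mm (along the axis) of any valve marker, or when the epicardial
#' intersection is not a single simple closed curve.
#'
#' @param mesh an [lv_mesh()].
#' @param frame an `axis_frame` from [compute_axes()]; computed if `NULL`.
#' @param n_slices number of slice planes (default 25).
#' @param apex_offset starting fraction of the apex-to-base length (0.20).
#' @param valve_tol valve clearance along the axis, mm.
#' @param jitter data-augmentation flag: when positive, each plane position
#'   is perturbed uniformly by up to `jitter` times half the plane spacing
#'   (at most 1), seeded by `jitter_seed`; the default 0 is the fixed,
#'   reproducible protocol.
#' @param jitter_seed seed for the position jitter.
#' @return list of `slice_contours` objects with fields `plane_origin`,
#'   `plane_normal`, `epi_contours`, `endo_contours`, `hits_valve`,
#'   `self_intersecting`, `slice_index` (0-based), `normalized_position`.
#' @export
slice_mesh <- function(mesh, frame = NULL, n_slices = 25L, apex_offset = 0.20,
                       valve_tol = 2.0, jitter = 0, jitter_seed = 1L) {
  if (n_slices < 2L) stop("n_slices must be at least 2")
  if (apex_offset < 0 || apex_offset >= 1) stop("apex_offset must be in [0, 1)")
  if (jitter < 0 || jitter > 1) stop("jitter must be in [0, 1]")
  if (is.null(frame)) frame <- compute_axes(mesh)
  ax <- frame$long_axis
  s <- seq(apex_offset * frame$length, frame$length, length.out = n_slices)
  if (jitter > 0) {
    half <- diff(s[1:2]) / 2
    set.seed(jitter_seed)
    s <- pmin(pmax(s + runif(n_slices, -jitter * half, jitter * half),
                   apex_offset * frame$length), frame$length)
  }
  valve_s <- if (is.null(mesh$valve_points)) numeric(0) else
    drop(sweep(mesh$valve_points, 2L, frame$apex_point) %*% ax)
  out <- vector("list", n_slices)
  for (i in seq_len(n_slices)) {
    origin <- frame$apex_point + s[i] * ax
    epi_c <- mesh_plane_contours(mesh$epi, origin, ax)
    endo_c <- mesh_plane_contours(mesh$endo, origin, ax)
    hits_valve <- (length(valve_s) > 0L && any(abs(valve_s - s[i]) < valve_tol)) ||
      (length(epi_c) != 1L && length(epi_c) > 0L) ||
      !attr(epi_c, "closed_ok") || !attr(endo_c, "closed_ok")
    selfx <- any(vapply(c(epi_c, endo_c), polyline_self_intersects, logical(1L)))
    out[[i]] <- structure(list(plane_origin = origin,
                               plane_normal = ax,
                               epi_contours = epi_c,
                               endo_contours = endo_c,
                               hits_valve = hits_valve,
                               self_intersecting = selfx,
                               slice_index = i - 1L,
                               normalized_position = s[i] / frame$length),
                          class = "slice_contours")
  }
  out
}

polygon_area_centroid <- function(poly) {
  x <- poly[-nrow(poly), 1L]; y <- poly[-nrow(poly), 2L]
  n <- length(x)
  x2 <- x[c(2:n, 1L)]; y2 <- y[c(2:n, 1L)]
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(list(area = 0, centroid = c(mean(x), mean(y))))
  cx <- sum((x + x2) * cr) / (6 * a)
  cy <- sum((y + y2) * cr) / (6 * a)
  list(area = abs(a), centroid = c(cx, cy))
}

# Even-odd scanline fill on pixel centers.  `boundary` = "inclusive" counts a
# center lying exactly on a crossing as inside; "interior" excludes it.
fill_even_odd <- function(contours, origin, size, res, boundary = "inclusive") {
  grid <- matrix(FALSE, size, size)
  if (length(contours) == 0L) return(grid)
  segs <- do.call(rbind, lapply(contours, function(p) {
    n <- nrow(p)
    cbind(p[-n, 1L], p[-n, 2L], p[-1L, 1L], p[-1L, 2L])
  }))
  xs <- origin[1L] + (seq_len(size) - 1L) * res
  eps <- 1e-9
  lo <- pmin(segs[, 2L], segs[, 4L])
  hi <- pmax(segs[, 2L], segs[, 4L])
  r_min <- max(1L, floor((min(lo) - origin[2L]) / res) + 1L)
  r_max <- min(size, ceiling((max(hi) - origin[2L]) / res) + 1L)
  if (r_max < r_min) return(grid)
  for (r in r_min:r_max) {
    y <- origin[2L] + (r - 1L) * res
    act <- which(lo <= y & hi > y)
    if (length(act) == 0L) next
    sa <- segs[act, , drop = FALSE]
    cr <- sa[, 1L] + (y - sa[, 2L]) * (sa[, 3L] - sa[, 1L]) / (sa[, 4L] - sa[, 2L])
    cr <- sort(cr)
    parity <- findInterval(xs - eps, cr) %% 2L == 1L
    if (boundary == "inclusive") {
      on <- findInterval(xs + eps, cr) - findInterval(xs - eps, cr) > 0L
      grid[r, ] <- parity | on
    } else {
      on <- findInterval(xs + eps, cr) - findInterval(xs - eps, cr) > 0L
      grid[r, ] <- parity & !on
    }
  }
  grid
}

#' Rasterize slice contours into a binary anatomical mask
#'
#' A pixel center is foreground iff it lies inside the epicardial
#' contour(s) and outside every endocardial contour, by the even-odd rule.
#' Pixel centers exactly on the epicardial or endocardial contour count as
#' myocardium.  The mask is centered so that the area centroid of the
#' largest epicardial contour maps to pixel (size/2, size/2) (1-based).
#'
#' @param contours a `slice_contours` object.
#' @param size raster side length in pixels (default 256).
#' @param resolution pixel edge in mm (default 1).
#' @param patient_id carried through to the mask metadata.
#' @return An `anatomical_mask`: integer `size x size` grid (0/1) with
#'   fields `resolution`, `origin`, `patient_id`, `slice_index`,
#'   `normalized_position`.
#' @export
rasterize_slice <- function(contours, size = 256L, resolution = 1,
                            patient_id = NA_character_) {
  empty <- length(contours$epi_contours) == 0L
  if (empty) {
    grid <- matrix(0L, size, size)
    return(structure(list(grid = grid, resolution = resolution,
                          origin = c(NA_real_, NA_real_),
                          patient_id = patient_id,
                          slice_index = contours$slice_index,
                          normalized_position = contours$normalized_position),
                     class = "anatomical_mask"))
  }
  areas <- vapply(contours$epi_contours,
                  function(p) polygon_area_centroid(p)$area, numeric(1L))
  ctr <- polygon_area_centroid(contours$epi_contours[[which.max(areas)]])$centroid
  half <- (size / 2 - 1) * resolution
  origin <- ctr - half   # pixel (1,1) center; centroid lands on (size/2, size/2)
  allp <- do.call(rbind, c(contours$epi_contours, contours$endo_contours))
  over_x <- max(abs(allp[, 1L] - ctr[1L])) - size * resolution / 2
  over_y <- max(abs(allp[, 2L] - ctr[2L])) - size * resolution / 2
  if (over_x > 0 || over_y > 0)
    stop(sprintf("contour exceeds the %.0f mm field of view by %.1f mm",
                 size * resolution, max(over_x, over_y)))
  epi_in <- fill_even_odd(contours$epi_contours, origin, size, resolution,
                          boundary = "inclusive")
  endo_in <- fill_even_odd(contours$endo_contours, origin, size, resolution,
                           boundary = "interior")
  grid <- matrix(0L, size, size)
  grid[epi_in & !endo_in] <- 1L
  structure(list(grid = grid, resolution = resolution, origin = origin,
                 patient_id = patient_id,
                 slice_index = contours$slice_index,
                 normalized_position = contours$normalized_position),
            class = "anatomical_mask")
}

#' Apply the slice exclusion rules
#'
#' A slice sample is excluded when its contours self-intersect, when the
#' plane hits a valve, or when the mask has fewer than `min_pixels`
#' foreground pixels (strict less-than).  The three checks are
#' order-independent; the reported reason follows the fixed priority
#' self_intersecting > valve > too_small.
#'
#' @param sample a `slice_sample` (see [slice_patient()]).
#' @param min_pixels minimum retained foreground pixel count (default 50).
#' @return the sample with `valid` and `reason` set.
#' @export
filter_slice <- function(sample, min_pixels = 50L) {
  npix <- sum(sample$mask$grid)
  reason <- "none"
  if (isTRUE(sample$self_intersecting)) reason <- "self_intersecting"
  else if (isTRUE(sample$hits_valve)) reason <- "valve"
  else if (npix < min_pixels) reason <- "too_small"
  sample$valid <- reason == "none"
  sample$reason <- reason
  sample$n_pixels <- npix
  sample
}

#' Binary scar ground truth for one slice plane
#'
#' The label is 1 iff the slice plane geometrically intersects the closed
#' scar surface; 0 when no scar mesh is present.  For a closed surface the
#' plane intersects iff the signed vertex distances span zero.
#'
#' @param contours a `slice_contours` object (provides plane).
#' @param scar_mesh closed scar [surface_mesh()] or `NULL`.
#' @return integer 0 or 1.
#' @export
label_slice <- function(contours, scar_mesh) {
  if (is.null(scar_mesh)) return(0L)
  be <- boundary_edges(scar_mesh)
  if (nrow(be) > 0L)
    stop(sprintf("scar mesh is open: %d boundary edges (first: %d-%d)",
                 nrow(be), be[1L, 1L], be[1L, 2L]))
  n <- contours$plane_normal
  d <- drop(scar_mesh$vertices %*% n) - sum(contours$plane_origin * n)
  as.integer(min(d) <= 1e-9 && max(d) >= -1e-9)
}
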