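# Fixture builders shared across test files.  Everything is generated in
# code; no binary fixtures.

# closed ellipsoid surface mesh, semi-axes (ax, ay, az), optional rotation
ellipsoid_mesh <- function(ax, ay, az, n_t = 24L, n_p = 48L, R = diag(3),
                           center = c(0, 0, 0)) {
  theta <- seq(pi / n_t, pi - pi / n_t, length.out = n_t)
  phi <- seq(0, 2 * pi, length.out = n_p + 1L)[-(n_p + 1L)]
  verts <- matrix(0, 2L + n_t * n_p, 3L)
  verts[1L, ] <- c(0, 0, -az)
  idx <- function(i, j) 1L + (i - 1L) * n_p + j
  for (i in seq_len(n_t))
    verts[idx(i, seq_len(n_p)), ] <-
      cbind(ax * sin(theta[i]) * cos(phi),
            ay * sin(theta[i]) * sin(phi),
            -az * cos(theta[i]))
  south <- nrow(verts)
  verts[south, ] <- c(0, 0, az)
  jn <- c(seq_len(n_p)[-1L], 1L)
  faces <- list()
  for (j in seq_len(n_p)) faces[[length(faces) + 1L]] <- c(1L, idx(1L, j), idx(1L, jn[j]))
  for (i in seq_len(n_t - 1L)) for (j in seq_len(n_p)) {
    faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, jn[j]))
    faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1L, jn[j]), idx(i, jn[j]))
  }
  for (j in seq_len(n_p)) faces[[length(faces) + 1L]] <- c(south, idx(n_t, jn[j]), idx(n_t, j))
  v <- sweep(verts %*% t(R), 2L, center, "+")
  surface_mesh(v, do.call(rbind, faces))
}

# two nested ellipsoids as an lv_mesh (no valve markers unless given)
ellipsoid_shell <- function(ax, ay, az, wall = 5, R = diag(3),
                            valve_points = NULL, id = "fixture") {
  lv_mesh(id,
          epi = ellipsoid_mesh(ax, ay, az, R = R),
          endo = ellipsoid_mesh(ax - wall, ay - wall, az - wall, R = R),
          valve_points = valve_points, validate = FALSE)
}

# closed right circular cylinder (axis = z), radius r, z in [0, h]
cylinder_mesh <- function(r, h, n_p = 64L, n_z = 20L) {
  zs <- seq(0, h, length.out = n_z)
  phi <- seq(0, 2 * pi, length.out = n_p + 1L)[-(n_p + 1L)]
  verts <- matrix(0, n_z * n_p + 2L, 3L)
  idx <- function(i, j) (i - 1L) * n_p + j
  for (i in seq_len(n_z))
    verts[idx(i, seq_len(n_p)), ] <- cbind(r * cos(phi), r * sin(phi), zs[i])
  bot <- n_z * n_p + 1L; top <- n_z * n_p + 2L
  verts[bot, ] <- c(0, 0, 0); verts[top, ] <- c(0, 0, h)
  jn <- c(seq_len(n_p)[-1L], 1L)
  faces <- list()
  for (j in seq_len(n_p)) faces[[length(faces) + 1L]] <- c(bot, idx(1L, jn[j]), idx(1L, j))
  for (i in seq_len(n_z - 1L)) for (j in seq_len(n_p)) {
    faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, jn[j]))
    faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1L, jn[j]), idx(i, jn[j]))
  }
  for (j in seq_len(n_p)) faces[[length(faces) + 1L]] <- c(top, idx(n_z, j), idx(n_z, jn[j]))
  surface_mesh(verts, do.call(rbind, faces))
}

# slice_contours object from explicit polygon lists (closed or not)
make_contours <- function(epi, endo = list(), origin = c(0, 0, 0),
                          normal = c(0, 0, 1), slice_index = 0L,
                          normalized_position = 0.5) {
  close_poly <- function(p) if (all(p[1L, ] == p[nrow(p), ])) p else rbind(p, p[1L, ])
  structure(list(plane_origin = origin, plane_normal = normal,
                 epi_contours = lapply(epi, close_poly),
                 endo_contours = lapply(endo, close_poly),
                 hits_valve = FALSE, self_intersecting = FALSE,
                 slice_index = slice_index,
                 normalized_position = normalized_position),
            class = "slice_contours")
}

circle_poly <- function(r, center = c(0, 0), n = 360L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)
  cbind(center[1L] + r * cos(th), center[2L] + r * sin(th))
}

# anatomical mask of an annulus built analytically (pixel-center membership)
annulus_mask <- function(r_epi, r_endo, center_px = c(128, 128), size = 256L) {
  xs <- matrix(seq_len(size), size, size, byrow = TRUE)
  ys <- matrix(seq_len(size), size, size)
  d2 <- (xs - center_px[1L])^2 + (ys - center_px[2L])^2
  grid <- matrix(0L, size, size)
  if (r_endo < 0) grid[d2 <= r_epi^2] <- 1L    # filled disc
  else grid[d2 <= r_epi^2 & d2 > r_endo^2] <- 1L
  structure(list(grid = grid, resolution = 1, origin = c(0, 0),
                 patient_id = "fixture", slice_index = 0L,
                 normalized_position = 0.5),
            class = "anatomical_mask")
}

# polar mask with a uniform (or sector-thinned) wall band
band_polar_mask <- function(r_in = 20L, thick = 10L, size = 256L,
                            sector = NULL, sector_thick = 4L) {
  g <- matrix(0L, size, size)
  for (j in seq_len(size)) {
    w <- if (!is.null(sector) && j >= sector[1L] && j <= sector[2L])
      sector_thick else thick
    g[(r_in + 1L):(r_in + w), j] <- 1L
  }
  structure(list(grid = g, radial_resolution = 1, angular_resolution = 360 / size,
                 center_used = c(0, 0), patient_id = "fixture",
                 slice_index = 0L, normalized_position = 0.5),
            class = "polar_mask")
}

# raw-packed dataset of band polar masks: scarred slices get a thin sector
toy_band_dataset <- function(n, seed = 1L, size = 256L) {
  set.seed(seed)
  y <- sample(0:1, n, replace = TRUE)
  masks <- vapply(y, function(lab) {
    r0 <- sample(16:26, 1L)
    sector <- if (lab == 1L) { s0 <- sample(1:(size - 45L), 1L); c(s0, s0 + 40L) }
    pm <- band_polar_mask(r0, 10L, size, sector, 5L)
    as.raw(as.integer(pm$grid))
  }, raw(size^2))
  list(masks = masks, labels = y)
}

# strongly separated classes: thick (25 mm) vs thin (6 mm) uniform walls
separable_band_dataset <- function(n, seed = 1L, size = 256L) {
  set.seed(seed)
  y <- sample(0:1, n, replace = TRUE)
  masks <- vapply(y, function(l) {
    pm <- band_polar_mask(sample(16:24, 1L), if (l == 1L) 25L else 6L, size)
    as.raw(as.integer(pm$grid))
  }, raw(size^2))
  list(masks = masks, labels = y)
}

tiny_dense_spec <- function(h) {
  structure(list(architecture = "toy", input_size = h, channels = 1L,
                 layers = list(list(type = "dense", n_in = as.integer(h^2),
                                    n_out = 1L, relu = FALSE))),
            class = "network_spec")
}
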