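test_that("PCA long axis recovers the major axis of a prolate shell", {
  shell <- ellipsoid_shell(25, 25, 45, wall = 5)  # major axis along z
  fr <- compute_axes(shell)
  expect_equal(abs(sum(fr$long_axis * c(0, 0, 1))), 1, tolerance = 1e-9)
  expect_equal(fr$length, 90, tolerance = 1e-6)

  # rotated by a known rotation: axis follows (oracle = R applied to z-hat)
  R <- lvscar:::rotation_from_axis_angle(c(1, 2, 0.5), 0.7)
  shell_r <- ellipsoid_shell(25, 25, 45, wall = 5, R = R)
  fr_r <- compute_axes(shell_r)
  expect_equal(abs(sum(fr_r$long_axis * drop(R %*% c(0, 0, 1)))), 1,
               tolerance = 1e-6)
  expect_equal(fr_r$length, 90, tolerance = 1e-6)
})

test_that("valve markers orient the axis apex-to-base", {
  vp <- matrix(c(5, 0, 44, -5, 0, 44), 2L, 3L, byrow = TRUE)  # near +z end
  shell <- ellipsoid_shell(25, 25, 45, wall = 5, valve_points = vp)
  fr <- compute_axes(shell)
  expect_gt(sum(fr$long_axis * c(0, 0, 1)), 0.99)       # base at +z
  expect_lt(fr$apex_point[3L], fr$base_point[3L])
})

test_that("degenerate vertex clouds raise rank errors; spheres warn", {
  pts <- cbind(runif(20), runif(20), 0)                  # coplanar
  fake <- list(patient_id = "x",
               epi = list(vertices = pts, faces = cbind(1:18, 2:19, 3:20)),
               endo = list(vertices = pts, faces = cbind(1:18, 2:19, 3:20)),
               valve_points = NULL)
  class(fake) <- "lv_mesh"
  expect_error(compute_axes(fake), "rank 2")
  line <- cbind(seq_len(20), 0, 0)
  fake$epi$vertices <- line
  expect_error(compute_axes(fake), "rank 1")
  # exactly symmetric cloud (cube vertices): principal axis is ambiguous
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) * 20
  sym <- list(patient_id = "cube",
              epi = list(vertices = cube, faces = cbind(1:6, 2:7, 3:8)),
              endo = list(vertices = cube * 0.5, faces = cbind(1:6, 2:7, 3:8)),
              valve_points = matrix(c(0, 0, 25), 1L))
  class(sym) <- "lv_mesh"
  expect_warning(compute_axes(sym), "ambiguous")
})

test_that("slicing produces exactly n_slices planes with the stated spacing", {
  mesh <- generate_lv_mesh(cohort_spec(seed = 2), scarred = FALSE, seed = 9)
  fr <- compute_axes(mesh)
  slices <- slice_mesh(mesh, fr)
  expect_length(slices, 25L)
  # first plane at apex + 0.20 * length, last at the base (inclusive)
  d1 <- sum((slices[[1L]]$plane_origin - fr$apex_point) * fr$long_axis)
  expect_equal(d1, 0.20 * fr$length, tolerance = 1e-9)
  d25 <- sum((slices[[25L]]$plane_origin - fr$apex_point) * fr$long_axis)
  expect_equal(d25, fr$length, tolerance = 1e-9)
  # spacing formula example: a 100 mm shell starts 20 mm above the apex
  shell <- ellipsoid_shell(28, 28, 50, wall = 6)
  fs <- compute_axes(shell)
  s2 <- slice_mesh(shell, fs)
  expect_equal(sum((s2[[1L]]$plane_origin - fs$apex_point) * fs$long_axis),
               20, tolerance = 1e-6)
})

test_that("cylinder slices are concentric circle pairs with analytic radii", {
  cyl_epi <- cylinder_mesh(30, 100)
  cyl_endo <- cylinder_mesh(20, 100)
  m <- lv_mesh("cyl", cyl_epi, cyl_endo, validate = FALSE)
  fr <- list(apex_point = c(0, 0, 0), base_point = c(0, 0, 100),
             long_axis = c(0, 0, 1), length = 100)
  class(fr) <- "axis_frame"
  slices <- slice_mesh(m, fr, n_slices = 25L, apex_offset = 0)
  mid <- slices[[13L]]
  expect_length(mid$epi_contours, 1L)
  expect_length(mid$endo_contours, 1L)
  r_epi <- sqrt(rowSums(mid$epi_contours[[1L]]^2))
  r_endo <- sqrt(rowSums(mid$endo_contours[[1L]]^2))
  # contour points lie on mesh chords: radius within r * (1 - cos(pi/n_p))
  chord_tol <- 30 * (1 - cos(pi / 64)) + 1e-9
  expect_lt(max(abs(r_epi - 30)), chord_tol)
  expect_lt(max(abs(r_endo - 20)), chord_tol)
  expect_true(all(r_epi <= 30 + 1e-9))
})

test_that("plane missing the mesh yields empty contours and an excluded slice", {
  cyl <- cylinder_mesh(20, 50)
  cont <- mesh_plane_contours(cyl, c(0, 0, 80), c(0, 0, 1))
  expect_length(cont, 0L)
  sc <- make_contours(epi = list())
  mask <- rasterize_slice(sc)
  smp <- filter_slice(list(mask = mask, hits_valve = FALSE,
                           self_intersecting = FALSE))
  expect_false(smp$valid)
  expect_identical(smp$reason, "too_small")
})

test_that("rasterization reproduces analytic annulus geometry", {
  sc <- make_contours(epi = list(circle_poly(30)),
                      endo = list(circle_poly(20)))
  mask <- rasterize_slice(sc)
  expect_identical(dim(mask$grid), c(256L, 256L))
  # wall thickness 10 +/- 1 px along horizontal/vertical/diagonal rays
  ctr <- c(128, 128)
  for (ang in c(0, 45, 90, 135, 180, 270) * pi / 180) {
    rr <- 0:60
    px <- round(ctr[1L] + rr * cos(ang)); py <- round(ctr[2L] + rr * sin(ang))
    th <- sum(mask$grid[cbind(py, px)])
    expect_true(abs(th - 10) <= 1)
  }
  # area within the boundary-discretization bound of 2 * perimeter pixels
  area <- sum(mask$grid)
  expect_lt(abs(area - pi * (30^2 - 20^2)), 2 * 2 * pi * 30)
  # per-pixel agreement with the analytic membership oracle
  oracle <- annulus_mask(30, 20)$grid
  expect_lt(mean(mask$grid != oracle), 0.01)
})

test_that("epicardial contour alone rasterizes to a filled disc", {
  sc <- make_contours(epi = list(circle_poly(15)))
  mask <- rasterize_slice(sc)
  expect_equal(sum(mask$grid), pi * 15^2, tolerance = 0.1)
  expect_equal(mask$grid[128, 128], 1L)
})

test_that("square rasterization matches a brute-force point-in-polygon count", {
  sq <- cbind(c(-5, 5, 5, -5, -5), c(-5, -5, 5, 5, -5))
  sc <- make_contours(epi = list(sq))
  mask <- rasterize_slice(sc)
  # brute force: pixel centers strictly inside (boundary pixels tolerated)
  expect_true(abs(sum(mask$grid) - 100) <= 44)
  expect_gte(sum(mask$grid), 100)   # boundary-inclusive convention
})

test_that("contour overflow beyond the field of view raises a sized error", {
  sc <- make_contours(epi = list(circle_poly(140)))
  expect_error(rasterize_slice(sc), "field of view")
})

test_that("exclusion rules: pixel threshold is strict, reasons prioritized, idempotent", {
  mk <- function(npix) {
    g <- matrix(0L, 256, 256); g[seq_len(npix)] <- 1L
    list(mask = list(grid = g), hits_valve = FALSE, self_intersecting = FALSE)
  }
  expect_false(filter_slice(mk(49))$valid)
  expect_identical(filter_slice(mk(49))$reason, "too_small")
  expect_true(filter_slice(mk(50))$valid)
  # a slice failing two rules is excluded regardless of check order
  s <- mk(10); s$hits_valve <- TRUE
  expect_false(filter_slice(s)$valid)
  s2 <- mk(5000); s2$hits_valve <- TRUE
  expect_false(filter_slice(s2)$valid)
  expect_identical(filter_slice(s2)$reason, "valve")
  # idempotence
  once <- filter_slice(mk(49)); twice <- filter_slice(once)
  expect_identical(once$valid, twice$valid)
  expect_identical(once$reason, twice$reason)
})

test_that("figure-eight contours are detected as self-intersecting", {
  bowtie <- cbind(c(0, 10, 10, 0, 0), c(0, 10, 0, 10, 0))
  expect_true(lvscar:::polyline_self_intersects(bowtie))
  t <- seq(0.2, 2 * pi + 0.2, length.out = 101L)  # crossing mid-segment
  eight <- cbind(10 * sin(t), 6 * sin(2 * t))
  expect_true(lvscar:::polyline_self_intersects(eight))
  expect_false(lvscar:::polyline_self_intersects(circle_poly(10)))
})

test_that("scar labels follow plane/scar-mesh intersection exactly", {
  mesh <- generate_lv_mesh(cohort_spec(seed = 4), scarred = TRUE, seed = 21)
  fr <- compute_axes(mesh)
  slices <- slice_mesh(mesh, fr)
  labels <- vapply(slices, label_slice, integer(1L), scar_mesh = mesh$scar)
  # brute-force oracle: signed plane distances of dense scar surface points
  v <- mesh$scar$vertices
  f <- mesh$scar$faces
  set.seed(1)
  w <- matrix(runif(3L * 4000L), ncol = 3L); w <- w / rowSums(w)
  fi <- sample.int(nrow(f), 4000L, replace = TRUE)
  pts <- w[, 1L] * v[f[fi, 1L], ] + w[, 2L] * v[f[fi, 2L], ] +
    w[, 3L] * v[f[fi, 3L], ]
  pts <- rbind(pts, v)
  oracle <- vapply(slices, function(sc) {
    d <- drop(pts %*% sc$plane_normal) - sum(sc$plane_origin * sc$plane_normal)
    as.integer(min(d) <= 0 && max(d) >= 0)
  }, integer(1L))
  expect_identical(labels, oracle)
  expect_gt(sum(labels), 0L)
  # contiguous block of positive planes
  pos <- which(labels == 1L)
  expect_identical(pos, seq(min(pos), max(pos)))
  # no scar -> all zero
  expect_identical(vapply(slices, label_slice, integer(1L), scar_mesh = NULL),
                   rep(0L, 25L))
})

test_that("a scar sphere spanning known planes labels exactly those planes", {
  cyl_epi <- cylinder_mesh(30, 100); cyl_endo <- cylinder_mesh(20, 100)
  m <- lv_mesh("cyl", cyl_epi, cyl_endo, validate = FALSE)
  fr <- structure(list(apex_point = c(0, 0, 0), base_point = c(0, 0, 100),
                       long_axis = c(0, 0, 1), length = 100),
                  class = "axis_frame")
  slices <- slice_mesh(m, fr, apex_offset = 0)  # planes at z = 0, 25/6, ...
  zs <- vapply(slices, function(s) s$plane_origin[3L], numeric(1L))
  # sphere covering planes 10..14 (z in [zs[11], zs[15]])
  zc <- (zs[11L] + zs[15L]) / 2; rad <- (zs[15L] - zs[11L]) / 2 + 1e-6
  scar <- ellipsoid_mesh(25, 25, rad, center = c(25, 0, zc))
  labels <- vapply(slices, label_slice, integer(1L), scar_mesh = scar)
  expect_identical(which(labels == 1L) - 1L, 10:14)
  # open mesh rejected with boundary-edge count
  open_scar <- scar
  open_scar$faces <- open_scar$faces[-1L, , drop = FALSE]
  expect_error(label_slice(slices[[11L]], open_scar), "boundary edges")
})

test_that("slicing a spheroid shell reproduces closed-form wall thickness", {
  # spheroid (a=45 axial, b=30 equatorial), uniform 8 mm wall along the
  # ellipsoid normal direction is approximated radially; mid slices give
  # in-plane thickness = r_epi(z) - r_endo(z), computable in closed form
  shell <- lv_mesh("sph",
                   epi = ellipsoid_mesh(30, 30, 45, n_t = 48, n_p = 96),
                   endo = ellipsoid_mesh(22, 22, 37, n_t = 48, n_p = 96),
                   validate = FALSE)
  fr <- compute_axes(shell)
  slices <- slice_mesh(shell, fr, apex_offset = 0.2)
  for (i in c(5L, 9L, 13L)) {
    sc <- slices[[i]]
    z <- sum((sc$plane_origin - c(0, 0, 0)) * c(0, 0, 1))
    r_epi_true <- 30 * sqrt(1 - (z / 45)^2)
    r_endo_true <- 22 * sqrt(pmax(1 - (z / 37)^2, 0))
    mask <- rasterize_slice(sc)
    th <- sum(mask$grid[128, ]) / 2          # two wall crossings per row
    expect_true(abs(th - (r_epi_true - r_endo_true)) <= 1)
  }
})

test_that("optional plane-position jitter is seeded and bounded", {
  mesh <- generate_lv_mesh(cohort_spec(seed = 2), scarred = FALSE, seed = 9)
  fr <- compute_axes(mesh)
  fixed <- slice_mesh(mesh, fr)
  j1 <- slice_mesh(mesh, fr, jitter = 0.8, jitter_seed = 4)
  j2 <- slice_mesh(mesh, fr, jitter = 0.8, jitter_seed = 4)
  expect_length(j1, 25L)
  pos <- function(sl) vapply(sl, function(s)
    sum((s$plane_origin - fr$apex_point) * fr$long_axis), numeric(1L))
  expect_identical(pos(j1), pos(j2))                  # seeded determinism
  expect_false(identical(pos(j1), pos(fixed)))
  half <- diff(pos(fixed)[1:2]) / 2
  expect_true(all(abs(pos(j1) - pos(fixed)) <= 0.8 * half + 1e-9))
  expect_error(slice_mesh(mesh, fr, jitter = 2), "jitter")
})
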