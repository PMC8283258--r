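## Seeded synthetic LV cohort generator.
##
## Base geometry: a truncated prolate spheroid (long axis along z, apex at
## -z), both surfaces parameterized on a polar-angle / azimuth grid, with
## low-order smooth random perturbation.  Scar is modeled as a contiguous
## patch of wall thinning with a raised-cosine boundary taper, plus a
## closed mid-wall scar sub-mesh filling the patch.

#' Scar morphology specification
#'
#' @param angular_extent circumferential extent of the scar patch, degrees.
#' @param axial_extent apex-to-base extent as a fraction of the LV length.
#' @param center_axial patch center as a fraction of the apex-to-base length.
#' @param center_angle patch center azimuth in degrees; `NA` draws one
#'   uniformly per patient.
#' @param thinning_factor scarred wall thickness / remote thickness, in
#'   (0, 1]; values near 1 give minimally remodeled (hard) scars.
#' @param taper fraction of each half-extent over which the thinning ramps
#'   smoothly to zero at the patch boundary.
#' @param shape_noise relative wobble of the patch boundary.
#' @return list of class `scar_spec`.
#' @export
scar_spec <- function(angular_extent = 80, axial_extent = 0.35,
                      center_axial = 0.45, center_angle = NA,
                      thinning_factor = 0.5, taper = 0.3, shape_noise = 0.05) {
  if (thinning_factor <= 0 || thinning_factor > 1)
    stop("thinning_factor must be in (0, 1]")
  if (angular_extent <= 0 || axial_extent <= 0) stop("extents must be positive")
  structure(list(angular_extent = angular_extent, axial_extent = axial_extent,
                 center_axial = center_axial, center_angle = center_angle,
                 thinning_factor = thinning_factor, taper = taper,
                 shape_noise = shape_noise),
            class = "scar_spec")
}

#' Synthetic cohort specification
#'
#' Defaults emulate the output of a semi-automated LV segmentation tool:
#' apex-to-base lengths of 75-95 mm, wall thickness 8-12 mm, and a paired
#' "second modality" mesh whose blood volume differs by 19% on average
#' (mean absolute relative difference), plus a random rigid displacement to
#' be recovered by registration.
#'
#' @param n_patients cohort size.
#' @param scar_prevalence fraction of patients carrying scar.
#' @param size_range apex-to-base length range, mm.
#' @param wall_thickness_range remote wall thickness range, mm.
#' @param scar a [scar_spec()].
#' @param modality_perturbation target mean |blood-volume difference| /
#'   volume between paired meshes.
#' @param shape_noise relative amplitude of the smooth surface perturbation.
#' @param seed integer master seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 10L, scar_prevalence = 0.5,
                        size_range = c(75, 95),
                        wall_thickness_range = c(8, 12),
                        scar = scar_spec(),
                        modality_perturbation = 0.19,
                        shape_noise = 0.02,
                        seed = 1L) {
  if (scar_prevalence < 0 || scar_prevalence > 1)
    stop("scar_prevalence must be in [0, 1]")
  if (any(size_range <= 0) || diff(size_range) < 0 ||
      any(wall_thickness_range <= 0) || diff(wall_thickness_range) < 0)
    stop("ranges must be positive and ordered")
  structure(list(n_patients = as.integer(n_patients),
                 scar_prevalence = scar_prevalence,
                 size_range = size_range,
                 wall_thickness_range = wall_thickness_range,
                 scar = scar,
                 modality_perturbation = modality_perturbation,
                 shape_noise = shape_noise,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# -- internal geometry builders ------------------------------------------

# smooth low-order perturbation field on (theta_tilde in [0,1], phi)
rand_field_coef <- function(amplitude, n_terms = 4L) {
  list(a = rnorm(n_terms, 0, amplitude),
       l = sample(1:2, n_terms, replace = TRUE),
       m = sample(1:3, n_terms, replace = TRUE),
       psi = runif(n_terms, 0, 2 * pi))
}

eval_field <- function(coef, theta_tilde, phi) {
  out <- 0
  for (j in seq_along(coef$a))
    out <- out + coef$a[j] * sin(pi * coef$l[j] * theta_tilde) *
      cos(coef$m[j] * phi + coef$psi[j])
  out
}

# closed surface-of-revolution-style mesh: pole + n_t rings + base cap
shell_mesh <- function(rho, theta, phi, pole_z, validate = FALSE) {
  n_t <- length(theta); n_p <- length(phi)
  st <- sin(theta); ct <- cos(theta)
  verts <- matrix(0, 1L + n_t * n_p + 1L, 3L)
  verts[1L, ] <- c(0, 0, pole_z)
  idx <- function(i, j) 1L + (i - 1L) * n_p + j
  for (i in seq_len(n_t)) {
    r <- rho[i, ]
    verts[idx(i, seq_len(n_p)), ] <- cbind(r * st[i] * cos(phi),
                                           r * st[i] * sin(phi),
                                           -r * ct[i])
  }
  rim <- verts[idx(n_t, seq_len(n_p)), , drop = FALSE]
  cap_center <- nrow(verts)
  verts[cap_center, ] <- colMeans(rim)
  jn <- c(seq_len(n_p)[-1L], 1L)
  faces <- matrix(0L, n_p + 2L * (n_t - 1L) * n_p + n_p, 3L)
  k <- 1L
  for (j in seq_len(n_p)) {            # apex fan
    faces[k, ] <- c(1L, idx(1L, j), idx(1L, jn[j])); k <- k + 1L
  }
  for (i in seq_len(n_t - 1L)) {
    for (j in seq_len(n_p)) {
      faces[k, ] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, jn[j])); k <- k + 1L
      faces[k, ] <- c(idx(i, j), idx(i + 1L, jn[j]), idx(i, jn[j])); k <- k + 1L
    }
  }
  for (j in seq_len(n_p)) {            # base cap fan
    faces[k, ] <- c(cap_center, idx(n_t, jn[j]), idx(n_t, j)); k <- k + 1L
  }
  surface_mesh(verts, faces)
}

# closed "pillow" between two n x m vertex grids sharing a boundary
pillow_mesh <- function(grid_a, grid_b, n, m) {
  ia <- function(i, j) (j - 1L) * n + i
  ib <- function(i, j) n * m + (j - 1L) * n + i
  verts <- rbind(grid_a, grid_b)
  faces <- list()
  for (j in seq_len(m - 1L)) for (i in seq_len(n - 1L)) {
    faces[[length(faces) + 1L]] <- c(ia(i, j), ia(i + 1L, j), ia(i + 1L, j + 1L))
    faces[[length(faces) + 1L]] <- c(ia(i, j), ia(i + 1L, j + 1L), ia(i, j + 1L))
    faces[[length(faces) + 1L]] <- c(ib(i, j), ib(i + 1L, j + 1L), ib(i + 1L, j))
    faces[[length(faces) + 1L]] <- c(ib(i, j), ib(i, j + 1L), ib(i + 1L, j + 1L))
  }
  perim <- c(ia(1L, seq_len(m)),                    # top row left->right
             ia(seq(2L, n), m),                     # right col down
             ia(n, seq(m - 1L, 1L)),                # bottom row right->left
             ia(seq(n - 1L, 2L), 1L))               # left col up
  off <- n * m
  np <- length(perim)
  nxt <- c(seq_len(np)[-1L], 1L)
  for (k in seq_len(np)) {
    a1 <- perim[k]; a2 <- perim[nxt[k]]
    b1 <- perim[k] + off; b2 <- perim[nxt[k]] + off
    faces[[length(faces) + 1L]] <- c(a1, a2, b2)
    faces[[length(faces) + 1L]] <- c(a1, b2, b1)
  }
  surface_mesh(verts, do.call(rbind, faces))
}

draw_patient_params <- function(spec) {
  theta_max <- 105 * pi / 180
  L <- runif(1L, spec$size_range[1L], spec$size_range[2L])
  a <- L / (1 - cos(theta_max))
  b <- a * runif(1L, 0.50, 0.60)
  w0 <- runif(1L, spec$wall_thickness_range[1L], spec$wall_thickness_range[2L])
  ang <- if (is.na(spec$scar$center_angle)) runif(1L, 0, 360) else
    spec$scar$center_angle
  list(theta_max = theta_max, L = L, a = a, b = b, w0 = w0,
       scar_angle = ang * pi / 180)
}

# thinning membership in (zeta = axial fraction, phi); 1 = full thinning
scar_membership <- function(zeta, phi, params, sspec, wobble) {
  ramp <- function(u, taper) {
    # u: |offset| / half-extent; 1 inside the core, cosine falloff to 0 at 1
    out <- numeric(length(u))
    core <- 1 - taper
    out[u <= core] <- 1
    edge <- u > core & u < 1
    out[edge] <- 0.5 * (1 + cos(pi * (u[edge] - core) / taper))
    out
  }
  half_ax <- sspec$axial_extent / 2 * (1 + wobble$ax * sin(2 * phi + wobble$psi))
  half_an <- sspec$angular_extent * pi / 180 / 2
  dphi <- atan2(sin(phi - params$scar_angle), cos(phi - params$scar_angle))
  u_ax <- abs(zeta - sspec$center_axial) / half_ax
  u_an <- abs(dphi) / half_an
  ramp(u_ax, sspec$taper) * ramp(u_an, sspec$taper)
}

build_patient_mesh <- function(params, spec, scarred, pert_seed, patient_id) {
  set.seed(pert_seed)
  epi_coef <- rand_field_coef(spec$shape_noise)
  thk_coef <- rand_field_coef(0.03)
  wobble <- list(ax = spec$scar$shape_noise * runif(1L, 0.5, 1),
                 psi = runif(1L, 0, 2 * pi))
  n_t <- 36L; n_p <- 72L
  theta <- seq(params$theta_max / n_t, params$theta_max, length.out = n_t)
  phi <- seq(0, 2 * pi, length.out = n_p + 1L)[-(n_p + 1L)]
  tg <- matrix(theta, n_t, n_p)
  pg <- matrix(phi, n_t, n_p, byrow = TRUE)
  tt <- tg / params$theta_max
  r_ell <- 1 / sqrt((sin(tg) / params$b)^2 + (cos(tg) / params$a)^2)
  rho_epi <- r_ell * (1 + eval_field(epi_coef, tt, pg))
  zeta <- (-rho_epi * cos(tg) + params$a) / params$L   # axial fraction 0..~1
  w <- params$w0 * (1 + eval_field(thk_coef, tt, pg))
  memb <- if (scarred)
    scar_membership(zeta, pg, params, spec$scar, wobble) else 0
  thin <- 1 - (1 - spec$scar$thinning_factor) * memb
  w <- w * thin
  if (any(w <= 0)) stop("thinning produced non-positive wall thickness")
  rho_endo <- rho_epi - w
  if (any(rho_endo <= 1)) stop("wall thickness exceeds epicardial radius")
  epi <- shell_mesh(rho_epi, theta, phi, -params$a)
  endo <- shell_mesh(rho_endo, theta, phi, -(params$a - params$w0))

  scar <- NULL
  if (scarred) {
    ns <- 13L; ms <- 17L
    zr <- spec$scar$center_axial + spec$scar$axial_extent / 2 * seq(-1, 1, length.out = ns)
    pr <- params$scar_angle + spec$scar$angular_extent * pi / 180 / 2 *
      seq(-1, 1, length.out = ms)
    zg <- matrix(zr, ns, ms); pgs <- matrix(pr, ns, ms, byrow = TRUE)
    # invert z(theta) = -r_ellipsoid(theta) * cos(theta) on a fine grid so the
    # scar mesh's axial span matches the thinning membership exactly
    thf <- seq(1e-4, params$theta_max, length.out = 2048L)
    zf <- -cos(thf) / sqrt((sin(thf) / params$b)^2 + (cos(thf) / params$a)^2)
    zmm <- pmin(pmax(zg * params$L - params$a, min(zf) + 1e-6), max(zf) - 1e-6)
    th <- matrix(approx(zf, thf, xout = as.vector(zmm))$y, ns, ms)
    r_e <- 1 / sqrt((sin(th) / params$b)^2 + (cos(th) / params$a)^2) *
      (1 + eval_field(epi_coef, th / params$theta_max, pgs))
    wl <- params$w0 * (1 + eval_field(thk_coef, th / params$theta_max, pgs)) *
      (1 - (1 - spec$scar$thinning_factor) *
         scar_membership(zg, pgs, params, spec$scar, wobble))
    to_xyz <- function(r) cbind(c(r * sin(th) * cos(pgs)),
                                c(r * sin(th) * sin(pgs)),
                                c(-r * cos(th)))
    outer_sheet <- to_xyz(r_e - 0.3 * wl)
    inner_sheet <- to_xyz(r_e - 0.7 * wl)
    scar <- pillow_mesh(outer_sheet, inner_sheet, ns, ms)
  }

  rim_phi <- c(30, 150) * pi / 180
  jv <- vapply(rim_phi, function(p) which.min(abs(phi - p)), integer(1L))
  valve <- epi$vertices[1L + (n_t - 1L) * n_p + jv, , drop = FALSE]

  lv_mesh(patient_id, epi, endo, scar = scar, valve_points = valve,
          validate = FALSE)
}

#' Generate one synthetic LV mesh
#'
#' Truncated prolate-spheroid two-surface shell with smooth random shape
#' perturbation; when `scarred`, a contiguous patch has its wall thickness
#' multiplied by the scar spec's `thinning_factor` with a smooth boundary
#' taper, and a closed scar sub-mesh fills the patch mid-wall.  Valve
#' markers sit on the basal rim.  Fully reproducible from `seed`.
#'
#' @param spec a [cohort_spec()].
#' @param scarred logical.
#' @param seed integer seed.
#' @param patient_id identifier.
#' @return an [lv_mesh()] in its canonical frame (long axis = z, apex down).
#' @export
generate_lv_mesh <- function(spec = cohort_spec(), scarred = FALSE,
                             seed = 1L, patient_id = "synthetic") {
  set.seed(seed)
  params <- draw_patient_params(spec)
  pert_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  build_patient_mesh(params, spec, scarred, pert_seed, patient_id)
}

rotation_from_axis_angle <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3L], -u[2L], -u[3L], 0, u[1L], u[2L], -u[1L], 0), 3L, 3L)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

transform_lv_mesh <- function(mesh, R, t) {
  tf <- function(v) sweep(v %*% t(R), 2L, t, "+")
  mesh$epi$vertices <- tf(mesh$epi$vertices)
  mesh$endo$vertices <- tf(mesh$endo$vertices)
  if (!is.null(mesh$scar)) mesh$scar$vertices <- tf(mesh$scar$vertices)
  if (!is.null(mesh$valve_points)) mesh$valve_points <- tf(mesh$valve_points)
  mesh
}

scale_lv_mesh <- function(mesh, s) {
  mesh$epi$vertices <- mesh$epi$vertices * s
  mesh$endo$vertices <- mesh$endo$vertices * s
  if (!is.null(mesh$scar)) mesh$scar$vertices <- mesh$scar$vertices * s
  if (!is.null(mesh$valve_points)) mesh$valve_points <- mesh$valve_points * s
  mesh
}

# per-slice ground truth from the slicing protocol (plane/scar span test)
protocol_labels <- function(mesh, n_slices = 25L, apex_offset = 0.20) {
  frame <- compute_axes(mesh)
  s <- seq(apex_offset * frame$length, frame$length, length.out = n_slices)
  lab <- integer(n_slices)
  if (!is.null(mesh$scar)) {
    d <- drop(mesh$scar$vertices %*% frame$long_axis) -
      sum(frame$apex_point * frame$long_axis)
    lab <- as.integer(s >= min(d) - 1e-9 & s <= max(d) + 1e-9)
  }
  data.frame(slice_index = seq_len(n_slices) - 1L,
             normalized_position = s / frame$length,
             label = lab)
}

#' Generate a paired synthetic cohort
#'
#' For each patient: an "MRI-like" mesh (with scar sub-mesh for scarred
#' patients) and a paired "CTA-like" mesh built from the same patient
#' anatomy with an independent smooth perturbation, a global volume change
#' whose mean magnitude matches `modality_perturbation`, and a random rigid
#' displacement (to be undone by registration).  `ceiling(n * prevalence)`
#' patients are scarred.  Slice labels follow the slicing protocol on the
#' MRI-like mesh.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `lv_cohort`; each patient holds `mri`, `cta`,
#'   `scarred`, `labels`, `true_transform` (list `R`, `t` mapping MRI to
#'   CTA frame), `delta_volume` (signed relative blood-volume change).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  set.seed(spec$seed)
  n <- spec$n_patients
  n_scar <- ceiling(n * spec$scar_prevalence)
  scarred <- c(rep(TRUE, n_scar), rep(FALSE, n - n_scar))
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, 4L * n), n, 4L)
  patients <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(seeds[i, 1L])
    params <- draw_patient_params(spec)
    id <- sprintf("P%03d", i)
    mri <- build_patient_mesh(params, spec, scarred[i], seeds[i, 2L], id)
    cta <- build_patient_mesh(params, spec, scarred[i], seeds[i, 3L], id)
    set.seed(seeds[i, 4L])
    delta <- rnorm(1L, 0, spec$modality_perturbation * sqrt(pi / 2))
    delta <- max(min(delta, 0.45), -0.45)
    v1 <- mesh_volume(mri$endo)
    v2 <- mesh_volume(cta$endo)
    cta <- scale_lv_mesh(cta, ((1 + delta) * v1 / v2)^(1 / 3))
    ax <- rnorm(3L)
    R <- rotation_from_axis_angle(ax, runif(1L, 5, 20) * pi / 180)
    t <- runif(3L, -10, 10)
    cta <- transform_lv_mesh(cta, R, t)
    patients[[i]] <- list(patient_id = id, mri = mri, cta = cta,
                          scarred = scarred[i],
                          labels = protocol_labels(mri),
                          true_transform = list(R = R, t = t),
                          delta_volume = delta,
                          seeds = seeds[i, ])
  }
  structure(list(patients = patients, spec = spec), class = "lv_cohort")
}

#' @export
print.lv_cohort <- function(x, ...) {
  ns <- sum(vapply(x$patients, `[[`, logical(1L), "scarred"))
  cat(sprintf("synthetic LV cohort: %d patients (%d scarred), seed %d\n",
              length(x$patients), ns, x$spec$seed))
  invisible(x)
}
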