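## Rigid ICP registration of paired LV meshes and scar transfer.

#' Rigid transform
#'
#' @param R 3x3 rotation matrix (orthonormal, det +1).
#' @param t length-3 translation, mm.
#' @return list of class `rigid_transform`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  if (max(abs(R %*% t(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop("R is not a proper rotation")
  structure(list(R = R, t = as.numeric(t)), class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param transform a [rigid_transform()].
#' @param points `n x 3` matrix.
#' @return transformed `n x 3` matrix.
#' @export
apply_rigid <- function(transform, points) {
  sweep(points %*% t(transform$R), 2L, transform$t, "+")
}

compose_rigid <- function(b, a) {
  # returns b o a : x -> b(a(x))
  rigid_transform(b$R %*% a$R, drop(b$R %*% a$t) + b$t)
}

# rotation taking unit vector u onto unit vector v
rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  ax <- c(u[2L] * v[3L] - u[3L] * v[2L],
          u[3L] * v[1L] - u[1L] * v[3L],
          u[1L] * v[2L] - u[2L] * v[1L])
  s <- sqrt(sum(ax^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antipodal: rotate pi about any axis orthogonal to u
    o <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- o - sum(o * u) * u
    return(rotation_from_axis_angle(ax, pi))
  }
  rotation_from_axis_angle(ax, atan2(s, c_))
}

kabsch <- function(src, dst) {
  cs <- colMeans(src); cd <- colMeans(dst)
  H <- crossprod(sweep(src, 2L, cs), sweep(dst, 2L, cd))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cd - drop(R %*% cs)
  rigid_transform(R, t)
}

icp_initialize <- function(source, target, src_frame, tgt_frame) {
  R1 <- rotation_between(src_frame$long_axis, tgt_frame$long_axis)
  # roll about the target axis from valve-marker correspondence
  R <- R1
  if (!is.null(source$valve_points) && !is.null(target$valve_points)) {
    ax <- tgt_frame$long_axis
    sv <- drop(R1 %*% (source$valve_points[1L, ] - src_frame$apex_point))
    sv <- sv - sum(sv * ax) * ax
    tv <- target$valve_points[1L, ] - tgt_frame$apex_point
    tv <- tv - sum(tv * ax) * ax
    if (sqrt(sum(sv^2)) > 1e-6 && sqrt(sum(tv^2)) > 1e-6) {
      ang <- atan2(sum(ax * c(sv[2L] * tv[3L] - sv[3L] * tv[2L],
                              sv[3L] * tv[1L] - sv[1L] * tv[3L],
                              sv[1L] * tv[2L] - sv[2L] * tv[1L])),
                   sum(sv * tv))
      R <- rotation_from_axis_angle(ax, ang) %*% R1
    }
  }
  t <- tgt_frame$apex_point - drop(R %*% src_frame$apex_point)
  rigid_transform(R, t)
}

#' Rigid ICP registration of two LV meshes
#'
#' Initialization aligns the PCA axis frames (long axis onto long axis,
#' roll resolved from the first valve marker, apex onto apex), followed by
#' standard point-to-point ICP on the epicardial vertices: alternate
#' closest-point correspondence and Kabsch (SVD) transform estimation until
#' the mean closest-point distance changes by less than `tol` mm or
#' `max_iter` iterations.
#'
#' @param source,target [lv_mesh()] objects.
#' @param max_iter iteration cap (default 200).
#' @param tol convergence threshold on the mean distance change, mm.
#' @param n_sample number of source vertices used for correspondence
#'   (deterministic subsample; all vertices if fewer).
#' @param translation_only estimate a translation only (identity rotation),
#'   matching a pure-translation registration convention.
#' @return a `rigid_transform` mapping source into the target frame, with
#'   attributes `iterations`, `mean_distance`, `distance_trace`,
#'   `converged`.
#' @export
icp_register <- function(source, target, max_iter = 200L, tol = 1e-4,
                         n_sample = 600L, translation_only = FALSE) {
  src_frame <- compute_axes(source)
  tgt_frame <- compute_axes(target)
  tr <- if (translation_only)
    rigid_transform(diag(3), tgt_frame$apex_point - src_frame$apex_point)
  else icp_initialize(source, target, src_frame, tgt_frame)
  pts <- source$epi$vertices
  if (nrow(pts) > n_sample) {
    sel <- round(seq(1L, nrow(pts), length.out = n_sample))
    pts <- pts[sel, , drop = FALSE]
  }
  ref <- target$epi$vertices
  trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    cur <- apply_rigid(tr, pts)
    nn <- nn_closest_cpp(cur, ref)
    md <- mean(nn$dist)
    trace <- c(trace, md)
    step <- if (translation_only)
      rigid_transform(diag(3), colMeans(ref[nn$index, , drop = FALSE]) -
                        colMeans(cur))
    else kabsch(cur, ref[nn$index, , drop = FALSE])
    tr <- compose_rigid(step, tr)
    if (abs(prev - md) < tol) { converged <- TRUE; break }
    prev <- md
  }
  if (!converged)
    warning(sprintf("ICP hit the %d-iteration cap (mean distance %.4f mm)",
                    max_iter, prev))
  structure(tr, iterations = iter, mean_distance = trace[length(trace)],
            distance_trace = trace, converged = converged)
}

#' Transfer a scar mesh across modalities
#'
#' Maps every scar vertex by `x -> R x + t`; topology unchanged.
#'
#' @param scar a scar [surface_mesh()].
#' @param transform a [rigid_transform()] (typically from [icp_register()]).
#' @return the scar mesh in the target frame.
#' @export
transfer_scar <- function(scar, transform) {
  scar$vertices <- apply_rigid(transform, scar$vertices)
  scar
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(max(min((sum(diag(x$R)) - 1) / 2, 1), -1)) * 180 / pi
  cat(sprintf("rigid transform: rotation %.2f deg, translation (%.2f, %.2f, %.2f) mm\n",
              ang, x$t[1L], x$t[2L], x$t[3L]))
  invisible(x)
}

#' Serialize a rigid transform to JSON
#' @param transform a [rigid_transform()].
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_transform_json <- function(transform, path) {
  jsonlite::write_json(list(rotation = as.numeric(t(transform$R)),
                            translation = transform$t,
                            iterations = attr(transform, "iterations"),
                            mean_distance = attr(transform, "mean_distance"),
                            converged = attr(transform, "converged")),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
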