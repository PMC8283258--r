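## Mesh and raster file IO: ASCII STL, PLY and legacy VTK polydata for
## surfaces (no installed R package reads these formats), PNG for masks.

#' Write a surface mesh
#'
#' Format from the file extension: `.ply` (ASCII PLY), `.stl` (ASCII STL),
#' `.vtk` (legacy VTK polydata).
#'
#' @param mesh a [surface_mesh()].
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_surface_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  if (ext == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L), con)
  } else if (ext == "stl") {
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(f))) {
      tri <- v[f[i, ], , drop = FALSE]
      n <- c((tri[2, 2] - tri[1, 2]) * (tri[3, 3] - tri[1, 3]) -
               (tri[2, 3] - tri[1, 3]) * (tri[3, 2] - tri[1, 2]),
             (tri[2, 3] - tri[1, 3]) * (tri[3, 1] - tri[1, 1]) -
               (tri[2, 1] - tri[1, 1]) * (tri[3, 3] - tri[1, 3]),
             (tri[2, 1] - tri[1, 1]) * (tri[3, 2] - tri[1, 2]) -
               (tri[2, 2] - tri[1, 2]) * (tri[3, 1] - tri[1, 1]))
      nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
      writeLines(c(sprintf("facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                   "  outer loop",
                   sprintf("    vertex %.9g %.9g %.9g",
                           tri[, 1L], tri[, 2L], tri[, 3L]),
                   "  endloop", "endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  } else if (ext == "vtk") {
    writeLines(c("# vtk DataFile Version 3.0", "surface", "ASCII",
                 "DATASET POLYDATA",
                 sprintf("POINTS %d float", nrow(v))), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]), con)
    writeLines(sprintf("POLYGONS %d %d", nrow(f), 4L * nrow(f)), con)
    writeLines(sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L), con)
  } else stop("unsupported mesh format: ", ext)
  invisible(path)
}

#' Read a surface mesh (ASCII STL, PLY or legacy VTK polydata)
#'
#' STL facets are merged into shared vertices (exact coordinate match).
#'
#' @param path mesh file.
#' @return a [surface_mesh()].
#' @export
read_surface_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path, warn = FALSE)
  if (ext == "ply") {
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)[1L]))
    nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)[1L]))
    start <- which(lines == "end_header")[1L]
    vv <- do.call(rbind, lapply(strsplit(trimws(lines[start + seq_len(nv)]), "\\s+"),
                                function(x) as.numeric(x[1:3])))
    ff <- do.call(rbind, lapply(strsplit(trimws(lines[start + nv + seq_len(nf)]), "\\s+"),
                                function(x) as.integer(x[2:4]) + 1L))
    surface_mesh(vv, ff)
  } else if (ext == "stl") {
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                    function(x) as.numeric(x[2:4])))
    key <- paste(coords[, 1L], coords[, 2L], coords[, 3L])
    uk <- !duplicated(key)
    vid <- match(key, key[uk])
    vv <- coords[uk, , drop = FALSE]
    ff <- matrix(vid, ncol = 3L, byrow = TRUE)
    surface_mesh(vv, ff)
  } else if (ext == "vtk") {
    ip <- grep("^POINTS", lines)[1L]
    nv <- as.integer(strsplit(lines[ip], "\\s+")[[1L]][2L])
    nums <- as.numeric(unlist(strsplit(trimws(
      lines[(ip + 1L):(grep("^POLYGONS", lines)[1L] - 1L)]), "\\s+")))
    vv <- matrix(nums[seq_len(3L * nv)], ncol = 3L, byrow = TRUE)
    if_ <- grep("^POLYGONS", lines)[1L]
    nf <- as.integer(strsplit(lines[if_], "\\s+")[[1L]][2L])
    fnums <- as.integer(unlist(strsplit(trimws(lines[(if_ + 1L):length(lines)]), "\\s+")))
    fm <- matrix(fnums[seq_len(4L * nf)], ncol = 4L, byrow = TRUE)
    surface_mesh(vv, fm[, 2:4, drop = FALSE] + 1L)
  } else stop("unsupported mesh format: ", ext)
}

#' Write an LV mesh as per-surface files plus a JSON manifest
#'
#' Files follow the `<id>_epi.<fmt>`, `<id>_endo.<fmt>`, `<id>_scar.<fmt>`
#' naming convention; valve markers and file names go to
#' `<id>_manifest.json`.
#'
#' @param mesh an [lv_mesh()].
#' @param dir output directory (created).
#' @param format `"ply"`, `"stl"` or `"vtk"`.
#' @return manifest path invisibly.
#' @export
write_lv_mesh <- function(mesh, dir, format = "ply") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- mesh$patient_id
  files <- list(epi = sprintf("%s_epi.%s", id, format),
                endo = sprintf("%s_endo.%s", id, format))
  write_surface_mesh(mesh$epi, file.path(dir, files$epi))
  write_surface_mesh(mesh$endo, file.path(dir, files$endo))
  if (!is.null(mesh$scar)) {
    files$scar <- sprintf("%s_scar.%s", id, format)
    write_surface_mesh(mesh$scar, file.path(dir, files$scar))
  }
  manifest <- list(patient_id = id, files = files,
                   valve_points = if (is.null(mesh$valve_points)) NULL else
                     apply(mesh$valve_points, 1L, as.numeric, simplify = FALSE))
  mp <- file.path(dir, sprintf("%s_manifest.json", id))
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Read an LV mesh from a JSON manifest
#' @param manifest_path path to a `<id>_manifest.json`.
#' @param validate run [validate_lv_mesh()].
#' @return an [lv_mesh()].
#' @export
read_lv_mesh <- function(manifest_path, validate = FALSE) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  vp <- m$valve_points
  if (!is.null(vp) && !is.matrix(vp))
    vp <- do.call(rbind, lapply(vp, as.numeric))
  lv_mesh(m$patient_id,
          epi = read_surface_mesh(file.path(dir, m$files$epi)),
          endo = read_surface_mesh(file.path(dir, m$files$endo)),
          scar = if (is.null(m$files$scar)) NULL else
            read_surface_mesh(file.path(dir, m$files$scar)),
          valve_points = vp, validate = validate)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#' @param mask an `anatomical_mask` or `polar_mask`.
#' @param path output PNG.
#' @return `path` invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask$grid * 1.0, path)
  if (inherits(mask, "polar_mask")) {
    side <- list(center_used = mask$center_used,
                 radial_resolution = mask$radial_resolution,
                 angular_resolution = mask$angular_resolution)
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Write a cohort to disk (meshes + manifest CSV)
#' @param cohort an `lv_cohort`.
#' @param dir output directory.
#' @param format mesh format.
#' @return the cohort manifest CSV path invisibly.
#' @export
write_cohort <- function(cohort, dir, format = "ply") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort$patients, function(p) {
    write_lv_mesh(p$mri, file.path(dir, p$patient_id, "mri"), format)
    write_lv_mesh(p$cta, file.path(dir, p$patient_id, "cta"), format)
    write.csv(p$labels,
              file.path(dir, p$patient_id, "labels.csv"), row.names = FALSE)
    data.frame(patient_id = p$patient_id, scarred = p$scarred,
               delta_volume = p$delta_volume)
  })
  mp <- file.path(dir, "cohort.csv")
  write.csv(do.call(rbind, rows), mp, row.names = FALSE)
  invisible(mp)
}
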