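## Slice dataset container: per-slice metadata plus packed polar masks.

mask_to_raw <- function(grid) as.raw(as.integer(grid))

raw_to_mask <- function(col, size) matrix(as.integer(col), size, size)

new_slice_dataset <- function(info, masks, size = 256L) {
  structure(list(info = info, masks = masks, size = as.integer(size)),
            class = "slice_dataset")
}

#' @export
print.slice_dataset <- function(x, ...) {
  v <- x$info$valid
  cat(sprintf("slice dataset: %d slices from %d patients (%d valid, %d scar among valid)\n",
              nrow(x$info), length(unique(x$info$patient_id)),
              sum(v), sum(x$info$label[v] == 1L)))
  invisible(x)
}

#' Subset a slice dataset
#' @param x a `slice_dataset`.
#' @param i row index into `x$info`.
#' @param ... ignored.
#' @return a `slice_dataset` with the selected slices.
#' @export
`[.slice_dataset` <- function(x, i, ...) {
  info <- x$info[i, , drop = FALSE]
  rownames(info) <- NULL
  new_slice_dataset(info, x$masks[, i, drop = FALSE], x$size)
}

#' Valid (retained) samples of a slice dataset
#' @param dataset a `slice_dataset`.
#' @return the subset with `valid == TRUE`.
#' @export
valid_samples <- function(dataset) dataset[which(dataset$info$valid)]

#' Slice one LV mesh into labeled samples
#'
#' Runs the full per-patient geometry pipeline: PCA axes, short-axis
#' slicing, rasterization, scar labeling, exclusion filtering, and polar
#' re-encoding of the retained slices.
#'
#' @param mesh an [lv_mesh()].
#' @param scar_mesh scar surface used for ground truth (default the mesh's
#'   own); pass a transferred scar mesh for cross-modality labels, or
#'   `NULL` for all-negative labels.
#' @param n_slices,apex_offset,valve_tol slicing protocol parameters.
#' @param size,resolution raster geometry (256 px at 1 mm).
#' @param min_pixels exclusion threshold on foreground pixels.
#' @return list of `slice_sample` lists (fields `mask`, `polar`, `label`,
#'   `valid`, `reason`, ...).
#' @export
slice_patient <- function(mesh, scar_mesh = mesh$scar, n_slices = 25L,
                          apex_offset = 0.20, valve_tol = 2.0, size = 256L,
                          resolution = 1, min_pixels = 50L) {
  frame <- compute_axes(mesh)
  slices <- slice_mesh(mesh, frame, n_slices, apex_offset, valve_tol)
  lapply(slices, function(sc) {
    mask <- rasterize_slice(sc, size, resolution, patient_id = mesh$patient_id)
    smp <- list(mask = mask,
                label = label_slice(sc, scar_mesh),
                hits_valve = sc$hits_valve,
                self_intersecting = sc$self_intersecting,
                slice_index = sc$slice_index,
                normalized_position = sc$normalized_position,
                patient_id = mesh$patient_id)
    smp <- filter_slice(smp, min_pixels)
    smp$polar <- if (smp$valid)
      pad_polar(suppressWarnings(to_polar(mask, size = size)), size)
    else NULL
    class(smp) <- "slice_sample"
    smp
  })
}

#' Build a slice dataset from a synthetic cohort
#'
#' Applies [slice_patient()] to one modality of every patient.  Labels come
#' from each mesh's own scar sub-mesh (`labels = "native"`); for the
#' CTA-like meshes, `labels = "none"` leaves ground truth to the
#' registration-transfer test flow.
#'
#' @param cohort an `lv_cohort` from [generate_cohort()].
#' @param modality `"mri"` or `"cta"`.
#' @param labels `"native"` or `"none"`.
#' @param ... passed to [slice_patient()].
#' @return a `slice_dataset`.
#' @export
cohort_to_dataset <- function(cohort, modality = c("mri", "cta"),
                              labels = c("native", "none"), ...) {
  modality <- match.arg(modality)
  labels <- match.arg(labels)
  size <- list(...)$size
  if (is.null(size)) size <- 256L
  rows <- list(); cols <- list()
  for (p in cohort$patients) {
    mesh <- p[[modality]]
    samples <- slice_patient(mesh,
                             scar_mesh = if (labels == "native") mesh$scar else NULL,
                             ...)
    for (s in samples) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = p$patient_id,
        slice_index = s$slice_index,
        normalized_position = s$normalized_position,
        label = s$label,
        valid = s$valid,
        reason = s$reason,
        n_pixels = s$n_pixels,
        stringsAsFactors = FALSE)
      cols[[length(cols) + 1L]] <- if (is.null(s$polar))
        raw(size * size) else mask_to_raw(s$polar$grid)
    }
  }
  info <- do.call(rbind, rows)
  rownames(info) <- NULL
  masks <- do.call(cbind, cols)
  new_slice_dataset(info, masks, size)
}

#' Per-slice minimum wall thickness of a dataset
#'
#' Minimum, over angular columns with any foreground, of the foreground
#' row count in the polar mask (mm at 1 mm radial resolution).
#'
#' @param dataset a `slice_dataset` of polar masks.
#' @return numeric vector (Inf for empty masks).
#' @export
dataset_thickness <- function(dataset) {
  n <- ncol(dataset$masks)
  out <- numeric(n)
  for (i in seq_len(n)) {
    g <- raw_to_mask(dataset$masks[, i], dataset$size)
    cs <- colSums(g)
    cs <- cs[cs > 0]
    out[i] <- if (length(cs) == 0L) Inf else min(cs)
  }
  out
}

#' Write per-patient slice labels and exclusion reasons to CSV
#' @param dataset a `slice_dataset`.
#' @param path output CSV path.
#' @return `path` invisibly.
#' @export
write_labels_csv <- function(dataset, path) {
  write.csv(dataset$info, path, row.names = FALSE)
  invisible(path)
}

#' Read a slice label table written by [write_labels_csv()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_labels_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
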