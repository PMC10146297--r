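# Voxel-grid data model and file I/O. All downstream modules receive voxel
# spacing only through the voxel_volume / label_mask containers; nothing
# assumes isotropic voxels. Physical position of array element (i, j, k)
# (1-based) is origin + (index - 1) * spacing, with the third axis the slice
# (z) direction.

HU_MIN <- -1024
HU_MAX <- 4000

#' CT volume container
#'
#' A 3D grid of attenuation values in Hounsfield units (HU) together with the
#' geometric and acquisition metadata every pipeline stage needs: voxel
#' spacing in mm, physical origin, modality (`"CSCT"` for non-contrast
#' calcium-scoring CT, `"CCTA"` for contrast-enhanced angiography) and tube
#' voltage in kVp. HU values outside `[-1024, 4000]` are clipped with a
#' warning (scanner overflow voxels are tolerated, not fatal).
#'
#' @param data numeric 3D array of HU values.
#' @param spacing length-3 numeric, voxel size (dx, dy, dz) in mm; all > 0.
#' @param origin length-3 numeric, physical coordinate of the first voxel, mm.
#' @param modality `"CSCT"` or `"CCTA"`.
#' @param kvp tube voltage, one of 80, 90, 100, 120.
#' @return an object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, spacing, origin = c(0, 0, 0),
                         modality = c("CSCT", "CCTA"), kvp = 120L) {
  modality <- match.arg(modality)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_cac("volume data must be a 3D array", "cac_format_error")
  }
  if (any(dim(data) < 1L)) {
    stop_cac("volume must have at least one voxel per axis", "cac_format_error")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop_cac("spacing must be three positive numbers (mm)", "cac_format_error")
  }
  if (!kvp %in% c(80L, 90L, 100L, 120L)) {
    stop_cac("kvp must be one of 80, 90, 100, 120", "cac_parameter_error")
  }
  rng <- range(data, na.rm = TRUE)
  if (rng[1] < HU_MIN || rng[2] > HU_MAX) {
    warning(sprintf(
      "HU values outside [%d, %d] clipped (observed range %.0f..%.0f)",
      HU_MIN, HU_MAX, rng[1], rng[2]
    ), call. = FALSE)
    data <- clamp(data, HU_MIN, HU_MAX)
  }
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin),
         modality = modality, kvp = as.integer(kvp)),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf(
    "<voxel_volume> %s @ %d kVp, %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
    x$modality, x$kvp, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
    x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  invisible(x)
}

# Voxel volume in mm^3.
voxel_mm3 <- function(vol) prod(vol$spacing)

#' Integer label mask aligned to a voxel volume
#'
#' @param data integer 3D array (0 = background), same dim as its parent
#'   volume.
#' @param vol the parent [voxel_volume()] supplying spacing and origin.
#' @param semantics named integer vector mapping label names to label values,
#'   e.g. `c(coronary = 1L, vein = 2L)`.
#' @return an object of class `label_mask`.
#' @export
label_mask <- function(data, vol, semantics = integer()) {
  if (!identical(dim(data), dim(vol$data))) {
    stop_cac("label mask must match the parent volume shape", "cac_format_error")
  }
  if (any(data < 0L)) stop_cac("labels must be non-negative", "cac_format_error")
  storage.mode(data) <- "integer"
  structure(
    list(data = data, spacing = vol$spacing, origin = vol$origin,
         semantics = semantics),
    class = "label_mask"
  )
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d labelled voxels; labels: %s\n",
              sum(x$data > 0L),
              paste(sprintf("%s=%d", names(x$semantics), x$semantics),
                    collapse = ", ")))
  invisible(x)
}

#' Read a CT volume from a NIfTI file
#'
#' Spacing is taken from the file header; HU values pass through unmodified
#' apart from the container's overflow clipping. Directories (DICOM series)
#' are not supported; convert to NIfTI first.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @inheritParams voxel_volume
#' @return a [voxel_volume()].
#' @export
read_volume <- function(path, modality = c("CSCT", "CCTA"), kvp = 120L) {
  modality <- match.arg(modality)
  if (!file.exists(path)) {
    stop_cac(sprintf("no such file: %s", path), "cac_input_error")
  }
  if (dir.exists(path)) {
    stop_cac("directory input (DICOM series) is not supported; convert to NIfTI",
             "cac_format_error")
  }
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) {
    stop_cac("expected a 3D NIfTI volume", "cac_format_error")
  }
  arr <- array(as.numeric(arr), dim(arr))  # drop NIfTI header attributes
  spacing <- RNifti::pixdim(img)[1:3]
  voxel_volume(arr, spacing = spacing, origin = c(0, 0, 0),
               modality = modality, kvp = kvp)
}

#' Write a CT volume to a NIfTI file
#'
#' Lossless for the stored grid; the header spacing equals `vol$spacing`.
#'
#' @param vol a [voxel_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Hounsfield units from stored DICOM pixel values
#'
#' The standard linear rescale `HU = slope * stored + intercept`.
#'
#' @param stored stored pixel value(s).
#' @param slope,intercept DICOM RescaleSlope / RescaleIntercept.
#' @export
#' @examples
#' dicom_rescale_hu(1154, slope = 1, intercept = -1024)  # 130 HU
dicom_rescale_hu <- function(stored, slope = 1, intercept = 0) {
  slope * stored + intercept
}

#' Paired scores for one subject
#'
#' Holds per-vessel (LCA, RCA) and total volume and Agatston scores for two
#' scoring methods on the same subject.
#'
#' @param id subject identifier.
#' @param method_a,method_b named lists with elements `volume` and `agatston`,
#'   each a named numeric vector with entries `LCA`, `RCA`, `total`.
#' @param kvp tube voltage of the CCTA acquisition.
#' @return an object of class `score_pair`.
#' @export
score_pair <- function(id, method_a, method_b, kvp = 120L) {
  check_side <- function(m, label) {
    for (what in c("volume", "agatston")) {
      v <- m[[what]]
      if (is.null(v) || !all(c("LCA", "RCA", "total") %in% names(v))) {
        stop_cac(sprintf("%s$%s must contain LCA, RCA and total", label, what),
                 "cac_validation_error")
      }
      if (any(v < 0)) {
        stop_cac(sprintf("negative %s score for subject %s", what, id),
                 "cac_validation_error")
      }
      if (abs(v[["total"]] - v[["LCA"]] - v[["RCA"]]) >
          1e-3 + 1e-6 * abs(v[["total"]])) {
        stop_cac(sprintf("subject %s: total %s score != LCA + RCA", id, what),
                 "cac_validation_error")
      }
    }
  }
  check_side(method_a, "method_a")
  check_side(method_b, "method_b")
  structure(list(id = as.character(id), method_a = method_a,
                 method_b = method_b, kvp = as.integer(kvp)),
            class = "score_pair")
}

#' Read a paired score table
#'
#' Expects a CSV with columns `id, kvp, method, vessel_group, volume_score,
#' agatston_score`, with `method` taking exactly two values and
#' `vessel_group` in `LCA, RCA, total`. Every subject must be present for
#' both methods.
#'
#' @param path CSV file path.
#' @return list of [score_pair()] objects, one per subject.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop_cac(sprintf("no such file: %s", path), "cac_input_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "kvp", "method", "vessel_group", "volume_score", "agatston_score")
  if (!all(need %in% names(df))) {
    stop_cac(sprintf("score table must have columns: %s", paste(need, collapse = ", ")),
             "cac_format_error")
  }
  if (any(df$volume_score < 0) || any(df$agatston_score < 0)) {
    stop_cac("negative scores in score table", "cac_validation_error")
  }
  methods <- sort(unique(df$method))
  if (length(methods) != 2L) {
    stop_cac("score table must contain exactly two methods", "cac_validation_error")
  }
  ids <- unique(df$id)
  missing_ids <- ids[vapply(ids, function(i) {
    length(unique(df$method[df$id == i])) != 2L
  }, logical(1))]
  if (length(missing_ids)) {
    stop_cac(sprintf("subjects present for one method only: %s",
                     paste(missing_ids, collapse = ", ")),
             "cac_validation_error")
  }
  side <- function(sub, m) {
    s <- sub[sub$method == m, ]
    grab <- function(col) {
      v <- stats::setNames(s[[col]], s$vessel_group)[c("LCA", "RCA", "total")]
      names(v) <- c("LCA", "RCA", "total")
      v
    }
    list(volume = grab("volume_score"), agatston = grab("agatston_score"))
  }
  lapply(ids, function(i) {
    sub <- df[df$id == i, ]
    score_pair(i, side(sub, methods[1]), side(sub, methods[2]),
               kvp = sub$kvp[1])
  })
}

#' Write a paired score table
#'
#' Inverse of [read_score_table()]; methods are written as `auto` (method A)
#' and `reference` (method B).
#'
#' @param pairs list of [score_pair()] objects.
#' @param path output CSV path.
#' @export
write_score_table <- function(pairs, path) {
  rows <- do.call(rbind, lapply(pairs, function(p) {
    do.call(rbind, lapply(c(a = "method_a", b = "method_b"), function(side) {
      m <- p[[side]]
      data.frame(
        id = p$id, kvp = p$kvp,
        method = if (side == "method_a") "auto" else "reference",
        vessel_group = c("LCA", "RCA", "total"),
        volume_score = as.numeric(m$volume[c("LCA", "RCA", "total")]),
        agatston_score = as.numeric(m$agatston[c("LCA", "RCA", "total")])
      )
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
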