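# Clinically standard calcium scoring on non-contrast CT: per-slice
# 8-connected lesion detection with the classic >130 HU / >1 mm^2 filters,
# per-slice-component Agatston weighting, and the volume score.

#' Parameters of the standard Agatston scorer
#'
#' Defaults encode the clinical convention: voxels strictly above 130 HU,
#' per-slice connected components strictly above 1 mm^2, and peak-attenuation
#' weight bins at 130/200/300/400 HU mapping to weights 1-4.
#'
#' @param hu_threshold detection threshold in HU (strict `>`).
#' @param min_area_mm2 minimum per-slice component area in mm^2 (strict `>`).
#' @param weight_edges lower edges of the weight bins, HU.
#' @param per_slice_area if `TRUE` (default) the area filter is applied per
#'   slice-component; if `FALSE`, per 3D lesion total area.
#' @return an object of class `agatston_params`.
#' @export
agatston_params <- function(hu_threshold = 130, min_area_mm2 = 1,
                            weight_edges = c(130, 200, 300, 400),
                            per_slice_area = TRUE) {
  stopifnot(all(diff(weight_edges) > 0))
  structure(list(hu_threshold = hu_threshold, min_area_mm2 = min_area_mm2,
                 weight_edges = weight_edges, per_slice_area = per_slice_area),
            class = "agatston_params")
}

#' Agatston weight of a peak attenuation
#'
#' Step function of the per-slice peak HU: 130-199 HU -> 1, 200-299 -> 2,
#' 300-399 -> 3, >= 400 -> 4. Values at a bin edge map to the upper bin.
#'
#' @param peak_hu peak attenuation(s), must exceed the detection threshold.
#' @param params an [agatston_params()].
#' @return integer weight(s) in 1..4.
#' @export
#' @examples
#' agatston_weight(c(150, 250, 400))  # 1 2 4
agatston_weight <- function(peak_hu, params = agatston_params()) {
  if (any(peak_hu <= params$hu_threshold)) {
    stop_cac("agatston_weight requires peak HU above the detection threshold",
             "cac_contract_error")
  }
  findInterval(peak_hu, params$weight_edges)
}

#' Detect calcified lesions on a calcium-scoring CT
#'
#' Per-slice 2D 8-connected components of voxels with HU strictly above the
#' threshold and component area strictly above the minimum are retained;
#' components overlapping across adjacent slices are merged into one 3D
#' lesion for volume reporting. Each lesion records its per-slice areas and
#' per-slice peak HU, which drive the Agatston sum.
#'
#' @param vol a [voxel_volume()] (typically CSCT).
#' @param params an [agatston_params()].
#' @param mask optional [label_mask()]; detection is restricted to voxels
#'   with a positive label.
#' @return list of `lesion` objects with fields `voxels` (n x 3 index
#'   matrix), `slices`, `slice_area_mm2`, `slice_peak_hu`, `volume_mm3`,
#'   `peak_hu`, `vessel`.
#' @export
detect_lesions <- function(vol, params = agatston_params(), mask = NULL) {
  d <- dim(vol$data)
  pix_mm2 <- vol$spacing[1] * vol$spacing[2]
  above <- vol$data > params$hu_threshold
  if (!is.null(mask)) above <- above & mask$data > 0L
  if (!any(above)) return(list())

  # stage 1: per-slice 2D components with the area filter
  slabs <- label_slices_2d(above)
  keep <- array(FALSE, d)
  comp_id <- array(0L, d)  # globally unique per-slice component ids
  next_id <- 0L
  for (k in seq_len(d[3])) {
    lab <- slabs[[k]]
    if (!any(lab > 0L)) next
    sizes <- tabulate(lab[lab > 0L])
    ok <- which(sizes * pix_mm2 > params$min_area_mm2)
    if (!params$per_slice_area) ok <- which(sizes > 0L)
    if (!length(ok)) next
    sel <- lab %in% ok
    keep[, , k] <- sel
    remap <- integer(length(sizes))
    remap[ok] <- next_id + seq_along(ok)
    comp_id[, , k][sel] <- remap[lab[sel]]
    next_id <- next_id + length(ok)
  }
  if (!any(keep)) return(list())

  # stage 2: merge slice-components that overlap across adjacent slices
  les_lab <- label_components(keep, connectivity = 26L)
  if (!params$per_slice_area) {
    # area filter on the total lesion in-plane footprint instead
    sizes3 <- tabulate(les_lab[les_lab > 0L])
    drop <- which(sizes3 * pix_mm2 <= params$min_area_mm2)
    if (length(drop)) {
      keep[les_lab %in% drop] <- FALSE
      les_lab <- label_components(keep, connectivity = 26L)
    }
    if (!any(keep)) return(list())
  }

  vox <- which(keep, arr.ind = TRUE)
  lid <- les_lab[keep]
  hu <- vol$data[keep]
  lesions <- lapply(sort(unique(lid)), function(li) {
    sel <- lid == li
    v <- vox[sel, , drop = FALSE]
    h <- hu[sel]
    ks <- sort(unique(v[, 3]))
    area <- vapply(ks, function(k) sum(v[, 3] == k) * pix_mm2, numeric(1))
    peak <- vapply(ks, function(k) max(h[v[, 3] == k]), numeric(1))
    structure(list(
      voxels = v, slices = ks, slice_area_mm2 = area, slice_peak_hu = peak,
      volume_mm3 = nrow(v) * voxel_mm3(vol), peak_hu = max(h),
      vessel = "unassigned"
    ), class = "lesion")
  })
  lesions
}

#' Agatston score of detected lesions
#'
#' The weighted sum over lesions and slices of (slice component area in mm^2)
#' x (weight of the slice peak HU) x (slice thickness / 3 mm). The thickness
#' normalisation is a no-op on standard 3 mm calcium-scoring CT and maps
#' thinner reconstructions onto the same scale.
#'
#' @param lesions output of [detect_lesions()].
#' @param params an [agatston_params()].
#' @param slice_thickness_mm slice thickness of the scored volume, mm.
#' @return the total Agatston score (dimensionless).
#' @export
agatston_score <- function(lesions, params = agatston_params(),
                           slice_thickness_mm = 3) {
  if (!length(lesions)) return(0)
  per <- vapply(lesions, function(l) {
    sum(l$slice_area_mm2 * agatston_weight(l$slice_peak_hu, params))
  }, numeric(1))
  sum(per) * slice_thickness_mm / 3
}

#' Calcium volume score
#'
#' Total volume in mm^3 of all lesion member voxels.
#'
#' @param lesions output of [detect_lesions()].
#' @param vol the [voxel_volume()] the lesions were detected on.
#' @return volume in mm^3.
#' @export
volume_score <- function(lesions, vol) {
  if (!length(lesions)) return(0)
  sum(vapply(lesions, function(l) nrow(l$voxels), numeric(1))) * voxel_mm3(vol)
}

#' Reference scoring of a calcium-scoring CT in one call
#'
#' Runs [detect_lesions()], [agatston_score()] and [volume_score()] and
#' splits both scores by vessel using the lesions' `vessel` fields (assigned
#' by the caller, e.g. from phantom ground truth or a vessel mask).
#'
#' @inheritParams detect_lesions
#' @return list with `lesions`, `agatston` and `volume`, the latter two named
#'   vectors over `LCA`, `RCA`, `unassigned`, `total`.
#' @export
score_csct <- function(vol, params = agatston_params(), mask = NULL) {
  lesions <- detect_lesions(vol, params, mask)
  groups <- c("LCA", "RCA", "unassigned")
  ag <- stats::setNames(numeric(3), groups)
  vo <- stats::setNames(numeric(3), groups)
  for (l in lesions) {
    g <- if (l$vessel %in% groups) l$vessel else "unassigned"
    ag[g] <- ag[g] + agatston_score(list(l), params, vol$spacing[3])
    vo[g] <- vo[g] + volume_score(list(l), vol)
  }
  list(lesions = lesions,
       agatston = c(ag, total = sum(ag)),
       volume = c(vo, total = sum(vo)))
}
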