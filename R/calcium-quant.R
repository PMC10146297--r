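# Adaptive-threshold calcium extraction on CCTA and the CCTA-side volume and
# adaptive-weight Agatston scores. The two printed multipliers are applied
# literally: where the centerline attenuation is unreliable (calcium
# suspected on the centerline), a pixel is calcium when its attenuation
# exceeds 1.45 x the calibration factor (strict >); where the centerline is
# reliable, when it is at least 1.25 x the centerline attenuation (>=).

#' Adaptive threshold parameters
#'
#' @param calib_multiplier multiplier of the calibration factor used when
#'   the centerline attenuation is unreliable (strict `>` rule).
#' @param centerline_multiplier multiplier of the local centerline
#'   attenuation used when it is reliable (`>=` rule).
#' @return object of class `adaptive_threshold_params`.
#' @export
adaptive_threshold_params <- function(calib_multiplier = 1.45,
                                      centerline_multiplier = 1.25) {
  if (calib_multiplier <= 1 || centerline_multiplier <= 1) {
    stop_cac("both multipliers must exceed 1", "cac_parameter_error")
  }
  if (calib_multiplier <= centerline_multiplier) {
    stop_cac("calib_multiplier must exceed centerline_multiplier",
             "cac_parameter_error")
  }
  structure(list(calib_multiplier = calib_multiplier,
                 centerline_multiplier = centerline_multiplier),
            class = "adaptive_threshold_params")
}

#' Adaptive calcium threshold on one cross-section
#'
#' @param section a `cross_section` from [cross_sections()].
#' @param calib a [calibration_factor()].
#' @param params an [adaptive_threshold_params()].
#' @return logical vector over the section's disc samples: `TRUE` where the
#'   sample is classified calcium.
#' @export
adaptive_threshold <- function(section, calib,
                               params = adaptive_threshold_params()) {
  hu <- section$hu
  sel <- if (!section$reliable) {
    hu > params$calib_multiplier * calib$value
  } else {
    hu >= params$centerline_multiplier * section$center_hu
  }
  sel & !is.na(hu)
}

#' Extract the calcium mask from cross-sections
#'
#' Applies [adaptive_threshold()] to every section, maps calcium samples
#' back to voxel space, forms 3D connected components and drops components
#' smaller than `min_voxels`. Components inherit the vessel label voted by
#' the sections that contributed their voxels.
#'
#' @param sections list from [cross_sections()].
#' @param vol the CCTA [voxel_volume()].
#' @param calib a [calibration_factor()].
#' @param params an [adaptive_threshold_params()].
#' @param min_voxels minimum component size in voxels.
#' @param exclude optional [label_mask()] (e.g. the dilated aorta) whose
#'   voxels are never classified as coronary calcium: the near-ostium
#'   sampling discs overlap the aortic blood pool, which must not be scored.
#' @return a [label_mask()] with semantics `LCA = 1, RCA = 2,
#'   unassigned = 3`.
#' @export
extract_calcium_mask <- function(sections, vol, calib,
                                 params = adaptive_threshold_params(),
                                 min_voxels = 2L, exclude = NULL) {
  d <- dim(vol$data)
  votes <- list(LCA = array(0L, d), RCA = array(0L, d), unassigned = array(0L, d))
  hit <- array(FALSE, d)
  for (sec in sections) {
    is_ca <- adaptive_threshold(sec, calib, params)
    if (!any(is_ca)) next
    off <- sec$offsets[is_ca, , drop = FALSE]
    # reconstruct the in-plane basis exactly as cross_sections built it
    tv <- sec$normal
    ref <- if (abs(tv[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u <- ref - sum(ref * tv) * tv
    u <- u / sqrt(sum(u^2))
    w <- c(tv[2] * u[3] - tv[3] * u[2], tv[3] * u[1] - tv[1] * u[3],
           tv[1] * u[2] - tv[2] * u[1])
    pts <- cbind(sec$center[1] + off[, 1] * u[1] + off[, 2] * w[1],
                 sec$center[2] + off[, 1] * u[2] + off[, 2] * w[2],
                 sec$center[3] + off[, 1] * u[3] + off[, 2] * w[3])
    idx <- mm_to_index(vol, pts)
    idx <- idx[!is.na(idx[, 1]), , drop = FALSE]
    if (!nrow(idx)) next
    hit[idx] <- TRUE
    grp <- if (sec$label %in% c("LCA", "RCA")) sec$label else "unassigned"
    votes[[grp]][idx] <- votes[[grp]][idx] + 1L
  }
  if (!is.null(exclude)) hit[exclude$data > 0L] <- FALSE
  out <- array(0L, d)
  if (any(hit)) {
    lab <- label_components(hit, 26L)
    sizes <- tabulate(lab[lab > 0L])
    for (ci in which(sizes >= min_voxels)) {
      sel <- lab == ci
      v <- c(LCA = sum(votes$LCA[sel]), RCA = sum(votes$RCA[sel]),
             unassigned = sum(votes$unassigned[sel]))
      out[sel] <- match(names(which.max(v)), c("LCA", "RCA", "unassigned"))
    }
  }
  label_mask(out, vol, semantics = c(LCA = 1L, RCA = 2L, unassigned = 3L))
}

#' CCTA calcium volume score
#'
#' Per-vessel voxel count times voxel volume.
#'
#' @param mask calcium [label_mask()] from [extract_calcium_mask()].
#' @param vol the CCTA [voxel_volume()].
#' @return named vector (mm^3) over `LCA`, `RCA`, `unassigned`, `total`.
#' @export
ccta_volume_score <- function(mask, vol) {
  vv <- voxel_mm3(vol)
  per <- vapply(c(LCA = 1L, RCA = 2L, unassigned = 3L), function(l) {
    sum(mask$data == l) * vv
  }, numeric(1))
  c(per, total = sum(per))
}

#' Adaptive Agatston weight map
#'
#' The standard weight bin edges (130/200/300/400 HU) scaled by the ratio of
#' the measured calibration factor to the packaged reference calibration
#' (the blood-pool working level at 120 kVp). At the reference calibration
#' the map reduces exactly to the standard Agatston bins; at lower tube
#' voltage, where both iodine and calcium attenuate higher, the bins scale
#' up with the calibration so that a plaque's weight is stable across kVp.
#'
#' @param calib a [calibration_factor()].
#' @param reference_calibration packaged reference value, HU.
#' @return object of class `adaptive_weight_map` with `edges` (scaled) and
#'   `scale`.
#' @export
adaptive_weight_map <- function(calib, reference_calibration = 400) {
  scale <- calib$value / reference_calibration
  structure(list(edges = c(130, 200, 300, 400) * scale, scale = scale,
                 reference_calibration = reference_calibration),
            class = "adaptive_weight_map")
}

#' Adaptive-weight Agatston score on CCTA
#'
#' Each calcium voxel contributes its in-plane area (mm^2) times the weight
#' of its attenuation under the adaptive bin edges, normalised by slice
#' thickness onto the 3 mm convention:
#' `score = sum(weight x dx dy) x dz / 3`. At the reference calibration and
#' 3 mm slices this is a voxel-wise analogue of the standard Agatston sum.
#'
#' @param mask calcium [label_mask()].
#' @param vol the CCTA [voxel_volume()].
#' @param calib a [calibration_factor()].
#' @param wmap an [adaptive_weight_map()]; defaults to the map for `calib`.
#' @return named vector over `LCA`, `RCA`, `unassigned`, `total`.
#' @export
adaptive_agatston <- function(mask, vol, calib, wmap = adaptive_weight_map(calib)) {
  pix <- vol$spacing[1] * vol$spacing[2]
  zfac <- vol$spacing[3] / 3
  per <- vapply(c(LCA = 1L, RCA = 2L, unassigned = 3L), function(l) {
    sel <- mask$data == l
    if (!any(sel)) return(0)
    w <- findInterval(vol$data[sel], wmap$edges)
    sum(w) * pix * zfac
  }, numeric(1))
  c(per, total = sum(per))
}

#' Assemble a score report
#'
#' JSON-serialisable record of one automated CCTA quantification: per-vessel
#' and total volume and Agatston scores, risk category, calibration value,
#' kVp, failure flag/reason and stage timings.
#'
#' @param ccta the CCTA [voxel_volume()] (or `NULL` on failure).
#' @param volume,agatston named score vectors (or `NULL` on failure).
#' @param calib a [calibration_factor()] (or `NULL`).
#' @param failure `NULL`, or a list with `stage` and `reason`.
#' @param timings named numeric vector of stage durations, seconds.
#' @return object of class `score_report`.
#' @export
score_report <- function(ccta = NULL, volume = NULL, agatston = NULL,
                         calib = NULL, failure = NULL, timings = numeric()) {
  rep <- list(
    failed = !is.null(failure),
    failure = failure,
    kvp = if (!is.null(ccta)) ccta$kvp else NA_integer_,
    calibration = if (!is.null(calib)) calib$value else NA_real_,
    volume = volume,
    agatston = agatston,
    risk_category = if (!is.null(agatston)) {
      as.character(classify_risk(agatston[["total"]]))
    } else NA_character_,
    timings = as.list(timings)
  )
  structure(rep, class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  if (x$failed) {
    cat(sprintf("<score_report> FAILED at %s: %s\n", x$failure$stage, x$failure$reason))
    return(invisible(x))
  }
  cat(sprintf("<score_report> kVp %d, calibration %.1f HU\n", x$kvp, x$calibration))
  cat(sprintf("  volume mm^3: LCA %.1f, RCA %.1f, total %.1f\n",
              x$volume[["LCA"]], x$volume[["RCA"]], x$volume[["total"]]))
  cat(sprintf("  Agatston: LCA %.1f, RCA %.1f, total %.1f (risk %s)\n",
              x$agatston[["LCA"]], x$agatston[["RCA"]], x$agatston[["total"]],
              x$risk_category))
  invisible(x)
}

#' Serialise / restore a score report as JSON
#'
#' @param report a [score_report()].
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @export
write_score_report <- function(report, path = NULL) {
  rep <- unclass(report)
  for (f in c("volume", "agatston")) {
    if (!is.null(rep[[f]])) rep[[f]] <- as.list(rep[[f]])
  }
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname write_score_report
#' @param json JSON string or file path produced by [write_score_report()].
#' @export
read_score_report <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  for (f in c("volume", "agatston")) {
    if (!is.null(x[[f]])) x[[f]] <- unlist(x[[f]])
  }
  structure(x, class = "score_report")
}
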