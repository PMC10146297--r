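# End-to-end orchestration: configuration with defaults, the automated CCTA
# scoring pipeline as one call with typed failure handling, and the phantom
# validation study (cohort generation -> reference CSCT scoring -> CCTA
# pipeline -> agreement statistics, excluding recorded failures the way a
# clinical validation excludes failed cases).

#' Pipeline configuration
#'
#' Every tunable of every stage with its frozen default. Thresholds and
#' multipliers were fixed once against a phantom tuning cohort and are not
#' data-adaptive at run time; the two adaptive-threshold multipliers are the
#' published values.
#'
#' @param ... named overrides of the defaults.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    gmm_k = 4L,
    gmm_subsample = 1e5,
    vessel_scales_mm = c(1.0, 1.6),
    hysteresis_high = 0.30,
    hysteresis_low = 0.05,
    vessel_hu_min = 150,
    aorta_radius_band_mm = c(10, 25),
    aorta_circularity_min = 0.8,
    calibration_a = 1,
    calibration_b = 0,
    reference_calibration = 400,
    gap_mm = 5,
    gap_angle_deg = 45,
    hu_floor_frac = 0.5,
    reliability_multiplier = 1.3,
    reliability_floor_frac = 0.85,
    calib_multiplier = 1.45,
    centerline_multiplier = 1.25,
    section_step_mm = 0.5,
    disc_radius_mm = 3.5,
    sample_spacing_mm = 0.3,
    min_component_voxels = 2L,
    cohort_n = 20L,
    cohort_seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop_cac(sprintf("unknown config fields: %s", paste(unknown, collapse = ", ")),
             "cac_parameter_error")
  }
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config a [pipeline_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the automated CCTA calcium quantification pipeline
#'
#' Executes the full chain on one contrast-enhanced volume: mixture-based
#' intensity modelling, attenuation-window standardisation, aorta
#' segmentation and calibration, Hessian vesselness and coronary
#' segmentation, gap connection and mislabel removal, skeletonisation,
#' cross-section sampling, adaptive-threshold calcium extraction and
#' scoring. Any typed stage failure (aorta not found, no coronary seed,
#' calibration out of band) is caught and returned as a failed
#' [score_report()], never an error.
#'
#' @param ccta a CCTA [voxel_volume()].
#' @param config a [pipeline_config()].
#' @param vessel_metadata optional named vector passed to
#'   [assign_vessel_labels()] for boundary-ambiguous ostia.
#' @return a [score_report()]; on success the attribute `detail` carries the
#'   intermediate objects (calibration, tree, masks).
#' @export
run_ccta_pipeline <- function(ccta, config = pipeline_config(),
                              vessel_metadata = NULL) {
  timings <- c()
  clock <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- expr
    list(val = val, dt = proc.time()[["elapsed"]] - t0)
  }
  fail <- function(stage, cond) {
    score_report(ccta = ccta, failure = list(stage = stage,
                                             reason = conditionMessage(cond)),
                 timings = timings)
  }
  stage <- "gmm"
  res <- tryCatch({
    st <- clock(fit_gmm_em(ccta, k = config$gmm_k, seed = config$seed,
                           subsample = config$gmm_subsample))
    timings["gmm"] <- st$dt
    model <- st$val

    stage <- "preprocess"
    st <- clock(optimize_attenuation_window(ccta, model))
    timings["preprocess"] <- st$dt
    pre <- st$val

    stage <- "aorta"
    st <- clock(segment_aorta(ccta, radius_band_mm = config$aorta_radius_band_mm,
                              circularity_min = config$aorta_circularity_min,
                              seed = config$seed, model = model))
    timings["aorta"] <- st$dt
    aorta <- st$val

    stage <- "calibration"
    st <- clock(calibration_factor(ccta, aorta, kvp = ccta$kvp,
                                   coef = c(config$calibration_a,
                                            config$calibration_b)))
    timings["calibration"] <- st$dt
    calib <- st$val

    stage <- "vesselness"
    st <- clock(vesselness(pre, scales_mm = config$vessel_scales_mm))
    timings["vesselness"] <- st$dt
    vmap <- st$val

    stage <- "coronary"
    st <- clock({
      cor_mask <- suppressWarnings(
        segment_coronary(pre, vmap, aorta, th_high = config$hysteresis_high,
                         th_low = config$hysteresis_low,
                         hu_min = config$vessel_hu_min))
      if (!any(cor_mask$data > 0L)) {
        stop_cac("no coronary seed adjacent to the aorta", "cac_no_seed_error")
      }
      cor_mask <- connect_gaps(cor_mask, ccta, max_gap_mm = config$gap_mm,
                               max_angle_deg = config$gap_angle_deg)
      cor_mask <- remove_mislabeled(cor_mask, aorta, ccta, calib)
      if (!any(cor_mask$data > 0L)) {
        stop_cac("no coronary component survived post-processing",
                 "cac_no_seed_error")
      }
      cor_mask
    })
    timings["coronary"] <- st$dt

    stage <- "centerline"
    st <- clock({
      tree <- skeletonize(cor_mask, ccta, aorta)
      if (!length(tree$segments)) {
        stop_cac("empty centerline tree", "cac_no_seed_error")
      }
      assign_vessel_labels(tree, aorta, metadata = vessel_metadata)
    })
    timings["centerline"] <- st$dt
    tree <- st$val

    stage <- "quantification"
    st <- clock({
      sections <- cross_sections(tree, ccta, calib,
                                 step_mm = config$section_step_mm,
                                 disc_radius_mm = config$disc_radius_mm,
                                 sample_spacing_mm = config$sample_spacing_mm,
                                 reliability_multiplier = config$reliability_multiplier,
                                 reliability_floor_frac = config$reliability_floor_frac)
      params <- adaptive_threshold_params(config$calib_multiplier,
                                          config$centerline_multiplier)
      aorta_excl <- label_mask(
        array(as.integer(dilate_mask(aorta$data > 0L, iter = 2L)), dim(ccta$data)),
        ccta, semantics = c(aorta = 1L))
      ca_mask <- extract_calcium_mask(sections, ccta, calib, params,
                                      min_voxels = config$min_component_voxels,
                                      exclude = aorta_excl)
      wmap <- adaptive_weight_map(calib, config$reference_calibration)
      list(mask = ca_mask,
           volume = ccta_volume_score(ca_mask, ccta),
           agatston = adaptive_agatston(ca_mask, ccta, calib, wmap))
    })
    timings["quantification"] <- st$dt
    q <- st$val

    rep <- score_report(ccta = ccta, volume = q$volume, agatston = q$agatston,
                        calib = calib, timings = timings)
    attr(rep, "detail") <- list(calibration = calib, aorta = aorta,
                                coronary = cor_mask, tree = tree,
                                calcium_mask = q$mask)
    rep
  }, cacscore_error = function(cond) fail(stage, cond))
  res
}

# Assign lesion vessels from known plaque centres (phantom ground truth).
assign_lesion_vessels <- function(lesions, vol, centers, vessels) {
  if (!length(lesions) || !nrow(centers)) return(lesions)
  lapply(lesions, function(l) {
    ctr <- colMeans(index_to_mm(vol, l$voxels))
    l$vessel <- vessels[which.min(sqrt(rowSums(sweep(centers, 2, ctr)^2)))]
    l
  })
}

#' Run the phantom validation study
#'
#' Generates a deterministic phantom cohort, scores the CSCT arm with the
#' standard reference scorer (lesion vessels assigned from the phantom
#' ground truth, as a human reader would assign them), runs the automated
#' CCTA pipeline on the contrast arm, excludes recorded failures from the
#' statistics while tallying them, and reports the full set of agreement
#' statistics for the total Agatston and volume scores.
#'
#' @param config a [pipeline_config()]; `cohort_n` and `cohort_seed` control
#'   the cohort.
#' @param progress print one line per subject.
#' @return list with `pairs` (per-subject [score_pair()]), `reports`
#'   (per-subject [score_report()]), `reference` and `auto` score tables,
#'   `agreement_agatston`, `agreement_volume`, `failures` and `truth`
#'   summaries.
#' @export
run_validation <- function(config = pipeline_config(), progress = FALSE) {
  specs <- default_cohort(config$cohort_n, config$cohort_seed)
  reports <- list()
  pairs <- list()
  failures <- list()
  truth_rows <- list()
  for (i in seq_along(specs)) {
    pair <- render_pair(specs[[i]])
    # reference arm: standard scoring of the (noisy) CSCT acquisition
    ref <- score_csct(pair$csct)
    ref$lesions <- assign_lesion_vessels(ref$lesions, pair$csct,
                                         pair$truth$plaque_centers,
                                         pair$truth$plaque_vessel)
    refsc <- score_csct_from_lesions(ref$lesions, pair$csct)
    rep <- run_ccta_pipeline(pair$ccta, config)
    reports[[i]] <- rep
    truth_rows[[i]] <- data.frame(
      subject = i, kvp = specs[[i]]$kvp,
      truth_agatston = pair$truth$agatston_ref[["total"]],
      truth_volume_ccta = sum(pair$truth$per_plaque_mm3_ccta)
    )
    if (rep$failed) {
      failures[[length(failures) + 1L]] <- list(subject = i,
                                                stage = rep$failure$stage,
                                                reason = rep$failure$reason)
      next
    }
    grab <- function(v) {
      out <- c(LCA = unname(v[["LCA"]]), RCA = unname(v[["RCA"]]))
      c(out, total = unname(sum(out)))
    }
    pairs[[length(pairs) + 1L]] <- score_pair(
      id = sprintf("S%03d", i),
      method_a = list(volume = grab(rep$volume), agatston = grab(rep$agatston)),
      method_b = list(volume = grab(refsc$volume), agatston = grab(refsc$agatston)),
      kvp = specs[[i]]$kvp
    )
    if (progress) {
      cat(sprintf("subject %d/%d: auto %.1f vs ref %.1f (Agatston)\n",
                  i, length(specs), rep$agatston[["total"]],
                  refsc$agatston[["total"]]))
    }
  }
  if (!length(pairs)) {
    return(list(pairs = list(), reports = reports, failures = failures,
                agreement_agatston = NULL, agreement_volume = NULL,
                truth = do.call(rbind, truth_rows),
                error = "all subjects failed; no statistics computable"))
  }
  auto_ag <- vapply(pairs, function(p) p$method_a$agatston[["total"]], numeric(1))
  ref_ag <- vapply(pairs, function(p) p$method_b$agatston[["total"]], numeric(1))
  auto_vo <- vapply(pairs, function(p) p$method_a$volume[["total"]], numeric(1))
  ref_vo <- vapply(pairs, function(p) p$method_b$volume[["total"]], numeric(1))
  enough <- length(pairs) >= 3L  # the correlation statistics need n >= 3
  list(
    pairs = pairs, reports = reports, failures = failures,
    agreement_agatston = if (enough) {
      agreement_report(auto_ag, ref_ag, categorical = TRUE)
    },
    agreement_volume = if (enough) {
      agreement_report(auto_vo, ref_vo, categorical = FALSE)
    },
    scores = data.frame(
      id = vapply(pairs, `[[`, character(1), "id"),
      kvp = vapply(pairs, `[[`, integer(1), "kvp"),
      auto_agatston = auto_ag, ref_agatston = ref_ag,
      auto_volume = auto_vo, ref_volume = ref_vo
    ),
    truth = do.call(rbind, truth_rows)
  )
}
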