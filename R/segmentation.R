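# Classical CCTA segmentation stack: Gaussian-mixture intensity modelling by
# EM, an attenuation-window remap that standardises the contrast blood pool,
# multi-scale Hessian (Frangi) vesselness, ascending-aorta detection by
# per-slice circular-component analysis, hysteresis + aorta-seeded coronary
# segmentation, and the aorta-derived calibration factor. These classical
# operators carry the same I/O and failure contracts as the trained networks
# used in the original clinical software, which are not distributable.

#' Fit a Gaussian mixture to the volume's HU histogram by EM
#'
#' One-dimensional EM on a seeded subsample of voxel values, initialised by
#' k-means. Components are reported sorted by mean and mapped to tissue
#' classes (air/lung, soft tissue, contrast blood pool, calcium/bone) by
#' their mean attenuation.
#'
#' @param vol a [voxel_volume()] with at least 1000 voxels.
#' @param k number of components (1..6).
#' @param seed RNG seed for the subsample and initialisation.
#' @param subsample maximum number of voxels used for fitting.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return object of class `gmm_model` with `mean`, `sd`, `weight`,
#'   `class` (per component), `loglik` trace and `converged` flag.
#' @export
fit_gmm_em <- function(vol, k = 4L, seed = 1L, subsample = 1e5,
                       max_iter = 200L, tol = 1e-6) {
  if (k < 1L || k > 6L) stop_cac("k must be in 1..6", "cac_parameter_error")
  x <- as.numeric(vol$data)
  if (length(x) < 1000L) stop_cac("volume too small for mixture fitting", "cac_input_error")
  set.seed(seed)
  if (length(x) > subsample) x <- sample(x, subsample)
  n <- length(x)
  if (k == 1L || stats::sd(x) == 0) {
    m <- mean(x); s <- max(stats::sd(x), 1e-3)
    mod <- list(mean = rep(m, k), sd = rep(s, k),
                weight = c(1, rep(0, k - 1L)),
                loglik = sum(stats::dnorm(x, m, s, log = TRUE)),
                converged = TRUE)
    return(finish_gmm(mod))
  }
  km <- suppressWarnings(stats::kmeans(x, centers = k, nstart = 3L, iter.max = 30L))
  mu <- as.numeric(km$centers)
  sg <- vapply(seq_len(k), function(j) {
    s <- stats::sd(x[km$cluster == j])
    if (!is.finite(s) || s < 1e-3) 1e-3 else s
  }, numeric(1))
  w <- as.numeric(tabulate(km$cluster, k)) / n
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) w[j] * stats::dnorm(x, mu[j], sg[j]),
                   numeric(n))
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    resp <- dens / tot
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * x) / pmax(nk, 1e-12)
    sg <- sqrt(colSums(resp * (outer(x, mu, `-`))^2) / pmax(nk, 1e-12))
    sg <- pmax(sg, 1e-3)
    if (is.finite(ll_old) && ll - ll_old < tol * abs(ll)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged) {
    warning("EM did not converge within the iteration cap; returning best model",
            call. = FALSE)
  }
  finish_gmm(list(mean = mu, sd = sg, weight = w, loglik = ll_trace,
                  converged = converged))
}

# Sort components by mean and attach tissue-class semantics.
finish_gmm <- function(mod) {
  o <- order(mod$mean)
  mod$mean <- mod$mean[o]; mod$sd <- mod$sd[o]; mod$weight <- mod$weight[o]
  mod$class <- vapply(mod$mean, function(m) {
    if (m < -200) "air/lung"
    else if (m < 150) "soft tissue"
    else if (m < 800) "contrast blood pool"
    else "calcium/bone"
  }, character(1))
  structure(mod, class = "gmm_model")
}

#' @export
print.gmm_model <- function(x, ...) {
  cat("<gmm_model>\n")
  for (j in seq_along(x$mean)) {
    cat(sprintf("  %-20s mean %8.1f HU, sd %7.1f, weight %.3f\n",
                x$class[j], x$mean[j], x$sd[j], x$weight[j]))
  }
  invisible(x)
}

# Working level the remap sends the contrast blood pool to (HU).
BLOOD_POOL_WORKING_LEVEL <- 400

#' Standardise the attenuation window of a contrast-enhanced volume
#'
#' A monotone piecewise-linear intensity remap that sends the fitted
#' contrast-blood-pool mean to a fixed working level (400 HU) and compresses
#' attenuation below the soft-tissue level, so that downstream vesselness
#' thresholds see a comparable blood pool regardless of tube voltage or
#' contrast protocol. The mapping is invertible on the blood-pool range.
#'
#' @param vol a contrast-enhanced [voxel_volume()].
#' @param model a [fit_gmm_em()] model of `vol`.
#' @return a preprocessed [voxel_volume()].
#' @export
optimize_attenuation_window <- function(vol, model) {
  blood <- which(model$mean >= 150 & model$mean <= 800 & model$weight > 1e-4)
  if (!length(blood)) {
    stop_cac("no contrast blood pool component found (non-contrast input?)",
             "cac_calibration_error")
  }
  m_b <- model$mean[blood[which.max(model$weight[blood])]]
  soft <- which(model$class == "soft tissue" & model$weight > 1e-4)
  m_s <- if (length(soft)) model$mean[soft[which.max(model$weight[soft])]] else 40
  s_hi <- (BLOOD_POOL_WORKING_LEVEL - m_s) / max(m_b - m_s, 1)
  v <- vol$data
  out <- ifelse(v <= m_s, m_s + (v - m_s) * 0.5, m_s + (v - m_s) * s_hi)
  out <- clamp(out, HU_MIN, HU_MAX)
  res <- vol
  res$data <- out
  attr(res, "remap") <- list(m_s = m_s, m_b = m_b, slope_low = 0.5, slope_high = s_hi,
                             working_level = BLOOD_POOL_WORKING_LEVEL)
  res
}

#' Multi-scale Hessian (Frangi) vesselness
#'
#' Bright-tube vesselness in [0, 1]: at each scale the Gaussian-smoothed
#' Hessian is decomposed into eigenvalues |l1| <= |l2| <= |l3|; the response
#' combines the plate-vs-line ratio, the blob ratio and second-order
#' structure, is zero where l2 or l3 is positive (dark or ridge-like
#' structure), and the map takes the maximum over scales.
#'
#' @param vol a (preprocessed) [voxel_volume()].
#' @param scales_mm Gaussian scales in mm covering the expected lumen radii.
#' @param alpha,beta Frangi ratio sensitivities.
#' @return numeric 3D array of vesselness scores in [0, 1].
#' @export
vesselness <- function(vol, scales_mm = c(1.0, 1.6), alpha = 0.5, beta = 0.5) {
  v <- vol$data
  out <- array(0, dim(v))
  for (s in scales_mm) {
    sig_vox <- s / vol$spacing
    hxx <- gauss_deriv(v, sig_vox, vol$spacing, c(2L, 0L, 0L)) * s^2
    hyy <- gauss_deriv(v, sig_vox, vol$spacing, c(0L, 2L, 0L)) * s^2
    hzz <- gauss_deriv(v, sig_vox, vol$spacing, c(0L, 0L, 2L)) * s^2
    hxy <- gauss_deriv(v, sig_vox, vol$spacing, c(1L, 1L, 0L)) * s^2
    hxz <- gauss_deriv(v, sig_vox, vol$spacing, c(1L, 0L, 1L)) * s^2
    hyz <- gauss_deriv(v, sig_vox, vol$spacing, c(0L, 1L, 1L)) * s^2
    ev <- eig_sym3(hxx, hyy, hzz, hxy, hxz, hyz)
    l1 <- ev$l1; l2 <- ev$l2; l3 <- ev$l3
    a2 <- pmax(abs(l2), 1e-12); a3 <- pmax(abs(l3), 1e-12)
    ra <- a2 / a3
    rb <- abs(l1) / sqrt(a2 * a3)
    s2 <- l1^2 + l2^2 + l3^2
    cpar <- sqrt(max(s2)) / 2
    if (cpar < 1e-12) next
    resp <- (1 - exp(-ra^2 / (2 * alpha^2))) *
      exp(-rb^2 / (2 * beta^2)) *
      (1 - exp(-s2 / (2 * cpar^2)))
    resp[l2 > 0 | l3 > 0] <- 0
    out <- pmax(out, resp)
  }
  out
}

#' Segment the ascending aorta
#'
#' Per-slice detection of the largest bright, near-circular component: the
#' slice is thresholded at the blood-pool low bound from a Gaussian-mixture
#' fit, 8-connected components are screened by equivalent radius (within the
#' given band) and circularity (area over the circumscribed circle of the
#' component), and the winning component per slice (largest radius,
#' tie-break on higher median HU) is kept. Slices must agree on >= 3
#' consecutive levels; the central third of the aortic extent is returned as
#' the calibration portion, with the full extent available for seeding.
#'
#' @param vol a contrast-enhanced [voxel_volume()].
#' @param radius_band_mm admissible aorta radius range.
#' @param circularity_min minimum circularity in (0, 1].
#' @param seed RNG seed for the internal mixture fit.
#' @param model optional pre-fitted [fit_gmm_em()] model of `vol`.
#' @return a [label_mask()] with labels `aorta_mid = 1` (central third,
#'   used for calibration) and `aorta = 2` (rest of the detected extent);
#'   attribute `center_mm` holds the mean in-plane centre.
#' @export
segment_aorta <- function(vol, radius_band_mm = c(10, 25),
                          circularity_min = 0.8, seed = 11L, model = NULL) {
  if (vol$modality != "CCTA") {
    stop_cac("aorta segmentation expects a contrast-enhanced CCTA volume",
             "cac_segmentation_failure")
  }
  if (is.null(model)) model <- fit_gmm_em(vol, k = 4L, seed = seed)
  blood <- which(model$mean >= 150 & model$mean <= 800 & model$weight > 1e-4)
  if (!length(blood)) {
    stop_cac("no contrast blood pool found: aorta segmentation failed",
             "cac_segmentation_failure")
  }
  j <- blood[which.max(model$weight[blood])]
  thr <- model$mean[j] - 2.5 * model$sd[j]
  thr <- max(thr, 150)
  d <- dim(vol$data)
  pix <- vol$spacing[1] * vol$spacing[2]
  # in-plane opening radius (voxels): suppresses attached coronary ostia and
  # thin bridges before the circularity screen
  open_iter <- max(1L, round(1 / mean(vol$spacing[1:2])))
  hits <- vector("list", d[3])
  for (k in seq_len(d[3])) {
    sl <- array(vol$data[, , k] > thr, c(d[1], d[2], 1L))
    er <- !dilate_mask(!sl, iter = open_iter)
    opened <- dilate_mask(er, iter = open_iter) & sl
    lab <- label_components(opened, 26L)
    nl <- max(lab)
    if (nl == 0L) next
    best <- NULL
    for (ci in seq_len(nl)) {
      sel <- which(lab == ci, arr.ind = TRUE)[, 1:2, drop = FALSE]
      area <- nrow(sel) * pix
      r_eq <- sqrt(area / pi)
      if (r_eq < radius_band_mm[1] || r_eq > radius_band_mm[2]) next
      ctr <- colMeans(sel)
      rmax <- sqrt(max((sel[, 1] - ctr[1])^2 * vol$spacing[1]^2 +
                         (sel[, 2] - ctr[2])^2 * vol$spacing[2]^2))
      circ <- area / (pi * rmax^2)
      if (circ < circularity_min) next
      med_hu <- stats::median(vol$data[, , k][sel])
      cand <- list(sel = sel, r_eq = r_eq, circ = circ, med = med_hu, ctr = ctr)
      if (is.null(best) || cand$r_eq > best$r_eq + 1e-9 ||
          (abs(cand$r_eq - best$r_eq) <= 1e-9 && cand$med > best$med)) {
        best <- cand
      }
    }
    hits[[k]] <- best
  }
  got <- which(!vapply(hits, is.null, logical(1)))
  runs <- if (length(got)) split(got, cumsum(c(1, diff(got) != 1))) else list()
  run_len <- vapply(runs, length, integer(1))
  if (!length(runs) || max(run_len) < 3L) {
    stop_cac("no circular bright component on >= 3 consecutive slices: aorta not found",
             "cac_segmentation_failure")
  }
  span <- runs[[which.max(run_len)]]
  n_sp <- length(span)
  mid <- span[seq.int(ceiling(n_sp / 3) + 1L, length.out = max(1L, floor(n_sp / 3)))]
  data <- array(0L, d)
  for (k in span) {
    sel <- hits[[k]]$sel
    data[cbind(sel, k)] <- if (k %in% mid) 1L else 2L
  }
  ctr_vox <- colMeans(do.call(rbind, lapply(span, function(k) hits[[k]]$ctr)))
  out <- label_mask(data, vol, semantics = c(aorta_mid = 1L, aorta = 2L))
  attr(out, "center_mm") <- vol$origin[1:2] + (ctr_vox - 1) * vol$spacing[1:2]
  attr(out, "slices") <- span
  out
}

#' Segment the coronary tree from a vesselness map
#'
#' Hysteresis thresholding of the vesselness map (components of the low
#' threshold that contain at least one high-threshold voxel), followed by
#' seeding at voxels adjacent to the dilated aorta surface. Components
#' reachable from a seed are labelled coronary; other bright tubes (e.g.
#' veins) are kept as flagged candidates for the post-processing stage.
#'
#' @param vol the (preprocessed) [voxel_volume()] the map was computed on.
#' @param vmap vesselness array from [vesselness()].
#' @param aorta aorta [label_mask()] from [segment_aorta()].
#' @param th_high,th_low hysteresis thresholds on the vesselness score.
#' @param hu_min minimum HU for a vessel voxel (suppresses dark tubes).
#' @return a [label_mask()] with `coronary = 1` (aorta-connected) and
#'   `candidate = 2` (bright tubes without an ostium connection). Empty
#'   mask with a warning when no seed is found.
#' @export
segment_coronary <- function(vol, vmap, aorta, th_high = 0.30, th_low = 0.05,
                             hu_min = 150) {
  strong <- vmap >= th_high & vol$data > hu_min
  weak <- vmap >= th_low & vol$data > hu_min
  weak <- weak & !(aorta$data > 0L)
  d <- dim(vol$data)
  out <- array(0L, d)
  if (any(weak)) {
    lab <- label_components(weak, 26L)
    keep <- sort(unique(lab[strong & weak]))
    keep <- setdiff(keep, 0L)
    if (length(keep)) {
      shell <- dilate_mask(aorta$data > 0L, iter = 3L) & !(aorta$data > 0L)
      seeded <- sort(unique(lab[shell & lab > 0L]))
      seeded <- intersect(seeded, keep)
      out[lab %in% seeded] <- 1L
      out[lab %in% setdiff(keep, seeded)] <- 2L
    }
  }
  if (!any(out == 1L)) {
    warning("no coronary seed adjacent to the aorta; returning empty coronary mask",
            call. = FALSE)
  }
  label_mask(out, vol, semantics = c(coronary = 1L, candidate = 2L))
}

#' Calibration factor from the segmented aorta
#'
#' The representative coronary attenuation that drives the adaptive calcium
#' threshold and the adaptive Agatston weights. Computed as an affine
#' function `a * median(aorta HU) + b` of the median attenuation over the
#' mid-ascending aorta portion - deliberately a robust location estimate
#' with a packaged correction, not a plain mean. The packaged `(a, b)` was
#' fixed once against the phantom tuning cohort, where the aorta median
#' tracks the true lumen enhancement directly (a = 1, b = 0).
#'
#' @param vol the contrast-enhanced [voxel_volume()].
#' @param aorta [label_mask()] from [segment_aorta()].
#' @param kvp tube voltage of the acquisition.
#' @param coef affine correction `c(a, b)`.
#' @return object of class `calibration_factor` with `value`,
#'   `aorta_stats` (median, IQR, voxel count) and `kvp`.
#' @export
calibration_factor <- function(vol, aorta, kvp = vol$kvp,
                               coef = c(a = 1, b = 0)) {
  sel <- aorta$data == 1L
  if (sum(sel) < 500L) {
    stop_cac("aorta mask too small for calibration (< 500 voxels)",
             "cac_calibration_error")
  }
  hu <- vol$data[sel]
  med <- stats::median(hu)
  value <- coef[[1]] * med + coef[[2]]
  if (value <= 0 || value < 0.5 * med || value > 1.5 * med) {
    stop_cac("calibration factor outside the sanity band around the aorta median",
             "cac_calibration_error")
  }
  structure(list(value = value,
                 aorta_stats = c(median = med, iqr = stats::IQR(hu),
                                 n = sum(sel)),
                 kvp = as.integer(kvp)),
            class = "calibration_factor")
}

#' @export
print.calibration_factor <- function(x, ...) {
  cat(sprintf("<calibration_factor> %.1f HU (aorta median %.1f, IQR %.1f, n = %d) @ %d kVp\n",
              x$value, x$aorta_stats["median"], x$aorta_stats["iqr"],
              x$aorta_stats["n"], x$kvp))
  invisible(x)
}
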