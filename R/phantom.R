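# Synthetic paired CSCT/CCTA phantom of one simulated heart: an ascending
# aorta blood pool, a contrast-opacified coronary tree (two LCA branches and
# one RCA branch), a non-coronary bright tube standing in for a cardiac
# vein, soft-tissue background with a fat pocket and an air margin, and
# spherical calcified plaques whose attenuation depends on tube voltage.
# Ground truth (calcium masks, per-plaque volumes, reference scores) comes
# from the noise-free renderings.

#' Tube-voltage attenuation scale
#'
#' Multiplicative HU scale of calcium or iodine relative to the 120 kVp
#' reference, from a two-point model linear in 1/kVp fixed at
#' `scale(120) = 1` and `scale(80) = 1.55` (calcium) / `1.70` (iodine).
#' Lower tube voltage increases measured attenuation of both materials,
#' iodine more steeply than calcium - the physics that motivates the
#' aorta-derived calibration of thresholds and weights.
#'
#' @param kvp tube voltage, one of 80, 90, 100, 120.
#' @param material `"calcium"` or `"iodine"`.
#' @return dimensionless scale factor (1 at 120 kVp).
#' @export
#' @examples
#' kvp_attenuation_scale(80, "calcium")  # 1.55
kvp_attenuation_scale <- function(kvp, material = c("calcium", "iodine")) {
  material <- match.arg(material)
  if (!kvp %in% c(80L, 90L, 100L, 120L)) {
    stop_cac("kvp must be one of 80, 90, 100, 120", "cac_parameter_error")
  }
  slope <- if (material == "calcium") KVP_SLOPE_CALCIUM else KVP_SLOPE_IODINE
  1 + slope * (1 / kvp - 1 / 120)
}

# 1/kVp slopes fixed so that scale(80) = 1.55 (calcium) and 1.70 (iodine);
# shared by the renderer and the adaptive weight map.
KVP_SLOPE_CALCIUM <- 0.55 / (1 / 80 - 1 / 120)  # = 132
KVP_SLOPE_IODINE <- 0.70 / (1 / 80 - 1 / 120)   # = 168

#' Default heart geometry of the phantom
#'
#' A 45 x 45 x 36 mm field of view holding a 15 mm-radius ascending aorta,
#' three coronary branches (LCA main, LCA diagonal, RCA) leaving the aorta
#' surface at mid-height, a free-floating bright tube emulating a cardiac
#' vein (deliberately not connected to an ostium, to exercise mislabel
#' removal), a fat pocket and an air margin. Coordinates in mm.
#'
#' @return list describing aorta, branches, vein, fat and air structures.
#' @export
default_heart_geometry <- function() {
  list(
    fov_mm = c(45, 45, 36),
    aorta = list(center = c(29, 29), radius = 15, blood_hu = 40),
    branches = list(
      LCA_main = list(
        label = "LCA", lumen_radius = 1.4,
        points = rbind(c(14, 29, 18), c(10, 26, 17.5), c(7, 20, 16),
                       c(6, 14, 13), c(6, 9, 9), c(7, 5, 4))
      ),
      LCA_diag = list(
        label = "LCA", lumen_radius = 1.2,
        points = rbind(c(14, 29, 18), c(10, 26, 17.5), c(7, 20, 16),
                       c(5.5, 18, 20), c(4.5, 17, 25), c(5, 17, 30))
      ),
      RCA = list(
        label = "RCA", lumen_radius = 1.35,
        points = rbind(c(29, 14, 18), c(26, 10, 19), c(20, 7, 21),
                       c(14, 6, 24), c(9, 7, 28), c(6, 10, 32))
      )
    ),
    vein = list(points = rbind(c(10, 35, 4), c(10, 35, 32)), radius = 1.5,
                enhances = TRUE),
    fat = list(center = c(36, 8, 18), radius = 6, hu = -80),
    air_slab_x_mm = 1.5,
    soft_tissue_hu = 40
  )
}

#' Phantom specification
#'
#' Everything needed to render one deterministic paired CSCT/CCTA study.
#' Plaques are spheres placed at an arc-length position along a named branch
#' with an intrinsic calcium density index `d` in [0, 1] that maps to a base
#' attenuation `130 + 770 d` HU at 120 kVp, so the density range spans all
#' four Agatston weight bins.
#'
#' @param seed integer RNG seed; fixed seed gives bit-identical volumes.
#' @param kvp CCTA tube voltage (the CSCT arm is always acquired at
#'   120 kVp, mirroring the fixed calcium-scoring protocol).
#' @param plaques data.frame with columns `branch` (name in the geometry),
#'   `s_mm` (arc-length position), `radius_mm`, `density`.
#' @param contrast_hu_mean lumen/aorta enhancement in HU at 120 kVp.
#' @param noise_sd additive Gaussian noise, HU.
#' @param in_plane_mm in-plane voxel size (both modalities).
#' @param geometry a heart geometry, see [default_heart_geometry()].
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L, kvp = 120L,
                         plaques = data.frame(branch = character(),
                                              s_mm = numeric(),
                                              radius_mm = numeric(),
                                              density = numeric()),
                         contrast_hu_mean = 400, noise_sd = 15,
                         in_plane_mm = 0.5,
                         geometry = default_heart_geometry()) {
  if (!kvp %in% c(80L, 90L, 100L, 120L)) {
    stop_cac("kvp must be one of 80, 90, 100, 120", "cac_parameter_error")
  }
  plaques <- as.data.frame(plaques)
  if (nrow(plaques)) {
    if (!all(plaques$branch %in% names(geometry$branches))) {
      stop_cac("plaque declared on an unknown branch", "cac_spec_error")
    }
    if (any(plaques$radius_mm <= 0)) stop_cac("plaque radius must be > 0", "cac_spec_error")
    if (any(plaques$density < 0 | plaques$density > 1)) {
      stop_cac("plaque density index must lie in [0, 1]", "cac_spec_error")
    }
  }
  structure(list(seed = as.integer(seed), kvp = as.integer(kvp),
                 plaques = plaques, contrast_hu_mean = contrast_hu_mean,
                 noise_sd = noise_sd, in_plane_mm = in_plane_mm,
                 geometry = geometry),
            class = "phantom_spec")
}

# Densely resample a polyline with a natural cubic spline in its arc-length
# parameter; returns points every `step` mm plus the total length.
resample_polyline <- function(points, step = 0.5) {
  seg <- sqrt(rowSums(diff(points)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  t <- seq(0, L, by = step)
  if (t[length(t)] < L) t <- c(t, L)
  out <- sapply(1:3, function(j) {
    if (nrow(points) > 2) {
      stats::spline(s, points[, j], xout = t, method = "natural")$y
    } else {
      stats::approx(s, points[, j], xout = t)$y
    }
  })
  list(points = out, length = L, s = t)
}

# Arc-length position along a branch -> centre point (mm).
branch_point <- function(branch, s_mm) {
  rp <- resample_polyline(branch$points, 0.25)
  s <- clamp(s_mm, 0, rp$length)
  i <- which.min(abs(rp$s - s))
  rp$points[i, ]
}

# Geometry of a rendering grid for one modality.
render_grid <- function(spec, modality) {
  fov <- spec$geometry$fov_mm
  dz <- if (modality == "CSCT") 3 else 0.75
  dxy <- spec$in_plane_mm
  dims <- c(round(fov[1] / dxy), round(fov[2] / dxy), round(fov[3] / dz))
  spacing <- c(dxy, dxy, dz)
  list(dims = as.integer(dims), spacing = spacing, origin = spacing / 2,
       modality = modality)
}

# Partial-volume occupancy of a tube around a polyline, computed on a
# z-supersampled distance field restricted to per-segment bounding boxes.
# Returns a full-size occupancy array in [0, 1].
tube_occupancy <- function(grid, points, radius, step = 1) {
  d <- grid$dims; sp <- grid$spacing; or <- grid$origin
  fz <- max(1L, ceiling(sp[3] / 0.75))
  dzs <- sp[3] / fz
  rp <- resample_polyline(points, step)
  P <- rp$points
  w <- mean(sp[1:2])
  margin <- radius + w + dzs
  nzs <- d[3] * fz
  xs <- or[1] + (seq_len(d[1]) - 1) * sp[1]
  ys <- or[2] + (seq_len(d[2]) - 1) * sp[2]
  zs <- or[3] - sp[3] / 2 + (seq_len(nzs) - 0.5) * dzs
  dist <- array(Inf, c(d[1], d[2], nzs))
  for (i in seq_len(nrow(P) - 1)) {
    a <- P[i, ]; b <- P[i + 1, ]
    lo <- pmin(a, b) - margin; hi <- pmax(a, b) + margin
    ix <- which(xs >= lo[1] & xs <= hi[1])
    iy <- which(ys >= lo[2] & ys <= hi[2])
    iz <- which(zs >= lo[3] & zs <= hi[3])
    if (!length(ix) || !length(iy) || !length(iz)) next
    g <- expand.grid(x = xs[ix], y = ys[iy], z = zs[iz])
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 > 0) {
      ((g$x - a[1]) * ab[1] + (g$y - a[2]) * ab[2] + (g$z - a[3]) * ab[3]) / len2
    } else rep(0, nrow(g))
    t <- clamp(t, 0, 1)
    dd <- sqrt((g$x - (a[1] + t * ab[1]))^2 + (g$y - (a[2] + t * ab[2]))^2 +
                 (g$z - (a[3] + t * ab[3]))^2)
    cur <- dist[ix, iy, iz]
    dist[ix, iy, iz] <- pmin(cur, array(dd, dim(cur)))
  }
  alpha <- clamp((radius - dist) / w + 0.5, 0, 1)
  if (fz > 1L) {
    # box-average the z-supersamples back onto the slice grid
    dim(alpha) <- c(d[1] * d[2], fz, d[3])
    alpha <- apply(alpha, c(1, 3), mean)
    dim(alpha) <- d
  }
  alpha
}

# Occupancy of a sphere by supersampled subvoxel counting (4x in plane, and
# enough z subdivisions to reach <= 0.25 mm), restricted to its bounding box.
sphere_occupancy <- function(grid, center, radius) {
  d <- grid$dims; sp <- grid$spacing; or <- grid$origin
  f <- c(4L, 4L, max(4L, ceiling(sp[3] / 0.25)))
  alpha <- array(0, d)
  ilo <- pmax(1L, floor((center - radius - or) / sp) + 1L)
  ihi <- pmin(d, ceiling((center + radius - or) / sp) + 1L)
  if (any(ilo > ihi)) return(alpha)
  offs <- lapply(1:3, function(ax) ((seq_len(f[ax]) - 0.5) / f[ax] - 0.5) * sp[ax])
  ix <- ilo[1]:ihi[1]; iy <- ilo[2]:ihi[2]; iz <- ilo[3]:ihi[3]
  cx <- or[1] + (ix - 1) * sp[1]; cy <- or[2] + (iy - 1) * sp[2]
  cz <- or[3] + (iz - 1) * sp[3]
  sub <- expand.grid(dx = offs[[1]], dy = offs[[2]], dz = offs[[3]])
  g <- expand.grid(x = cx, y = cy, z = cz)
  inside <- numeric(nrow(g))
  for (s in seq_len(nrow(sub))) {
    inside <- inside + as.numeric(
      (g$x + sub$dx[s] - center[1])^2 + (g$y + sub$dy[s] - center[2])^2 +
        (g$z + sub$dz[s] - center[3])^2 <= radius^2
    )
  }
  alpha[ix, iy, iz] <- array(inside / nrow(sub), c(length(ix), length(iy), length(iz)))
  alpha
}

# Render one modality; returns the noise-free HU array, the per-plaque
# calcium occupancy list and the grid description.
render_modality <- function(spec, modality) {
  geo <- spec$geometry
  grid <- render_grid(spec, modality)
  d <- grid$dims
  s_io <- if (modality == "CCTA") kvp_attenuation_scale(spec$kvp, "iodine") else NA
  s_ca <- if (modality == "CCTA") kvp_attenuation_scale(spec$kvp, "calcium") else 1
  lumen_hu <- if (modality == "CCTA") spec$contrast_hu_mean * s_io else geo$aorta$blood_hu

  v <- array(geo$soft_tissue_hu, d)
  xs <- grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1]
  # air margin outside the body
  n_air <- sum(xs <= geo$air_slab_x_mm)
  if (n_air > 0) v[seq_len(n_air), , ] <- -1000
  # fat pocket
  af <- sphere_occupancy(grid, geo$fat$center, geo$fat$radius)
  v <- v * (1 - af) + geo$fat$hu * af
  # ascending aorta: vertical cylinder, in-plane analytic partial volume
  ys <- grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2]
  dxy <- sqrt(outer((xs - geo$aorta$center[1])^2, (ys - geo$aorta$center[2])^2, `+`))
  aa <- clamp((geo$aorta$radius - dxy) / mean(grid$spacing[1:2]) + 0.5, 0, 1)
  aa <- array(rep(aa, d[3]), d)
  v <- v * (1 - aa) + lumen_hu * aa
  # coronary branches
  for (br in geo$branches) {
    ab <- tube_occupancy(grid, br$points, br$lumen_radius)
    v <- v * (1 - ab) + lumen_hu * ab
  }
  # vein surrogate: enhances like the blood pool on CCTA, blood on CSCT
  vein_hu <- if (modality == "CCTA" && isTRUE(geo$vein$enhances)) lumen_hu else geo$aorta$blood_hu
  av <- tube_occupancy(grid, geo$vein$points, geo$vein$radius)
  v <- v * (1 - av) + vein_hu * av
  # calcified plaques, rendered last so they displace lumen contrast
  plaque_occ <- list()
  if (nrow(spec$plaques)) {
    for (p in seq_len(nrow(spec$plaques))) {
      pl <- spec$plaques[p, ]
      ctr <- branch_point(geo$branches[[pl$branch]], pl$s_mm)
      if (any(ctr - pl$radius_mm < 0) ||
          any(ctr + pl$radius_mm > geo$fov_mm)) {
        stop_cac(sprintf("plaque %d extends outside the phantom grid", p),
                 "cac_spec_error")
      }
      ap <- sphere_occupancy(grid, ctr, pl$radius_mm)
      hu_ca <- (130 + pl$density * 770) * s_ca
      v <- v * (1 - ap) + hu_ca * ap
      plaque_occ[[p]] <- ap
    }
  }
  list(hu = v, grid = grid, plaque_occ = plaque_occ)
}

#' Render a paired CSCT/CCTA study with ground truth
#'
#' Renders the same simulated heart twice: a non-contrast calcium-scoring CT
#' at 120 kVp with 3 mm slices, and a contrast-enhanced CCTA at the spec's
#' tube voltage with 0.75 mm slices. Calcium attenuation scales with kVp via
#' [kvp_attenuation_scale()]; lumen and aorta enhancement scales with the
#' iodine factor. Ground truth comes from the noise-free renderings: the
#' calcium masks (occupancy >= 0.5), per-plaque volumes and vessel labels,
#' and the reference Agatston/volume scores obtained by running the standard
#' scorer on the noise-free CSCT rendering.
#'
#' @param spec a [phantom_spec()].
#' @return list with `csct`, `ccta` (both [voxel_volume()]) and `truth`.
#' @export
render_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  rc <- render_modality(spec, "CSCT")
  ra <- render_modality(spec, "CCTA")

  truth_of <- function(r, vol) {
    occ_tot <- array(0, r$grid$dims)
    for (a in r$plaque_occ) occ_tot <- pmax(occ_tot, a)
    mask <- label_mask(array(as.integer(occ_tot >= 0.5), r$grid$dims), vol,
                       semantics = c(calcium = 1L))
    per_plaque <- vapply(r$plaque_occ, function(a) {
      sum(a >= 0.5) * prod(r$grid$spacing)
    }, numeric(1))
    list(mask = mask, per_plaque_mm3 = per_plaque)
  }

  mkvol <- function(r, kvp, noise_seed) {
    hu <- r$hu
    if (spec$noise_sd > 0) {
      set.seed(noise_seed %% .Machine$integer.max)
      hu <- hu + array(stats::rnorm(length(hu), 0, spec$noise_sd), dim(hu))
    }
    suppressWarnings(voxel_volume(hu, r$grid$spacing, r$grid$origin,
                                  modality = r$grid$modality, kvp = kvp))
  }

  csct <- mkvol(rc, 120L, (spec$seed %% 1073741823L) * 2L + 1L)
  ccta <- mkvol(ra, spec$kvp, (spec$seed %% 1073741823L) * 2L + 2L)

  csct_nf <- suppressWarnings(voxel_volume(rc$hu, rc$grid$spacing, rc$grid$origin,
                                           modality = "CSCT", kvp = 120L))
  tc <- truth_of(rc, csct_nf)
  ta <- truth_of(ra, ccta)

  # reference scores from the noise-free CSCT rendering, with lesion vessels
  # assigned from the nearest plaque
  ref <- score_csct(csct_nf)
  plaque_centers <- if (nrow(spec$plaques)) {
    t(vapply(seq_len(nrow(spec$plaques)), function(p) {
      branch_point(spec$geometry$branches[[spec$plaques$branch[p]]],
                   spec$plaques$s_mm[p])
    }, numeric(3)))
  } else matrix(numeric(0), 0, 3)
  plaque_vessel <- if (nrow(spec$plaques)) {
    vapply(spec$plaques$branch, function(b) spec$geometry$branches[[b]]$label,
           character(1))
  } else character(0)
  if (length(ref$lesions) && nrow(plaque_centers)) {
    ref$lesions <- lapply(ref$lesions, function(l) {
      ctr <- colMeans(index_to_mm(csct_nf, l$voxels))
      dd <- sqrt(rowSums(sweep(plaque_centers, 2, ctr)^2))
      l$vessel <- plaque_vessel[which.min(dd)]
      l
    })
    ref <- c(list(lesions = ref$lesions),
             score_csct_from_lesions(ref$lesions, csct_nf))
  }

  truth <- list(
    calcium_csct = tc$mask, calcium_ccta = ta$mask,
    per_plaque_mm3_csct = tc$per_plaque_mm3,
    per_plaque_mm3_ccta = ta$per_plaque_mm3,
    plaque_vessel = plaque_vessel,
    plaque_centers = plaque_centers,
    agatston_ref = ref$agatston, volume_ref = ref$volume
  )
  list(csct = csct, ccta = ccta, truth = truth)
}

# Re-aggregate per-vessel scores after lesion vessel assignment.
score_csct_from_lesions <- function(lesions, vol, params = agatston_params()) {
  groups <- c("LCA", "RCA", "unassigned")
  ag <- stats::setNames(numeric(3), groups)
  vo <- stats::setNames(numeric(3), groups)
  for (l in lesions) {
    g <- if (l$vessel %in% groups) l$vessel else "unassigned"
    ag[g] <- ag[g] + agatston_score(list(l), params, vol$spacing[3])
    vo[g] <- vo[g] + volume_score(list(l), vol)
  }
  list(agatston = c(ag, total = sum(ag)), volume = c(vo, total = sum(vo)))
}

# Plaque recipes per intended risk stratum; sizes and densities chosen so
# the reference Agatston score of the stratum lands near the centre of its
# bin (counts x radius x density increase with stratum; densities are high,
# as clinically scored plaques are, so plaques remain visible above the
# contrast-enhanced lumen).
COHORT_RECIPES <- list(
  list(n = 0L, radius = NA, density = NA),
  list(n = 1L, radius = 0.8, density = 0.70),
  list(n = 2L, radius = 1.4, density = 0.80),
  list(n = 4L, radius = 1.9, density = 0.85),
  list(n = 8L, radius = 2.4, density = 0.90)
)

#' Deterministic phantom cohort
#'
#' Generates `n` phantom specs cycling through the five risk strata (so
#' every risk category including zero calcium is represented for n >= 5),
#' with tube voltages allocated deterministically in the proportions
#' 80 kVp : 100 kVp : 120 kVp = 25% : 69% : 6% observed clinically, and
#' seeded jitter of plaque size, density and position.
#'
#' @param n number of subjects (>= 1).
#' @param seed integer RNG seed.
#' @return list of [phantom_spec()] objects.
#' @export
default_cohort <- function(n, seed = 1L) {
  if (n < 1L) stop_cac("cohort size must be >= 1", "cac_parameter_error")
  set.seed(seed)
  subj_seeds <- sample.int(.Machine$integer.max - 10L, n)
  # deterministic kVp allocation in the target proportions
  kvp_pool <- rep(c(80L, 100L, 120L), times = pmax(1L, round(n * c(0.25, 0.69, 0.06))))
  kvp_pool <- kvp_pool[seq_len(min(n, length(kvp_pool)))]
  if (length(kvp_pool) < n) kvp_pool <- c(kvp_pool, rep(100L, n - length(kvp_pool)))
  kvps <- sample(kvp_pool, n)
  strata <- rep(0:4, length.out = n)
  geo <- default_heart_geometry()
  # available plaque slots: arc positions spaced along each branch
  slots <- do.call(rbind, lapply(names(geo$branches), function(b) {
    L <- resample_polyline(geo$branches[[b]]$points, 0.5)$length
    s <- seq(5, L - 5, by = 7)
    data.frame(branch = b, s_mm = s, stringsAsFactors = FALSE)
  }))
  lapply(seq_len(n), function(i) {
    rec <- COHORT_RECIPES[[strata[i] + 1L]]
    set.seed(subj_seeds[i])
    plaques <- if (rec$n > 0L) {
      pick <- slots[sample.int(nrow(slots), rec$n), ]
      data.frame(
        branch = pick$branch,
        s_mm = pick$s_mm + stats::runif(rec$n, -1.5, 1.5),
        radius_mm = rec$radius * stats::runif(rec$n, 0.92, 1.08),
        density = clamp(rec$density * stats::runif(rec$n, 0.92, 1.08), 0, 1)
      )
    } else {
      data.frame(branch = character(), s_mm = numeric(),
                 radius_mm = numeric(), density = numeric())
    }
    phantom_spec(seed = subj_seeds[i], kvp = kvps[i], plaques = plaques,
                 geometry = geo)
  })
}
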