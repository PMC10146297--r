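# Shared fixture builders. Everything is generated in code at test time;
# expensive renders are cached for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Small uniform volume with selected voxels overridden.
make_vol <- function(dims = c(8, 8, 4), spacing = c(0.5, 0.5, 3), hu = 40,
                     modality = "CSCT", kvp = 120) {
  voxel_volume(array(hu, dims), spacing = spacing, modality = modality, kvp = kvp)
}

# Straight cylinder of the given radius along the z axis, partial-volume
# rasterised, centred in the grid.
cylinder_vol <- function(radius_mm = 1.5, hu = 400, bg = 40,
                         dims = c(40, 40, 40), spacing = c(0.5, 0.5, 0.5),
                         modality = "CCTA") {
  origin <- spacing / 2
  ctr <- origin[1:2] + (dims[1:2] - 1) * spacing[1:2] / 2
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  d2 <- sqrt(outer((xs - ctr[1])^2, (ys - ctr[2])^2, `+`))
  alpha <- pmin(pmax((radius_mm - d2) / mean(spacing[1:2]) + 0.5, 0), 1)
  v <- array(rep(bg * (1 - alpha) + hu * alpha, dims[3]), dims)
  voxel_volume(v, spacing = spacing, origin = origin, modality = modality)
}

# One rendered phantom pair with two plaques, shared across tests.
phantom_fixture <- function() {
  cached("phantom_pair", {
    spec <- phantom_spec(
      seed = 42L, kvp = 100L,
      plaques = data.frame(branch = c("LCA_main", "RCA"), s_mm = c(12, 15),
                           radius_mm = c(2.0, 1.5), density = c(0.9, 0.8))
    )
    render_pair(spec)
  })
}

# Pipeline detail objects for the shared phantom.
pipeline_fixture <- function() {
  cached("pipeline_detail", {
    pair <- phantom_fixture()
    rep <- run_ccta_pipeline(pair$ccta, pipeline_config())
    list(pair = pair, report = rep, detail = attr(rep, "detail"))
  })
}

# Independent brute-force reference scorer used as the oracle for the
# Agatston/volume implementation. Deliberately avoids connected-component
# shortcuts: per-slice labels are found by iterative label propagation over
# pixel pairs, and both scores are accumulated slice by slice (the Agatston
# sum and the total calcium volume are slice-additive, so no 3D merging is
# needed).
brute_force_scores <- function(vol, hu_thr = 130, min_area = 1) {
  d <- dim(vol$data)
  pix <- vol$spacing[1] * vol$spacing[2]
  thick <- vol$spacing[3]
  total_ag <- 0
  total_vox <- 0L
  weight_of <- function(p) {
    if (p >= 400) 4 else if (p >= 300) 3 else if (p >= 200) 2 else 1
  }
  for (k in seq_len(d[3])) {
    sl <- vol$data[, , k]
    lab <- matrix(0L, d[1], d[2])
    lab[sl > hu_thr] <- seq_len(sum(sl > hu_thr))
    repeat {
      changed <- FALSE
      for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
        if (lab[i, j] == 0L) next
        for (di in -1:1) for (dj in -1:1) {
          ii <- i + di; jj <- j + dj
          if (ii < 1 || jj < 1 || ii > d[1] || jj > d[2]) next
          if (lab[ii, jj] > 0L && lab[ii, jj] < lab[i, j]) {
            lab[i, j] <- lab[ii, jj]
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    for (id in setdiff(unique(as.vector(lab)), 0L)) {
      sel <- lab == id
      area <- sum(sel) * pix
      if (area > min_area) {
        total_ag <- total_ag + area * weight_of(max(sl[sel])) * thick / 3
        total_vox <- total_vox + sum(sel)
      }
    }
  }
  list(agatston = total_ag, volume = total_vox * prod(vol$spacing))
}

# Random sparse-blob test grid for the oracle comparison.
random_lesion_vol <- function(seed, dims = c(32, 32, 4)) {
  set.seed(seed)
  v <- array(50, dims)
  n_blob <- sample(2:5, 1)
  for (b in seq_len(n_blob)) {
    c0 <- c(sample(4:(dims[1] - 3), 1), sample(4:(dims[2] - 3), 1),
            sample(seq_len(dims[3]), 1))
    r <- stats::runif(1, 0.8, 2.5)
    hu <- stats::runif(1, 120, 600)
    for (i in max(1, c0[1] - 5):min(dims[1], c0[1] + 5)) {
      for (j in max(1, c0[2] - 5):min(dims[2], c0[2] + 5)) {
        dd <- sqrt((i - c0[1])^2 + (j - c0[2])^2) * 0.5
        if (dd <= r) v[i, j, c0[3]] <- max(v[i, j, c0[3]], hu * (1 - 0.3 * dd / r))
      }
    }
  }
  v <- v + array(stats::rnorm(prod(dims), 0, 10), dims)
  suppressWarnings(voxel_volume(v, spacing = c(0.5, 0.5, 3), modality = "CSCT"))
}
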