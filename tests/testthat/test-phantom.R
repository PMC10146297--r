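# Synthetic paired CSCT/CCTA phantom generator.

test_that("kvp attenuation scale follows the declared two-point model", {
  expect_equal(kvp_attenuation_scale(120, "calcium"), 1.0)
  expect_equal(kvp_attenuation_scale(120, "iodine"), 1.0)
  expect_equal(kvp_attenuation_scale(80, "calcium"), 1.55)
  expect_equal(kvp_attenuation_scale(80, "iodine"), 1.70)
  # monotone decreasing in kvp, iodine steeper than calcium
  for (mat in c("calcium", "iodine")) {
    s <- vapply(c(80, 90, 100, 120), kvp_attenuation_scale, numeric(1), mat)
    expect_true(all(diff(s) < 0))
  }
  s90 <- kvp_attenuation_scale(90, "iodine")
  expect_lt(s90, kvp_attenuation_scale(80, "iodine"))
  expect_gt(s90, kvp_attenuation_scale(100, "iodine"))
  expect_gt(kvp_attenuation_scale(80, "iodine"),
            kvp_attenuation_scale(80, "calcium"))
  expect_error(kvp_attenuation_scale(110, "calcium"), class = "cac_parameter_error")
})

test_that("phantom spec validates plaque declarations", {
  expect_error(phantom_spec(plaques = data.frame(branch = "nope", s_mm = 5,
                                                 radius_mm = 1, density = 0.5)),
               class = "cac_spec_error")
  expect_error(phantom_spec(plaques = data.frame(branch = "RCA", s_mm = 5,
                                                 radius_mm = -1, density = 0.5)),
               class = "cac_spec_error")
  expect_error(phantom_spec(plaques = data.frame(branch = "RCA", s_mm = 5,
                                                 radius_mm = 1, density = 1.5)),
               class = "cac_spec_error")
})

test_that("zero-plaque spec renders calcium-free truth", {
  pair <- render_pair(phantom_spec(seed = 3, noise_sd = 0))
  expect_equal(sum(pair$truth$calcium_csct$data), 0L)
  expect_equal(sum(pair$truth$calcium_ccta$data), 0L)
  expect_equal(pair$truth$agatston_ref[["total"]], 0)
  expect_equal(pair$truth$volume_ref[["total"]], 0)
  # acquisition geometry of the two arms
  expect_equal(pair$csct$spacing[3], 3)
  expect_equal(pair$ccta$spacing[3], 0.75)
  expect_equal(pair$csct$kvp, 120L)
})

test_that("rendering is deterministic for a fixed seed", {
  spec <- phantom_spec(seed = 9, kvp = 100,
                       plaques = data.frame(branch = "RCA", s_mm = 10,
                                            radius_mm = 1.5, density = 0.7))
  p1 <- render_pair(spec)
  p2 <- render_pair(spec)
  expect_identical(p1$csct$data, p2$csct$data)
  expect_identical(p1$ccta$data, p2$ccta$data)
})

test_that("rasterised sphere volume matches the analytic volume", {
  spec <- phantom_spec(seed = 7, kvp = 120, noise_sd = 0,
                       plaques = data.frame(branch = "LCA_main", s_mm = 12,
                                            radius_mm = 2.0, density = 1.0))
  pair <- render_pair(spec)
  vv <- prod(pair$ccta$spacing)
  expect_lt(abs(sum(pair$truth$per_plaque_mm3_ccta) - 4 / 3 * pi * 2^3), vv)
})

test_that("calcium attenuation increases at lower tube voltage", {
  pl <- data.frame(branch = "RCA", s_mm = 12, radius_mm = 2, density = 0.8)
  p80 <- render_pair(phantom_spec(seed = 5, kvp = 80, plaques = pl, noise_sd = 0))
  p120 <- render_pair(phantom_spec(seed = 5, kvp = 120, plaques = pl, noise_sd = 0))
  m80 <- max(p80$ccta$data)
  m120 <- max(p120$ccta$data)
  expect_gt(m80, m120)
  expect_equal(m80 / m120, 1.55, tolerance = 0.01)
})

test_that("reference scorer on the noise-free CSCT reproduces truth exactly", {
  spec <- phantom_spec(seed = 13, kvp = 100, noise_sd = 0,
                       plaques = data.frame(branch = c("LCA_main", "RCA"),
                                            s_mm = c(10, 14),
                                            radius_mm = c(1.8, 1.4),
                                            density = c(0.9, 0.6)))
  pair <- render_pair(spec)
  res <- score_csct(pair$csct)
  expect_equal(agatston_score(res$lesions, slice_thickness_mm = 3),
               pair$truth$agatston_ref[["total"]])
  expect_equal(volume_score(res$lesions, pair$csct),
               pair$truth$volume_ref[["total"]])
})

test_that("default cohort is deterministic, stratified and kvp-balanced", {
  c1 <- default_cohort(100, seed = 77)
  c2 <- default_cohort(100, seed = 77)
  expect_identical(lapply(c1, function(s) s$plaques),
                   lapply(c2, function(s) s$plaques))
  kvps <- vapply(c1, `[[`, integer(1), "kvp")
  freq <- table(factor(kvps, levels = c(80, 100, 120))) / 100
  expect_lt(abs(freq[["80"]] - 0.25), 0.05)
  expect_lt(abs(freq[["100"]] - 0.69), 0.05)
  expect_lt(abs(freq[["120"]] - 0.06), 0.05)
  # all five burden strata present for n >= 20, including zero calcium
  c20 <- default_cohort(20, seed = 3)
  n_plaques <- vapply(c20, function(s) nrow(s$plaques), integer(1))
  expect_setequal(sort(unique(n_plaques)), c(0L, 1L, 2L, 4L, 8L))
  expect_error(default_cohort(0), class = "cac_parameter_error")
})

test_that("reference category is robust to acquisition noise", {
  # re-render the CSCT arm of a small cohort with and without noise at the
  # protocol level (15 HU); the assigned risk category must agree for at
  # least 95% of subjects
  specs <- default_cohort(10, seed = 5)
  flips <- 0L
  for (s in specs) {
    r <- cacscore:::render_modality(s, "CSCT")
    vol0 <- voxel_volume(r$hu, r$grid$spacing, r$grid$origin,
                         modality = "CSCT", kvp = 120L)
    set.seed(s$seed %% 1000000L)
    vol1 <- vol0
    vol1$data <- vol1$data + array(rnorm(length(vol0$data), 0, 15),
                                   dim(vol0$data))
    a0 <- agatston_score(detect_lesions(vol0), slice_thickness_mm = 3)
    a1 <- agatston_score(detect_lesions(vol1), slice_thickness_mm = 3)
    if (classify_risk(a0) != classify_risk(a1)) flips <- flips + 1L
  }
  expect_lte(flips / 10, 0.05)
})
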