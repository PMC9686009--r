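test_that("make_phantom is deterministic and anatomically bounded", {
  sp <- phantom_spec(seed = 5)
  p1 <- make_phantom(sp); p2 <- make_phantom(sp)
  expect_identical(p1$truth$values, p2$truth$values)
  expect_identical(p1$masks$mandible$mask, p2$masks$mandible$mask)
  # without inserts nothing reaches the metal segmentation threshold
  expect_lt(max(p1$truth$values), 2500)
  expect_false(any(p1$masks$metal$mask))
  # all masks share the grid and are logical
  for (m in p1$masks) {
    expect_identical(dim(m$mask), dim(p1$truth$values))
    expect_type(m$mask, "logical")
  }
})

test_that("metal inserts paint the right area at the right HU", {
  sp <- phantom_spec(seed = 6, metal_inserts = list(
    list(position = NULL, radius = 3, material = "stainless_steel")))
  ph <- make_phantom(sp)
  area <- sum(ph$masks$metal$mask)
  expect_lt(abs(area - pi * 3^2) / (pi * 3^2), 0.2)
  # interior of the insert carries the material HU (edges are blurred)
  expect_gte(max(ph$truth$values), 3000)
  expect_error(make_phantom(phantom_spec(seed = 1, metal_inserts = list(
    list(position = c(60, 60), radius = 3, material = "titanium_alloy")))),
    "outside the head")
  expect_error(phantom_spec(metal_inserts = list(
    list(position = NULL, radius = 3, material = "gold"))), "material")
})

test_that("kV simulation reconstructs air and artifact-free soft tissue", {
  air <- image_volume(matrix(-1000, 64, 64))
  acq <- acquisition_params(n_angles = 90)
  rec <- simulate_kvct(air, acq, seed = 1)
  expect_lt(mean(abs(rec$values + 1000)), 10)
  expect_error(simulate_kvct(image_volume(matrix(0, 1, 1))$values, acq),
               "mvmar_volume")
  pr <- clean_pair()
  mae_soft <- mean(abs(pr$ct$values - clamp_hu(pr$truth)$values)[
    pr$masks$soft_tissue$mask])
  expect_lt(mae_soft, 40)
  ai <- artifact_index(pr$ct, pr$masks$soft_tissue,
                       truth = clamp_hu(pr$truth))
  expect_lt(ai, artifact_threshold_no_metal("kvct"))
})

test_that("metal drives the kV artifact index far above the no-metal level", {
  clean <- clean_pair(); metal <- steel_pair()
  ai_clean <- artifact_index(clean$ct, clean$masks$soft_tissue,
                             truth = clamp_hu(clean$truth))
  ai_metal <- artifact_index(metal$ct, metal$masks$soft_tissue,
                             metal$masks$metal, truth = clamp_hu(metal$truth))
  expect_gte(ai_metal, 5 * ai_clean)
})

test_that("MV simulation is clamped, streak-free and noisier than kV", {
  pr <- steel_pair()
  expect_lte(max(pr$mv$values), 1400)
  mv_truth <- image_volume(mv_compress_hu(clamp_hu(pr$truth)$values),
                           spacing = pr$truth$spacing, modality = "mvcbct")
  ai_mv <- artifact_index(pr$mv, pr$masks$soft_tissue, pr$masks$metal,
                          truth = mv_truth)
  expect_lt(ai_mv, artifact_threshold_no_metal("mvcbct"))
  # noise ordering in a uniform soft-tissue ROI, metal-free phantom so the
  # kV side carries no streaks, same phantom and seed for both modalities
  cl <- clean_pair()
  cl_mv_truth <- image_volume(mv_compress_hu(clamp_hu(cl$truth)$values),
                              spacing = cl$truth$spacing, modality = "mvcbct")
  oc <- mvmar:::erode_mask(cl$masks$oral_cavity$mask, 2L)
  kv_noise <- sd((cl$ct$values - clamp_hu(cl$truth)$values)[oc])
  mv_noise <- sd((cl$mv$values - cl_mv_truth$values)[oc])
  expect_gt(mv_noise, kv_noise)
})

test_that("make_dataset rounds metal counts and reproduces manifests", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  set1 <- make_dataset(4, 0.5, out_dir = d1, seed = 3, shape = c(64, 64))
  expect_length(set1, 4)
  metal_flags <- vapply(set1, function(p) p$has_metal, logical(1))
  expect_equal(sum(metal_flags), 2)   # round(4 * 0.5)
  set2 <- make_dataset(4, 0.5, out_dir = d2, seed = 3, shape = c(64, 64))
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
  # files exist and round-trip
  expect_true(file.exists(file.path(d1, "case001_ct.nii.gz")))
  back <- read_volume(file.path(d1, "case001_ct.nii.gz"), modality = "kvct")
  expect_equal(back$values, round(set1[[1]]$ct$values))
  # single metal-free case
  one <- make_dataset(1, 0, seed = 9, shape = c(64, 64))
  expect_length(one, 1)
  expect_false(one[[1]]$has_metal)
})
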