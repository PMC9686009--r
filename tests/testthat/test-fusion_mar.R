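const_vol <- function(x, n = 4, modality = "sct")
  image_volume(matrix(x, n, n), modality = modality)

test_that("fuse_p4 assigns each pixel from exactly one candidate by band", {
  sel <- image_volume(matrix(c(-100, 0, 399, 400, 600, 799, 800, 1200,
                               2000, 350, 450, 900, -1000, 399.5, 799.5, 1500),
                             4), modality = "sct")
  cands <- candidate_set(const_vol(1), const_vol(2), const_vol(3),
                         selector = sel)
  fused <- fuse_p4(cands)
  s <- sel$values
  expect_true(all(fused$values[s < 400] == 2))
  expect_true(all(fused$values[s >= 400 & s < 800] == 1))
  expect_true(all(fused$values[s >= 800] == 3))
  # degenerate fusion: identical candidates pass through
  cands2 <- candidate_set(const_vol(7), const_vol(7), const_vol(7),
                          selector = sel)
  expect_equal(fuse_p4(cands2)$values, matrix(7, 4, 4))
  expect_error(candidate_set(const_vol(1), const_vol(2, n = 5), const_vol(3)),
               "geometry")
})

test_that("fusion bands partition the HU axis exactly once per pixel", {
  set.seed(12)
  p1 <- random_volume(16, "sct", 1); p2 <- random_volume(16, "sct", 2)
  p3 <- random_volume(16, "sct", 3)
  # make candidate values pairwise distinct so provenance is unambiguous
  p2$values <- p2$values + 0.25; p3$values <- p3$values + 0.5
  fused <- fuse_p4(candidate_set(p1, p2, p3, selector = "p3"))
  s <- p3$values
  from <- (fused$values == p1$values) + (fused$values == p2$values) +
          (fused$values == p3$values)
  expect_true(all(from == 1 | (s >= 800 & fused$values == p3$values)))
  expect_true(all((s < 400) + (s >= 400 & s < 800) + (s >= 800) == 1))
  expect_equal(fused$values[s < 400], p2$values[s < 400])
  expect_equal(fused$values[s >= 400 & s < 800], p1$values[s >= 400 & s < 800])
  expect_equal(fused$values[s >= 800], p3$values[s >= 800])
})

test_that("segment_metal takes the intersection of the dual thresholds", {
  ct <- image_volume(matrix(c(3000, 3000, 2000, 2501, 2500, 2499), 2),
                     modality = "kvct")
  mv <- image_volume(matrix(c(500, 100, 500, 301, 500, 500), 2),
                     modality = "mvcbct")
  m <- segment_metal(ct, mv)
  expect_identical(as.vector(m$mask),
                   c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(m$provenance, c(ct_threshold = 2500, mv_threshold = 300))
  # all-air pair
  air <- const_vol(-1000, modality = "kvct")
  airm <- const_vol(-1000, modality = "mvcbct")
  expect_false(any(segment_metal(air, airm)$mask))
  # threshold monotonicity: raising the MV threshold never grows the mask
  set.seed(8)
  for (i in 1:5) {
    ctr <- random_volume(12, "kvct", 100 + i)
    mvr <- random_volume(12, "mvcbct", 200 + i, lo = -1000, hi = 1400)
    lo <- segment_metal(ctr, mvr, mv_threshold = 300)$mask
    hi <- segment_metal(ctr, mvr, mv_threshold = 600)$mask
    expect_true(all(lo | !hi))  # hi subset of lo
  }
})

test_that("small-component cleanup only ever shrinks the mask", {
  ct <- image_volume(matrix(-1000, 8, 8), modality = "kvct")
  ct$values[2, 2] <- 3000                       # isolated speck
  ct$values[5:7, 5:7] <- 3000                   # real component
  mv <- image_volume(matrix(500, 8, 8), modality = "mvcbct")
  raw <- segment_metal(ct, mv)
  cleaned <- segment_metal(ct, mv, min_component = 3)
  expect_true(all(cleaned$mask | !raw$mask) || sum(cleaned$mask) <= sum(raw$mask))
  expect_false(cleaned$mask[2, 2])
  expect_true(all(cleaned$mask[5:7, 5:7]))
})

test_that("apply_mar copies CT metal pixels exactly and only there", {
  pr <- steel_pair()
  res <- apply_mar(pr$ct, pr$mv)
  expect_true(any(res$mask$mask))
  # copy-back exactness, bitwise
  expect_identical(res$sct$values[res$mask$mask],
                   pr$ct$values[res$mask$mask])
  expect_identical(res$sct$values[!res$mask$mask],
                   res$fused$values[!res$mask$mask])
  # segmentation covers >= 80% of the true metal
  truth_metal <- pr$masks$metal$mask
  expect_gte(sum(res$mask$mask & truth_metal) / sum(truth_metal), 0.8)
})

test_that("metal-free pairs pass through MAR untouched", {
  pr <- clean_pair()
  res <- apply_mar(pr$ct, pr$mv)
  expect_false(any(res$mask$mask))
  expect_identical(res$sct$values, res$fused$values)
})
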