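test_that("toy dose engine matches the exponential closed form", {
  red <- matrix(1, 32, 32)
  d <- toy_dose(red, beam_angles = 0, k = 0.005, prescription = 6000,
                norm_point = c(1, 1))
  depth <- (seq_len(32) - 0.5) * 1
  want <- exp(-0.005 * depth)
  want <- want / want[1] * 6000
  for (j in c(1, 16, 32))
    expect_equal(d$dose[, j], want, tolerance = 1e-6)
  # vacuum: no attenuation anywhere
  dv <- toy_dose(matrix(0, 16, 16), beam_angles = 0)
  expect_true(all(abs(dv$dose - dv$dose[1, 1]) < 1e-9))
  # doubling RED strictly lowers the dose beyond the entrance voxel
  d2 <- toy_dose(red * 2, beam_angles = 0, norm_point = c(1, 1))
  expect_true(all(d2$dose[-1, ] < d$dose[-1, ]))
  expect_error(toy_dose(red, beam_angles = numeric(0)), "zero beams")
  expect_error(dose_grid(matrix(-1, 2, 2)), "non-negative")
})

test_that("gamma is exact against exhaustive search and 100% on identity", {
  set.seed(20)
  for (rep in 1:5) {
    base <- matrix(runif(400, 10, 100), 20)
    test <- base * (1 + matrix(rnorm(400, sd = 0.03), 20))
    ref <- dose_grid(base, prescription = 100)
    tst <- dose_grid(test, prescription = 100)
    for (crit in list(c(2, 2), c(1, 1))) {
      got <- gamma_pass_rate(ref, tst, gamma_criteria(crit[1], crit[2]))
      want <- gamma_oracle(base, test, crit[1], crit[2])
      expect_equal(got$pass_rate, want, tolerance = 1e-9)
    }
    expect_equal(gamma_pass_rate(ref, ref, gamma_criteria(1, 1))$pass_rate,
                 100)
  }
})

test_that("loosening gamma criteria never lowers the pass rate", {
  set.seed(30)
  for (rep in 1:5) {
    a <- dose_grid(matrix(runif(256, 0, 80), 16))
    b <- dose_grid(matrix(runif(256, 0, 80), 16))
    tight <- gamma_pass_rate(a, b, gamma_criteria(1, 1))$pass_rate
    loose <- gamma_pass_rate(a, b, gamma_criteria(2, 2))$pass_rate
    expect_gte(loose, tight)
    dta_only <- gamma_pass_rate(a, b, gamma_criteria(2, 1))$pass_rate
    dd_only <- gamma_pass_rate(a, b, gamma_criteria(1, 2))$pass_rate
    expect_gte(dta_only, tight); expect_gte(dd_only, tight)
  }
  # cutoff can empty the evaluable set
  z <- dose_grid(matrix(1, 4, 4))
  expect_error(gamma_pass_rate(z, z, gamma_criteria(1, 1,
                                                    low_dose_cutoff = 200)),
               "evaluable")
})

test_that("DVH metrics match order-statistic closed forms", {
  roi <- structure_mask("ptv", matrix(TRUE, 10, 10))
  unif <- dose_grid(matrix(6000, 10, 10), prescription = 6000)
  r <- dvh_metrics(unif, roi)
  expect_equal(r$Dmean, 6000); expect_equal(r$D5, 6000)
  expect_equal(r$D95, 6000)
  expect_equal(r$V95, 100); expect_equal(r$V100, 100); expect_equal(r$V110, 0)
  # two-voxel counting
  two <- dose_grid(matrix(c(5000, 7000, 0, 0), 2), prescription = 6000)
  m2 <- structure_mask("r", matrix(c(TRUE, TRUE, FALSE, FALSE), 2))
  expect_equal(suppressWarnings(dvh_metrics(two, m2))$V100, 50)
  # linear ramp: D50 is the midpoint within one-voxel interpolation
  ramp <- dose_grid(matrix(seq(0, 6000, length.out = 100), 10),
                    prescription = 6000)
  r3 <- dvh_metrics(ramp, roi)
  expect_equal(r3$D50, 3000, tolerance = 6000 / 99)
  # tiny ROI: D0.1cc falls back to Dmax with a warning
  tiny <- structure_mask("cord", matrix(c(TRUE, rep(FALSE, 99)), 10))
  expect_warning(r4 <- dvh_metrics(ramp, tiny), "0.1 cc")
  expect_equal(r4$D0.1cc, max(ramp$dose[tiny$mask]))
})

test_that("DVH invariants hold on random dose fixtures", {
  set.seed(41)
  roi <- structure_mask("r", matrix(runif(144) > 0.3, 12))
  for (i in 1:10) {
    d <- dose_grid(matrix(runif(144, 0, 7000), 12), prescription = 6000)
    r <- dvh_metrics(d, roi)
    expect_true(r$D95 <= r$D50 && r$D50 <= r$D5)
    expect_true(r$V95 >= r$V100 && r$V100 >= r$V110)
  }
})

test_that("dose_compare tabulates the clinical metric schema", {
  red <- matrix(1, 16, 16)
  d1 <- toy_dose(red, prescription = 6000)
  d2 <- toy_dose(red * 1.05, prescription = 6000)
  rois <- list(
    ptv = structure_mask("ptv", matrix(rep(c(TRUE, FALSE), 128), 16)),
    mandible = structure_mask("mandible", matrix(rep(c(FALSE, TRUE), 128), 16)),
    oral_cavity = structure_mask("oc", matrix(TRUE, 16, 16)),
    parotid = structure_mask("pa", matrix(TRUE, 16, 16)),
    spinal_cord = structure_mask("sc", matrix(TRUE, 16, 16)))
  tab <- dose_compare(d1, d2, rois)
  expect_equal(nrow(tab), 6 + 2 + 2 + 2 + 1)
  expect_setequal(tab$metric[tab$roi == "ptv"],
                  c("Dmean", "D5", "D95", "V95", "V100", "V110"))
  expect_setequal(tab$metric[tab$roi == "mandible"], c("D2", "Dmean"))
  expect_setequal(tab$metric[tab$roi == "oral_cavity"], c("D50", "Dmean"))
  expect_setequal(tab$metric[tab$roi == "spinal_cord"], "D0.1cc")
  # identical inputs give zero differences
  tab0 <- dose_compare(d1, d1, rois)
  expect_true(all(tab0$abs_diff == 0))
})
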