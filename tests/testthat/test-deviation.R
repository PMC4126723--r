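# Univariate stage: scalar and voxel-wise z-deviation, threshold decisions,
# resemblance rule, probabilistic maps.

test_that("scalar z-scores reproduce the published case deviations", {
  ref <- ws_td_reference()
  r <- function(m, g) {
    row <- ref[ref$measure == m, ]
    list(mean = row[[paste0("mean_", g)]], sd = row[[paste0("sd_", g)]])
  }
  # verbal IQ 90 vs the WS group
  expect_equal(round(zscore_scalar(90, r("verbal_iq", "ws")), 2), 2.44)
  # visuo-motor integration 75 vs WS: the printed summaries give 3.20; the
  # published table prints 3.21 (computed there from unrounded means/SDs)
  expect_equal(zscore_scalar(75, r("beery_vmi", "ws")), 3.21, tolerance = 0.011)
  # verbal IQ 90 vs TD
  expect_equal(round(zscore_scalar(90, r("verbal_iq", "td")), 2), -1.21)
  # case exactly at the group mean
  expect_equal(zscore_scalar(71.90, r("verbal_iq", "ws")), 0)
})

test_that("zero reference SD is an invalid measure", {
  expect_error(zscore_scalar(1, list(mean = 0, sd = 0)), "SD is zero")
})

test_that("scalar z is affine-equivariant", {
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(15, 50, 8)
    case <- rnorm(1, 50, 8)
    z0 <- zscore_scalar(case, reference_stats(x, "WS"))
    shift <- runif(1, -30, 30); scale <- runif(1, 0.2, 5)
    z_shift <- zscore_scalar(case + shift, reference_stats(x + shift, "WS"))
    z_scale <- zscore_scalar(case * scale, reference_stats(x * scale, "WS"))
    expect_equal(z_shift, z0, tolerance = 1e-10)
    expect_equal(z_scale, z0, tolerance = 1e-10)
  }
})

test_that("voxel-wise z-map is zero at the cohort mean and matches closed form", {
  dim3 <- c(4, 4, 4)
  mask <- full_mask(dim3)
  set.seed(22)
  cohort <- rand_cohort(5, dim3)
  ref <- reference_stats(cohort, "WS", mask = mask)
  case_mean <- voxel_image(ref$mean, spacing = c(2, 2, 2), subject_id = "mu")
  d <- zscore_map(case_mean, ref)
  expect_true(all(abs(d$z[d$valid]) < 1e-12))
  expect_equal(sum(d$exceed_pos) + sum(d$exceed_neg), 0L)

  # cohort {v, -v}: mean 0, sd |v|*sqrt(2); case v gives z = 1/sqrt(2)
  v <- array(rnorm(prod(dim3)), dim3)
  coh2 <- list(voxel_image(v, c(2, 2, 2), "a"),
               voxel_image(-v, c(2, 2, 2), "b"))
  d2 <- zscore_map(voxel_image(v, c(2, 2, 2), "case"), coh2, mask)
  nz <- d2$valid & (v != 0)
  expect_equal(unname(d2$z[nz]), unname(sign(v[nz]) / sqrt(2)),
               tolerance = 1e-10)
})

test_that("zero-SD voxels are invalid and excluded from exceed counts", {
  dim3 <- c(3, 3, 3)
  mask <- full_mask(dim3)
  a <- array(1, dim3); b <- array(1, dim3)
  a[1, 1, 1] <- 2  # only this voxel varies across the cohort
  coh <- list(voxel_image(a, c(2, 2, 2), "a"), voxel_image(b, c(2, 2, 2), "b"))
  case <- voxel_image(array(100, dim3), c(2, 2, 2), "case")
  d <- zscore_map(case, coh, mask)
  expect_equal(sum(d$valid), 1L)
  expect_equal(sum(d$exceed_pos), 1L)  # huge z only at the valid voxel
  expect_true(is.na(d$z[2, 2, 2]))
  expect_error(zscore_map(case, coh[1], mask), "n >= 2")
})

test_that("a case from the reference law exceeds |z| > 1.96 at ~5%", {
  # scalar simulation standing in for the voxel-wise law: reference n = 1000,
  # many cases; P(z > 1.96) -> 0.025
  set.seed(23)
  ref <- reference_stats(rnorm(1000, 10, 2), "TD")
  z <- (rnorm(20000, 10, 2) - ref$mean) / ref$sd
  expect_lt(abs(mean(z > 1.96) - 0.025), 0.01)
  expect_lt(abs(mean(abs(z) > 1.96) - 0.05), 0.012)
})

test_that("resemblance is exhaustive over the four exceed patterns", {
  dev <- function(z) scalar_deviation(z, list(mean = 0, sd = 1),
                                      threshold = 1.96)
  # exceeds vs WS only -> resembles TD
  expect_equal(resemblance(dev(2.3), dev(0.4)), "TD_like")
  # exceeds vs TD only -> resembles WS
  expect_equal(resemblance(dev(0.5), dev(-2.7)), "WS_like")
  expect_equal(resemblance(dev(2.1), dev(2.5)), "deviant_from_both")
  expect_equal(resemblance(dev(1.0), dev(-1.2)), "within_both")
  # exactly at threshold does not exceed (strict comparison)
  expect_equal(resemblance(dev(1.96), dev(0)), "within_both")
  # threshold mismatch is an error
  d165 <- scalar_deviation(2.3, list(mean = 0, sd = 1), threshold = 1.65)
  expect_error(resemblance(dev(2.3), d165), "mismatch")
})

test_that("one-tailed deviations flag only the stated tail", {
  up <- scalar_deviation(-3, list(mean = 0, sd = 1), threshold = 1.65,
                         tail = "upper")
  expect_false(up$exceed_neg || up$exceed_pos)
  lo <- scalar_deviation(-3, list(mean = 0, sd = 1), threshold = 1.65,
                         tail = "lower")
  expect_true(lo$exceed_neg)
})

test_that("ROI-level resemblance uses the any-valid-voxel rule and reports peak z", {
  dim3 <- c(6, 6, 6)
  mask <- full_mask(dim3)
  set.seed(24)
  coh <- rand_cohort(20, dim3)
  ref <- reference_stats(coh, "WS", mask = mask)
  # case = mean except one strong voxel inside the ROI
  arr <- ref$mean
  arr[2, 2, 2] <- arr[2, 2, 2] + 5 * ref$sd[2, 2, 2]
  case <- voxel_image(arr, c(2, 2, 2), "case")
  d_ws <- zscore_map(case, ref)
  d_td <- zscore_map(voxel_image(ref$mean, c(2, 2, 2), "case"), ref)
  roi <- array(FALSE, dim3); roi[1:3, 1:3, 1:3] <- TRUE
  rois <- roi_set(list(hot = roi, cold = !roi))
  tab <- resemblance(d_ws, d_td, rois)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$call[tab$roi == "hot"], "TD_like")
  expect_equal(tab$peak_z_vs_WS[tab$roi == "hot"], 5, tolerance = 1e-10)
  expect_equal(tab$call[tab$roi == "cold"], "within_both")
})

test_that("probabilistic maps match direct counting and are rationals over k", {
  dim3 <- c(4, 4, 4)
  mask <- full_mask(dim3)
  set.seed(25)
  coh <- rand_cohort(30, dim3)
  ref <- reference_stats(coh, "TD", mask = mask)
  members <- lapply(1:6, function(i) {
    zscore_map(rand_image(dim3, id = sprintf("m%d", i)), ref)
  })
  pm <- probabilistic_map(members)
  expect_equal(pm$k, 6L)
  # direct counting oracle
  cnt_pos <- Reduce(`+`, lapply(members, function(m) m$exceed_pos + 0))
  expect_equal(pm$prop_pos, cnt_pos / 6)
  # exact multiples of 1/k
  expect_true(all(abs(pm$prop_pos * 6 - round(pm$prop_pos * 6)) < 1e-12))
  expect_true(all(pm$prop_pos + pm$prop_neg <= 1 + 1e-12))

  # k = 1: values in {0, 1}
  pm1 <- probabilistic_map(members[1])
  expect_true(all(pm1$prop_pos %in% c(0, 1)))

  # engineered full agreement: all six members share an extreme voxel
  hot <- lapply(1:6, function(i) {
    arr <- ref$mean; arr[1, 1, 1] <- arr[1, 1, 1] + 10 * ref$sd[1, 1, 1]
    zscore_map(voxel_image(arr, c(2, 2, 2), sprintf("h%d", i)), ref)
  })
  expect_equal(probabilistic_map(hot)$prop_pos[1, 1, 1], 1.0)

  # mixed thresholds refuse to combine
  m165 <- zscore_map(rand_image(dim3), ref, threshold = 1.65)
  expect_error(probabilistic_map(c(members[1:2], list(m165))), "thresholds")
})
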