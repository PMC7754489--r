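make_stats <- function(sigma_v, n_phases, alpha = 0.05, shape = c(8, 8)) {
  z <- qnorm(1 - alpha / 2)
  structure(list(sigma_v = sigma_v, snr = NA, noise_sd_magnitude = NA,
                 ci_half_width = z * sigma_v / sqrt(n_phases),
                 sigma_v_map = matrix(sigma_v, shape[1], shape[2]),
                 ci_half_width_map = matrix(z * sigma_v / sqrt(n_phases),
                                            shape[1], shape[2]),
                 alpha = alpha, n_phases = n_phases),
            class = "velocity_stats")
}

test_that("median filter matches the brute-force oracle", {
  for (s in 1:4) {
    set.seed(s)
    x <- matrix(rnorm(24 * 24), 24, 24)
    for (w in c(3L, 5L, 9L))
      expect_equal(median_filter_2d(x, w, method = "exact"),
                   bf_median_filter(x, w))
  }
  # even windows are realized as the next odd size
  set.seed(9)
  x <- matrix(rnorm(20 * 20), 20, 20)
  expect_equal(median_filter_2d(x, 4, method = "exact"),
               bf_median_filter(x, 5))
  expect_error(median_filter_2d(x, 25), "larger than image")
  expect_error(median_filter_2d(x, 2), ">= 3")
})

test_that("histogram median backend agrees within quantization", {
  set.seed(2)
  x <- matrix(rnorm(40 * 40), 40, 40)
  a <- median_filter_2d(x, 7, method = "exact")
  b <- median_filter_2d(x, 7, method = "histogram")
  expect_lt(max(abs(a - b)), diff(range(x)) / 65535 + 1e-12)
  # constant image stays exact
  expect_equal(median_filter_2d(matrix(3.7, 16, 16), 5,
                                method = "histogram"),
               matrix(3.7, 16, 16))
})

test_that("component labelling matches flood fill for both connectivities", {
  for (s in 1:10) {
    set.seed(s)
    m <- matrix(rbinom(16 * 16, 1, 0.35), 16, 16)
    for (conn in c(4L, 8L))
      expect_true(same_labelling(label_components_2d(m, conn),
                                 bf_label(m, conn)))
  }
  # diagonal pixels: one component under 8, two under 4
  z <- matrix(0L, 5, 5); z[2, 2] <- 1L; z[3, 3] <- 1L
  expect_identical(max(label_components_2d(z, 8L)), 1L)
  expect_identical(max(label_components_2d(z, 4L)), 2L)
})

test_that("background phase correction zeroes offsets and keeps spikes", {
  v <- array(0.3, c(32, 32, 3))
  expect_equal(correct_background_phase(v, 9), array(0, c(32, 32, 3)))

  # linear row ramp + one spike: ramp removed in the interior, spike kept
  ramp <- matrix(rep(seq_len(32) * 0.01, 32), 32, 32)
  plane <- ramp; plane[16, 16] <- plane[16, 16] + 2
  v <- array(plane, c(32, 32, 1))
  v <- array(c(plane, plane), c(32, 32, 2))
  out <- correct_background_phase(v, 9)
  interior <- out[6:27, 6:27, 1]
  interior[11, 11] <- NA  # the spike pixel
  expect_lt(max(abs(interior), na.rm = TRUE), 1e-6)
  expect_gt(out[16, 16, 1], 1.9)
})

test_that("phase correction barely perturbs planted perforator curves", {
  ph <- synthesize_phantom(small_spec(
    n_perforators = 3L, n_big_vessels = 0L, noise_sd_magnitude = 0,
    perforator_pv_fraction = 1, seed = 12))
  out <- correct_background_phase(ph$series, 31)
  tr <- ph$truth$perforators
  for (i in seq_len(3)) {
    got <- out[tr$row[i], tr$col[i], ]
    want <- as.vector(ph$truth$curves[i, ])
    expect_lt(max(abs(got - want)) / max(abs(want)), 0.05)
  }
})

test_that("velocity noise estimate tracks the injected noise", {
  venc <- 4
  rel_err <- vapply(1:10, function(s) {
    ph <- synthesize_phantom(small_spec(n_perforators = 0L,
                                        n_big_vessels = 0L, seed = s))
    cw <- central_wm(ph$truth$wm_mask, ph$truth$brain_mask, 28)
    st <- estimate_velocity_noise(ph$series, cw)
    truth <- ph$truth$spec$noise_sd_velocity
    abs(st$sigma_v - truth) / truth
  }, numeric(1))
  expect_true(all(rel_err < 0.15))
})

test_that("sigma_v is linear in venc and guarded when noiseless", {
  ph <- synthesize_phantom(small_spec(n_perforators = 0L,
                                      n_big_vessels = 0L, seed = 3))
  cw <- central_wm(ph$truth$wm_mask, ph$truth$brain_mask, 28)
  s4 <- estimate_velocity_noise(ph$series, cw)
  s8 <- ph$series; s8$venc <- 8
  expect_equal(estimate_velocity_noise(s8, cw)$sigma_v, 2 * s4$sigma_v)

  quiet <- synthesize_phantom(small_spec(
    n_perforators = 2L, n_big_vessels = 0L, noise_sd_magnitude = 0,
    perforator_pv_fraction = 1, seed = 3))
  stq <- estimate_velocity_noise(quiet$series, cw)
  expect_true(is.infinite(stq$snr))
  expect_lte(stq$sigma_v, 4 * 1e-10)
  rec <- detect_perforators(correct_background_phase(quiet$series, 31),
                            stq, cw)
  expect_identical(nrow(rec), 2L)  # every planted source is significant
})

test_that("the peak-voxel rule picks the highest |V_mean| per group", {
  np <- 3L
  v <- array(0, c(8, 8, np))
  block <- rbind(c(3, 3), c(3, 4), c(4, 3), c(4, 4))
  vals <- c(-0.5, -0.9, -0.7, -0.6)
  for (i in 1:4) v[block[i, 1], block[i, 2], ] <- vals[i]
  wm <- matrix(1L, 8, 8)
  st <- make_stats(0.05, np)
  rec <- detect_perforators(v, st, wm, connectivity = 8L)
  expect_identical(nrow(rec), 1L)
  expect_identical(c(rec$row, rec$col), c(3L, 4L))
  expect_equal(rec$v_mean, -0.9)
  expect_identical(rec$cluster_size, 4L)
})

test_that("upward-flow groups are discarded and CIs exclude zero", {
  np <- 3L
  v <- array(0, c(8, 8, np))
  v[2, 2, ] <- 0.8    # upward: must be dropped
  v[6, 6, ] <- -0.8   # downward: kept
  wm <- matrix(1L, 8, 8)
  rec <- detect_perforators(v, make_stats(0.05, np), wm)
  expect_identical(nrow(rec), 1L)
  expect_true(all(rec$v_mean < 0))
  expect_true(all(rec$ci_high < 0))
  # an empty result is valid
  none <- detect_perforators(array(0, c(8, 8, np)),
                             make_stats(0.05, np), wm)
  expect_identical(nrow(none), 0L)
})

test_that("detections at smaller alpha are a subset of larger alpha", {
  ph <- synthesize_phantom(small_spec(seed = 15))
  cw <- central_wm(ph$truth$wm_mask, ph$truth$brain_mask, 28)
  vc <- correct_background_phase(ph$series, 31)
  st <- estimate_velocity_noise(ph$series, cw)
  r05 <- detect_perforators(vc, st, cw, alpha = 0.05)
  r01 <- detect_perforators(vc, st, cw, alpha = 0.01)
  expect_lte(nrow(r01), nrow(r05))
  sig01 <- attr(r01, "significant"); sig05 <- attr(r05, "significant")
  expect_true(all(sig01 <= sig05))
})
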