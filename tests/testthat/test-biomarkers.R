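# Frequency distributions, percentiles, risk volumes, voxel exclusion,
# low-enhancement and increasing-signal proxies.

test_that("nearest-rank percentile matches a sort-and-index oracle", {
  expect_equal(percentile_value(1:100, 35), 35)
  # constant distribution: the constant at every percentile
  expect_equal(percentile_value(rep(0.2, 50), c(1, 50, 99)), rep(0.2, 3))
  expect_error(percentile_value(1:10, 0), "1\\.\\.99")
  expect_error(percentile_value(1:10, 100), "1\\.\\.99")
  set.seed(10)
  v <- rnorm(1000)
  sv <- sort(v)
  for (p in c(10, 35, 90)) {
    expect_equal(percentile_value(v, p), sv[ceiling(p / 100 * 1000)])
  }
  # non-decreasing in p
  expect_true(all(diff(percentile_value(v, 1:99)) >= 0))
})

test_that("frequency distribution collects sorted masked values", {
  m <- map_from_values(rep(0.2, 50))
  fd <- frequency_distribution(m)
  expect_equal(fd$n_voxels, 50)
  expect_equal(fd$values, rep(0.2, 50))
  # mask intersection drops voxels
  keep <- array(TRUE, c(50, 1, 1)); keep[1:10, 1, 1] <- FALSE
  expect_equal(frequency_distribution(m, keep)$n_voxels, 40)
  # phantom distribution spans the configured range endpoints
  ph <- tiny_phantom(seed = 13, grid = c(16, 16, 5))
  fd2 <- frequency_distribution(ph$ktrans_map)
  rng <- ph$config$ktrans_range
  expect_lt(abs(min(fd2$values) - rng[1]), 0.02)
  expect_lt(abs(max(fd2$values) - rng[2]), 0.02)
})

test_that("risk volume counts strictly-below voxels times voxel volume", {
  vals <- c(0.05, 0.08, 0.10, 0.12, 0.14, 0.2, 0.3, 0.4, 0.5, 0.6)
  m <- map_from_values(vals)
  rv <- risk_volume(m, 0.13)
  expect_equal(rv$voxel_count, 4)
  expect_equal(rv$volume_cm3 * 1000, 4 * 0.78 * 0.78 * 5.0)  # 12.168 mm^3
  expect_equal(sum(rv$binary_map), 4)
  # boundary convention is strict: a voxel exactly at the threshold is out
  expect_equal(risk_volume(map_from_values(c(0.13, 0.14)), 0.13)$voxel_count, 0)
  expect_equal(risk_volume(m, 0.01)$volume_cm3, 0)
  expect_equal(risk_volume(m, 1)$voxel_count, 10)
  expect_error(risk_volume(m, -0.1), "non-negative")
})

test_that("risk volume is monotone in threshold and additive over sub-masks", {
  ph <- tiny_phantom(seed = 17)
  th <- seq(0.01, 1.06, by = 0.05)
  vol <- vapply(th, function(t) risk_volume(ph$ktrans_map, t)$volume_cm3,
                numeric(1))
  expect_true(all(diff(vol) >= 0))
  expect_equal(vol[length(vol)],
               sum(ph$tumor_mask) * prod(ph$voxel_dims_mm) / 1000)
  half1 <- ph$tumor_mask; half1[, , 3:4] <- FALSE
  half2 <- ph$tumor_mask & !half1
  expect_equal(risk_volume(ph$ktrans_map, 0.13, half1)$volume_cm3 +
                 risk_volume(ph$ktrans_map, 0.13, half2)$volume_cm3,
               risk_volume(ph$ktrans_map, 0.13)$volume_cm3)
})

test_that("T2-based exclusion recovers the phantom's fluid compartment", {
  ph <- tiny_phantom(seed = 23, grid = c(16, 16, 5), necrosis = 0.08)
  # tissue ~ N(100, 15), fluid ~ N(300, 20): an absolute cut at 200 separates
  refined <- exclude_voxels(ph$tumor_mask, ph$synthetic_t2, upper_cut = 200)
  removed <- ph$tumor_mask & !refined
  expect_identical(removed, ph$fluid_mask)
  expect_equal(attr(refined, "n_removed"), sum(ph$fluid_mask))
  # disabled rule: mask unchanged
  off <- exclude_voxels(ph$tumor_mask, ph$synthetic_t2, enabled = FALSE)
  expect_equal(sum(off), sum(ph$tumor_mask))
  # everything excluded is an error
  expect_error(exclude_voxels(ph$tumor_mask, ph$synthetic_t2, upper_cut = -1),
               "empty")
})

test_that("excluded and non-enhancing voxels reach no downstream statistic", {
  ph <- tiny_phantom(seed = 29, grid = c(12, 12, 4), necrosis = 0.1)
  refined <- exclude_voxels(ph$tumor_mask, ph$synthetic_t2, upper_cut = 200)
  fd <- frequency_distribution(ph$ktrans_map, refined)
  expect_equal(fd$n_voxels, sum(refined))
  rv <- risk_volume(ph$ktrans_map, 1.1, refined)
  expect_equal(rv$voxel_count, sum(refined))
  expect_false(any(rv$binary_map & ph$fluid_mask))
})

test_that("low-enhancement volume: extremes and correlation with risk volume", {
  ph <- tiny_phantom(seed = 31, grid = c(10, 10, 4), necrosis = 0)
  ser <- simulate_dce_series(ph, noise_sd = 0)
  vox_cm3 <- prod(ph$voxel_dims_mm) / 1000
  # cutoff 0: nothing is "low"; huge cutoff: everything is
  expect_equal(as.numeric(letv_volume(ser, enhancement_cutoff = 0)), 0)
  expect_equal(as.numeric(letv_volume(ser, enhancement_cutoff = 1e9)),
               sum(ser$mask) * vox_cm3)
  expect_error(letv_volume(ser, window_s = 5), "early window")
})

test_that("low-enhancing volume correlates with the Ktrans risk volume", {
  set.seed(41)
  rows <- lapply(1:25, function(p) {
    ph <- generate_phantom(phantom_config(grid_shape = c(8, 8, 3),
                                          low_region_fraction = runif(1, 0.05, 0.6),
                                          necrosis_fraction = 0,
                                          seed = 500 + p))
    ser <- simulate_dce_series(ph, noise_sd = 0)
    tibble::tibble(
      rv = risk_volume(ph$ktrans_map, 0.13)$volume_cm3,
      letv = as.numeric(letv_volume(ser)))
  })
  df <- dplyr::bind_rows(rows)
  st <- spearman_test(df$rv, df$letv)
  expect_gt(st$rho, 0.5)
})

test_that("increasing-signal volume matches a brute-force slope-sign count", {
  ph <- tiny_phantom(seed = 37, grid = c(8, 8, 3), necrosis = 0)
  ser <- simulate_dce_series(ph, noise_sd = 0)
  got <- attr(tvis_volume(ser, window_s = c(240, 600), slope_cutoff = 0),
              "voxel_count")
  inw <- ser$times_s >= 240 & ser$times_s <= 600
  tt <- ser$times_s[inw]
  lin <- which(ser$mask)
  mat <- matrix(ser$data, ncol = length(ser$times_s))[lin, inw]
  want <- sum(apply(mat, 1, function(y) coef(lm(y ~ tt))[2] > 0))
  expect_equal(got, want)
  expect_error(tvis_volume(ser, window_s = c(590, 600)), "3 frames")
  # all late signals falling: zero volume (decreasing synthetic curves)
  dec <- ser
  nt <- length(ser$times_s)
  dec$data <- array(rep(rev(seq_len(nt)), each = prod(dim(ser$mask))),
                    dim = dim(ser$data))
  expect_equal(as.numeric(tvis_volume(dec)), 0)
})

test_that("compute_biomarkers assembles one tidy row", {
  ph <- tiny_phantom(seed = 43, grid = c(10, 10, 4))
  ser <- simulate_dce_series(ph, noise_sd = 0)
  row <- compute_biomarkers(ph$ktrans_map, series = ser)
  expect_equal(nrow(row), 1)
  fd <- frequency_distribution(ph$ktrans_map)
  expect_equal(row$p_ktrans, percentile_value(fd, 35))
  expect_equal(row$rv_ktrans_cm3, risk_volume(ph$ktrans_map, 0.13)$volume_cm3)
})
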