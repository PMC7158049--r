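# Cohort splitting, percentile and threshold sweeps, optimum selection.

test_that("one-third/two-thirds split produces floor(n/3) risk patients", {
  r80 <- split_one_third(rnorm(80))
  expect_equal(sum(r80), 26)
  expect_equal(sum(!r80), 54)
  expect_equal(sum(split_one_third(rnorm(3))), 1)
  expect_equal(sum(split_one_third(rnorm(81))), 27)
  expect_error(split_one_third(1:2), "at least 3")
  # direction: lowest values are risk for percentile statistics...
  v <- c(5, 1, 9, 2, 8, 3)
  expect_equal(which(split_one_third(v, "low-is-risk")), c(2, 4))
  # ...largest for risk volumes
  expect_equal(which(split_one_third(v, "high-is-risk")), c(3, 5))
  # boundary ties break by stable patient order
  expect_equal(which(split_one_third(c(1, 1, 1, 1, 1, 1), "low-is-risk")),
               c(1, 2))
})

test_that("default threshold grid has 200 points up to 0.50", {
  g <- threshold_grid()
  expect_equal(length(g), 200)
  expect_equal(g[1], 0.0025)
  expect_equal(g[200], 0.50)
  expect_equal(unique(round(diff(g), 10)), 0.0025)
})

make_sweep_cohort <- function(n = 30, seed = 1, hr = 3) {
  cg <- generate_cohort(cohort_config(n_patients = n, hazard_ratio = hr,
                                      seed = seed),
                        phantom_config(grid_shape = c(8, 8, 3)))
  dists <- lapply(cg$phantoms, function(ph)
    frequency_distribution(ph$ktrans_map, !ph$fluid_mask))
  list(cohort = cg$cohort, dists = dists)
}

test_that("sweeps return full curves with valid ranges", {
  sc <- make_sweep_cohort(n = 30, seed = 2)
  psw <- percentile_sweep(sc$cohort, sc$dists, percentiles = 1:99)
  expect_equal(nrow(psw), 99)
  expect_true(all(psw$logrank_p_dfs > 0 & psw$logrank_p_dfs <= 1, na.rm = TRUE))
  expect_true(all(psw$auc_dfs >= 0 & psw$auc_dfs <= 1, na.rm = TRUE))
  tsw <- threshold_sweep(sc$cohort, sc$dists, threshold_grid(step = 0.01))
  expect_equal(nrow(tsw), 50)
  # per-patient RV curves are non-decreasing along the grid, hence the total
  # risk volume at the largest threshold is the largest
  vols <- vapply(threshold_grid(step = 0.01), function(th) {
    sum(vapply(sc$dists, function(d)
      sum(d$values < th) * d$voxel_volume_mm3 / 1000, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(vols) >= 0))
})

test_that("a minimal cohort sweeps without error", {
  sc <- make_sweep_cohort(n = 6, seed = 3)
  psw <- percentile_sweep(sc$cohort, sc$dists, percentiles = 1:99)
  expect_equal(nrow(psw), 99)
})

test_that("optimum selection is an argmax with smallest-value tie-breaking", {
  fake <- structure(
    tibble::tibble(axis = 1:5,
                   logrank_p_dfs = c(0.2, 0.04, 0.01, 0.04, 0.3),
                   logrank_p_os = c(0.3, 0.04, 0.02, 0.04, 0.2),
                   auc_dfs = c(0.5, 0.6, 0.9, 0.6, 0.5),
                   auc_os = c(0.5, 0.7, 0.7, 0.6, 0.5)),
    class = c("sweep_result", class(tibble::tibble())), axis_type = "percentile")
  opt <- select_optimum(fake, "dfs")
  expect_equal(opt$optimum, 3)
  expect_equal(opt$auc, 0.9)
  # plateau resolves to the smallest grid value
  expect_equal(select_optimum(fake, "os")$optimum, 2)
  expect_false(select_optimum(fake, "os")$agrees_other_endpoint)
  # random curve vs brute-force scan
  set.seed(9)
  fake$auc_dfs <- runif(5)
  expect_equal(select_optimum(fake, "dfs")$optimum,
               fake$axis[which.max(fake$auc_dfs)])
  # all-equal AUCs warn and return the smallest grid value
  fake$auc_dfs <- rep(0.5, 5)
  expect_warning(o <- select_optimum(fake, "dfs"), "all AUC")
  expect_equal(o$optimum, 1)
  # significant range: contiguous region below alpha for both endpoints
  sr <- significant_range(fake)
  expect_equal(sr$from, 2); expect_equal(sr$to, 4); expect_equal(sr$n_points, 3)
})

test_that("reversing the risk direction reflects the AUC about one half", {
  set.seed(4)
  score <- rnorm(40)
  lab <- rbinom(40, 1, 0.5)
  expect_equal(roc_auc(score, lab), 1 - roc_auc(-score, lab))
})

test_that("a planted hazard step at 0.13 1/min is recovered by the sweep", {
  sc <- make_sweep_cohort(n = 120, seed = 6, hr = 4)
  tsw <- threshold_sweep(sc$cohort, sc$dists, threshold_grid(step = 0.01))
  opt <- select_optimum(tsw, "dfs")
  expect_lt(abs(opt$optimum - 0.13), 0.05)
  expect_gt(opt$auc, 0.5)
})

test_that("null cohorts give approximately alpha-level significant fractions", {
  set.seed(15)
  fracs <- replicate(10, {
    n <- 40
    sim <- simulate_survival(n, 0.02)
    cohort <- tibble::tibble(dfs_months = sim$time_months,
                             dfs_event = sim$event,
                             os_months = sim$time_months,
                             os_event = sim$event)
    dists <- lapply(seq_len(n), function(i) sort(runif(200)))
    psw <- percentile_sweep(cohort, dists, percentiles = seq(5, 95, 10))
    mean(psw$logrank_p_dfs < 0.05, na.rm = TRUE)
  })
  # grid points are highly correlated, so the mean fraction is the right
  # summary: it should sit near alpha, far below any planted-signal level
  expect_lt(mean(fracs), 0.20)
})
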