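# Kaplan-Meier, log-rank, ROC AUC, Cox, Spearman, each against an
# independent oracle.

test_that("product-limit estimator matches the hand computation", {
  d <- tibble::tibble(time_months = c(5, 8, 12, 20), event = c(1, 1, 0, 1))
  f <- km_fit(d)
  expect_equal(survival_at(f, 4), 1.0)               # before the first event
  expect_equal(survival_at(f, 12), 0.5)              # (3/4)(2/3)
  expect_equal(survival_at(f, 20), 0)                # last subject fails
  expect_error(km_fit(tibble::tibble(time_months = c(0, 1), event = c(1, 1))),
               "positive")
})

test_that("uncensored KM equals the empirical survival function", {
  set.seed(3)
  d <- tibble::tibble(time_months = rexp(40, 0.1), event = 1)
  f <- km_fit(d)
  for (t in c(2, 5, 10, 30)) {
    expect_equal(survival_at(f, t), mean(d$time_months > t))
  }
})

test_that("log-rank matches the hand O-E/V statistic and a permutation p", {
  d <- tibble::tibble(time_months = c(3, 5, 9, 14, 7, 11, 16, 21),
                      event = c(1, 1, 1, 0, 1, 1, 0, 1),
                      group = rep(c("a", "b"), each = 4))
  got <- logrank_test(d)
  want <- logrank_bruteforce(d$time_months, d$event, d$group == "a")
  expect_equal(got$chisq, want, tolerance = 1e-10)
  expect_equal(got$p_value, pchisq(want, 1, lower.tail = FALSE))
  # permutation reference for the p-value
  set.seed(5)
  perm <- replicate(4000, {
    g <- sample(d$group)
    logrank_bruteforce(d$time_months, d$event, g == "a")
  })
  p_perm <- mean(perm >= want - 1e-12)
  expect_lt(abs(got$p_value - p_perm), 0.15)  # small-sample chi-square vs exact
  # label symmetry
  d2 <- d; d2$group <- ifelse(d$group == "a", "b", "a")
  expect_equal(logrank_test(d2)$chisq, got$chisq)
  # time-rescaling invariance
  d3 <- d; d3$time_months <- d$time_months * 7.3
  expect_equal(logrank_test(d3)$chisq, got$chisq)
})

test_that("log-rank edge cases", {
  same <- tibble::tibble(time_months = rep(c(2, 4, 6), 2),
                         event = rep(c(1, 0, 1), 2),
                         group = rep(c("a", "b"), each = 3))
  r <- logrank_test(same)
  expect_equal(r$chisq, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1)
  # all-censored group vs events: finite statistic
  mix <- tibble::tibble(time_months = c(5, 9, 13, 6, 10, 14),
                        event = c(0, 0, 0, 1, 1, 1),
                        group = rep(c("a", "b"), each = 3))
  expect_true(is.finite(logrank_test(mix)$chisq))
  # zero events overall
  none <- tibble::tibble(time_months = 1:4, event = 0,
                         group = c("a", "a", "b", "b"))
  expect_error(logrank_test(none), "zero events")
})

test_that("ROC AUC equals brute-force concordant-pair counting", {
  lab <- c(1, 1, 0, 0, 1, 0)
  sc <- c(3.2, 2.5, 1.1, 2.5, 4.0, 0.3)
  expect_equal(roc_auc(sc, lab), auc_bruteforce(sc, lab))
  # perfect separation and total ties
  expect_equal(roc_auc(c(5, 6, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(2, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both outcome classes")
  # score reversal maps AUC to 1 - AUC without ties
  set.seed(8)
  s <- rnorm(30); l <- rbinom(30, 1, 0.4)
  expect_equal(roc_auc(s, l) + roc_auc(-s, l), 1)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  s <- rnorm(50); l <- rbinom(50, 1, 0.5)
  ref <- as.numeric(pROC::auc(pROC::roc(l, s, direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(s, l), ref)
})

test_that("horizon labelling excludes early-censored patients", {
  # an event after the horizon still means event-free AT the horizon
  lab <- event_by_horizon(c(10, 70, 30, 80), c(1, 0, 0, 1), 60)
  expect_equal(lab, c(1L, 0L, NA_integer_, 0L))
})

test_that("Cox optimum matches a brute-force partial-likelihood grid", {
  d <- tibble::tibble(time_months = c(4, 7, 10, 13, 16, 20),
                      event = c(1, 1, 0, 1, 1, 1),
                      x = c(1.2, 0.4, 1.9, -0.3, 0.8, -1.1))
  fit <- cox_fit(d, "x")
  grid <- seq(-3, 3, by = 1e-3)
  ll <- vapply(grid, cox_pll, numeric(1),
               time = d$time_months, event = d$event, x = d$x)
  beta_grid <- grid[which.max(ll)]
  expect_lt(abs(tidy(fit)$estimate - beta_grid), 2e-3)
  expect_lt(abs(cox_pll(tidy(fit)$estimate, d$time_months, d$event, d$x) -
                  max(ll)), 1e-4)
  expect_equal(glance(fit)$n_events, 5)
})

test_that("Cox recovers a hazard ratio of 3 on two-group exponential data", {
  hits <- 0; n_rep <- 50
  set.seed(1000)
  for (r in seq_len(n_rep)) {
    g <- rep(0:1, each = 250)
    d <- simulate_survival(500, 0.02 * ifelse(g == 1, 3, 1),
                           censoring_rate = 0.005)
    d$x <- g
    td <- tidy(cox_fit(d, "x"))
    ci <- td$estimate + c(-1.96, 1.96) * td$std_error
    if (ci[1] <= log(3) && log(3) <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("degenerate Cox designs are flagged, not silently returned", {
  d <- tibble::tibble(time_months = c(2, 4, 6, 8), event = c(1, 1, 1, 0),
                      x = 1)
  td <- tidy(cox_fit(d, "x"))
  expect_true(td$flagged)
  expect_error(cox_fit(dplyr::mutate(d, event = 0), "x"), "zero events")
})

test_that("Spearman correlation matches rank-then-Pearson", {
  x <- c(2.1, 3.5, 1.2, 8.8, 4.4, 6.1, 0.9, 7.3)
  y <- c(5.5, 1.3, 9.9, 2.2, 7.7, 3.1, 8.4, 4.0)
  st <- spearman_test(x, y)
  expect_equal(st$rho, cor(rank(x), rank(y)))
  expect_equal(spearman_test(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_test(1:10, -(1:10)^3)$rho, -1)
  expect_error(spearman_test(1:5, rep(2, 5)), "zero variance")
  expect_error(spearman_test(1:2, 2:3), "at least 3")
})
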