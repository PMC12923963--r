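test_that("KM product-limit estimate matches hand computations", {
  km <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$survival, c(2/3, 1/3, 0))
  km2 <- km_estimate(c(1, 2, 3), c(FALSE, TRUE, TRUE))
  expect_equal(km2$event_times, c(2, 3))
  expect_equal(km2$survival, c(1/2, 0))
  km3 <- km_estimate(c(2, 4, 6), c(FALSE, FALSE, FALSE))
  expect_length(km3$event_times, 0L)
  expect_equal(km_survival_at(km3, c(1, 10)), c(1, 1))
  expect_error(km_estimate(numeric(), logical()), "no subjects")
  expect_error(km_estimate(c(-1, 2), c(TRUE, TRUE)), "non-negative")
})

test_that("without censoring KM equals the empirical survivor function", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(2:30, 1)
    times <- round(stats::rexp(n, 0.5), 1)
    km <- km_estimate(times, rep(TRUE, n))
    for (t in unique(times))
      expect_equal(km_survival_at(km, t), empirical_survivor(times, t))
  }
})

test_that("KM agrees with the survival package to 1e-10 on censored data", {
  skip_if_not_installed("survival")
  set.seed(202)
  for (i in 1:100) {
    d <- random_censored_data(sample(10:60, 1))
    km <- km_estimate(d$times, d$events)
    sf <- survival::survfit(survival::Surv(d$times, d$events) ~ 1,
                            conf.type = "log-log")
    idx <- match(km$event_times, sf$time)
    expect_true(all(abs(km$survival - sf$surv[idx]) < 1e-10))
    # complementary log-log band agrees where the estimate is interior
    interior <- km$survival > 0 & km$survival < 1
    expect_true(all(abs(km$ci_low[interior] - sf$lower[idx][interior]) < 1e-8))
    expect_true(all(abs(km$ci_high[interior] - sf$upper[idx][interior]) < 1e-8))
    expect_true(all(diff(km$survival) <= 1e-12))
    expect_true(all(km$ci_low <= km$survival + 1e-12 &
                      km$survival <= km$ci_high + 1e-12))
  }
})

test_that("log-rank statistic matches hand computation and the survival package", {
  r <- logrank_test(c(1, 2), c(TRUE, TRUE), c(3, 4), c(TRUE, TRUE))
  expect_equal(r$chi_square, 49 / 17, tolerance = 1e-12)
  expect_equal(r$observed, 2)
  expect_equal(r$expected, 5 / 6)
  expect_equal(r$variance, 17 / 36)

  same <- logrank_test(c(1, 2, 3), c(TRUE, FALSE, TRUE),
                       c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(same$chi_square, 0)
  expect_equal(same$p_value, 1)
  expect_error(logrank_test(numeric(), logical(), 1, TRUE), "non-empty")

  skip_if_not_installed("survival")
  set.seed(303)
  for (i in 1:20) {
    a <- random_censored_data(sample(10:40, 1))
    b <- random_censored_data(sample(10:40, 1))
    mine <- logrank_test(a$times, a$events, b$times, b$events)
    sd <- survival::survdiff(
      survival::Surv(c(a$times, b$times), c(a$events, b$events)) ~
        rep(1:2, c(length(a$times), length(b$times))))
    expect_equal(mine$chi_square, sd$chisq, tolerance = 1e-8)
  }
})

test_that("larger group separation monotonically strengthens the log-rank signal", {
  set.seed(404)
  base <- stats::rexp(60, 1)
  p_at_shift <- vapply(c(0, 0.5, 1.5), function(s) {
    logrank_test(base, rep(TRUE, 60), base + s, rep(TRUE, 60))$p_value
  }, numeric(1))
  expect_true(all(diff(p_at_shift) < 0))
})

test_that("five_year_status partitions records and honors the 5-year boundary", {
  d <- new_cohort(6)
  d$os_time_years <- c(6.2, 3.0, 5.0, 5.0, 2.1, 7.0)
  d$os_event <-      c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  d$rfs_time_years <- d$os_time_years
  d$rfs_event <- d$os_event
  st <- five_year_status(d, "os")
  expect_identical(as.character(st),
                   c("survivor",         # death after 5y is a 5-year survivor
                     "lost_before_5y",   # censored at 3y
                     "event_before_5y",  # event at exactly 5.0
                     "survivor",         # censored at exactly 5.0
                     "event_before_5y",
                     "survivor"))
  expect_false(any(is.na(st)))
  expect_identical(as.character(five_year_status(d, "rfs")[5]),
                   "event_before_5y")
})

test_that("median follow-up is computed among censored patients only", {
  d <- new_cohort(4)
  d$os_time_years <- c(5, 6, 7, 2)
  d$os_event <- c(FALSE, FALSE, FALSE, TRUE)
  d$rfs_time_years <- d$os_time_years; d$rfs_event <- d$os_event
  expect_equal(median_followup_censored(d)$median, 6)
  d2 <- new_cohort(2)
  d2$os_time_years <- c(4, 6); d2$os_event <- FALSE
  d2$rfs_time_years <- d2$os_time_years
  expect_equal(median_followup_censored(d2)$median, 5)
  d3 <- new_cohort(1)
  d3$os_time_years <- 2; d3$os_event <- TRUE
  d3$rfs_time_years <- 2; d3$rfs_event <- TRUE
  expect_error(median_followup_censored(d3), "no censored")
})

test_that("recurrence sites are counted with multiplicity per patient", {
  d <- new_cohort(5)
  idx <- 1:4
  d$os_time_years[idx] <- 4; d$os_event[idx] <- TRUE
  d$rfs_event[idx] <- TRUE
  d$recurrence_time_years[idx] <- c(0.5, 1.9, 3.0, 4.0)
  d$rfs_time_years[idx] <- d$recurrence_time_years[idx]
  d$recurrence_sites[idx] <- c("liver", "liver;lung", "lung", "peritoneum")
  rt <- recurrence_table(d)
  expect_identical(rt$n_recurrent, 4L)
  expect_equal(rt$table$pct[rt$table$site == "liver"], 50.0)
  expect_equal(rt$table$pct[rt$table$site == "lung"], 50.0)
  expect_equal(rt$table$pct[rt$table$site == "peritoneum"], 25.0)
  expect_equal(rt$pct_within_2y, 50.0)
  empty <- recurrence_table(new_cohort(3))
  expect_identical(empty$n_recurrent, 0L)
  expect_identical(nrow(empty$table), 0L)
})

test_that("multi-site recurrence percentages count co-occurring sites", {
  d <- new_cohort(4)
  d$os_time_years <- 4; d$os_event <- TRUE; d$rfs_event <- TRUE
  d$recurrence_time_years <- 1
  d$rfs_time_years <- 1
  d$recurrence_sites <- c("lymph_node_paraaortic",
                          "lymph_node_paraaortic;liver",
                          "lymph_node_paraaortic;lung;liver",
                          "liver")
  ms <- multisite_recurrence(d, "lymph_node_paraaortic")
  expect_identical(ms$n_site, 3L)
  expect_identical(ms$n_multisite, 2L)
  expect_equal(ms$pct_multisite, 66.7)
  expect_error(multisite_recurrence(d, "bone"), "unknown")
})

test_that("survival after recurrence uses time from recurrence with KM median rules", {
  d <- new_cohort(2)
  d$os_event <- TRUE
  d$os_time_years <- c(2.0, 3.0)
  d$recurrence_time_years <- c(1.0, 1.5)
  d$rfs_time_years <- d$recurrence_time_years
  d$rfs_event <- TRUE
  d$recurrence_sites <- "liver"
  res <- survival_after_recurrence(d)  # post-recurrence deaths at 1.0, 1.5
  expect_equal(res$median, 1.0)        # S(1.0) = 0.5 already qualifies

  d$os_event <- c(TRUE, FALSE)         # death at 1.0, censored at 1.5
  res2 <- survival_after_recurrence(d)
  expect_equal(res2$median, 1.0)       # S drops to exactly 0.5 at 1.0

  d$os_event <- FALSE                  # all recurrent patients censored
  d$rfs_event <- TRUE
  res3 <- survival_after_recurrence(d)
  expect_true(is.na(res3$median))      # median not reached

  d1 <- new_cohort(1)
  d1$os_time_years <- 3; d1$os_event <- TRUE
  d1$recurrence_time_years <- 1; d1$rfs_time_years <- 1
  d1$rfs_event <- TRUE; d1$recurrence_sites <- "lung"
  expect_equal(survival_after_recurrence(d1)$median, 2.0)
})
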