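# Independent oracles and fixture helpers shared across the suite.

# Clopper-Pearson by brute-force inversion of binomial tail tests:
# low solves P(X >= k | p) = alpha/2, high solves P(X <= k | p) = alpha/2.
cp_oracle <- function(k, n, level = 0.95) {
  a <- (1 - level) / 2
  low <- if (k == 0) 0 else
    stats::uniroot(function(p) stats::pbinom(k - 1, n, p, lower.tail = FALSE) - a,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  high <- if (k == n) 1 else
    stats::uniroot(function(p) stats::pbinom(k, n, p) - a,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(low = low, high = high)
}

# Empirical survivor function: with no censoring the KM estimate must equal
# the fraction of subjects with time > t.
empirical_survivor <- function(times, t) mean(times > t)

# Random right-censored dataset for cross-checks against the survival package.
random_censored_data <- function(n) {
  t_event <- stats::rexp(n, rate = 0.3)
  t_cens <- stats::rexp(n, rate = 0.2)
  # duplicate some times to exercise tie handling
  t_event <- round(t_event, 1)
  t_cens <- round(t_cens, 1)
  list(times = pmin(t_event, t_cens), events = t_event <= t_cens)
}

# A consistent mixed cohort exercising both endpoints: k deaths with
# recurrence, k censored-alive, a couple of early-lost patients.
mixed_test_cohort <- function() {
  d <- new_cohort(10)
  # 3 deaths after recurrence
  idx <- 1:3
  d$os_time_years[idx] <- c(2, 3, 4.5)
  d$os_event[idx] <- TRUE
  d$recurrence_time_years[idx] <- c(1, 2.5, 4)
  d$rfs_time_years[idx] <- c(1, 2.5, 4)
  d$rfs_event[idx] <- TRUE
  d$recurrence_sites[idx] <- c("liver", "liver;lung", "peritoneum")
  # 1 death without recurrence
  d$os_time_years[4] <- 3.5; d$os_event[4] <- TRUE
  d$rfs_time_years[4] <- 3.5; d$rfs_event[4] <- TRUE
  # 2 lost before 5 years
  d$os_time_years[5:6] <- c(2.2, 4.9)
  d$rfs_time_years[5:6] <- c(2.2, 4.9)
  d
}
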