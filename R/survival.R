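# Survival machinery: Kaplan-Meier product-limit estimation with Greenwood
# variance and complementary log-log confidence bands, the unstratified
# log-rank test, fixed 5-year status classification, follow-up summaries and
# recurrence tabulations.

#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survivor function from right-censored data. At each distinct
#' event time t with d events among n at risk, the estimate multiplies by
#' (1 - d/n); ties between events and censorings at the same time are
#' resolved by processing events first (censored subjects at t remain at risk
#' for the events at t). The variance follows Greenwood's formula and the
#' 95% pointwise band is computed on the complementary log-log scale, which
#' keeps it inside \[0, 1\]; where the estimate is exactly 0 or 1 the band is
#' degenerate at the estimate.
#'
#' @param times Non-negative follow-up times.
#' @param events Logical event indicators (`FALSE` = censored).
#' @param conf_level Confidence level of the pointwise band.
#' @return An object of class `km_curve`: a list with `event_times`
#'   (distinct times with at least one event, ascending), `n_at_risk`,
#'   `n_events`, `survival`, `std_err` (Greenwood standard error of the
#'   survival estimate), `ci_low`, `ci_high`, and `n` (subjects).
#' @export
#' @examples
#' km <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
#' km$survival  # 2/3, 1/3, 0
km_estimate <- function(times, events, conf_level = 0.95) {
  if (length(times) == 0L) stop("no subjects", call. = FALSE)
  if (length(times) != length(events))
    stop("times and events must have equal length", call. = FALSE)
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be finite and non-negative", call. = FALSE)
  events <- as.logical(events)

  tev <- sort(unique(times[events]))
  n_at_risk <- vapply(tev, function(t) sum(times >= t), numeric(1))
  n_events <- vapply(tev, function(t) sum(events & times == t), numeric(1))
  surv <- cumprod(1 - n_events / n_at_risk)

  # Greenwood: Var(S) = S^2 * sum d / (n (n - d)); the cumulative-hazard
  # variance term is also what the cloglog band needs.
  gw_term <- ifelse(n_at_risk > n_events,
                    n_events / (n_at_risk * (n_at_risk - n_events)), Inf)
  cum_gw <- cumsum(gw_term)
  std_err <- surv * sqrt(cum_gw)

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  interior <- surv > 0 & surv < 1 & is.finite(cum_gw)
  ci_low <- surv
  ci_high <- surv
  se_cll <- sqrt(cum_gw[interior]) / abs(log(surv[interior]))
  ci_low[interior] <- surv[interior]^exp(z * se_cll)
  ci_high[interior] <- surv[interior]^exp(-z * se_cll)

  structure(list(event_times = tev, n_at_risk = n_at_risk,
                 n_events = n_events, survival = surv, std_err = std_err,
                 ci_low = ci_low, ci_high = ci_high,
                 n = length(times), conf_level = conf_level),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", x$n, "subjects,",
      sum(x$n_events), "events\n")
  if (length(x$event_times) > 0L)
    print(utils::head(as.data.frame(x), 10L), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.km_curve <- function(x, ...) {
  data.frame(time = x$event_times, n_at_risk = x$n_at_risk,
             n_events = x$n_events, survival = x$survival,
             ci_low = x$ci_low, ci_high = x$ci_high)
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param curve A [km_estimate()] result.
#' @param t Times at which to evaluate the step function.
#' @return Survival probabilities (1 before the first event time).
#' @export
km_survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  vapply(t, function(ti) {
    i <- sum(curve$event_times <= ti)
    if (i == 0L) 1 else curve$survival[i]
  }, numeric(1))
}

#' Median survival time from a Kaplan-Meier curve
#'
#' Smallest event time at which the estimated survival drops to 0.5 or
#' below; `NA` (not reached) when the curve stays above 0.5.
#'
#' @param curve A [km_estimate()] result.
#' @return Time, or `NA_real_` when the median is not reached.
#' @export
km_median <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  hit <- which(curve$survival <= 0.5 + 1e-12)
  if (length(hit) == 0L) NA_real_ else curve$event_times[hit[1L]]
}

#' Unstratified two-group log-rank test
#'
#' Observed-minus-expected statistic with hypergeometric variance, summed
#' over distinct event times of the pooled sample and referred to a
#' chi-square distribution with one degree of freedom. No continuity
#' correction is applied.
#'
#' @param times_a,events_a Follow-up times and event indicators, group A.
#' @param times_b,events_b Follow-up times and event indicators, group B.
#' @return An object of class `logrank_result` with `chi_square`, `p_value`,
#'   `observed`, `expected` (both for group A) and `variance`.
#' @export
#' @examples
#' r <- logrank_test(c(1, 2), c(TRUE, TRUE), c(3, 4), c(TRUE, TRUE))
#' r$chi_square  # 49/17 = 2.882
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0L || length(times_b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  times <- c(times_a, times_b)
  events <- as.logical(c(events_a, events_b))
  grp_a <- rep(c(TRUE, FALSE), c(length(times_a), length(times_b)))

  tev <- sort(unique(times[events]))
  o1 <- e1 <- v <- 0
  for (t in tev) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp_a)
    d <- sum(events & times == t)
    d1 <- sum(events & times == t & grp_a)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- if (v > 0) (o1 - e1)^2 / v else 0
  p <- if (v > 0) stats::pchisq(chi, df = 1, lower.tail = FALSE) else 1
  structure(list(chi_square = chi, p_value = p,
                 observed = o1, expected = e1, variance = v),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.3f (1 df), p = %.4g\n",
              x$chi_square, x$p_value))
  invisible(x)
}

#' Fixed 5-year endpoint status
#'
#' Classifies each patient for a 5-year landmark: `event_before_5y` if the
#' endpoint event occurred at or before 5.0 years; `survivor` if the patient
#' is event-free at 5 years with follow-up reaching 5.0 years (an event
#' after 5 years still makes a 5-year survivor); `lost_before_5y` if
#' censored before 5.0 years.
#'
#' @param cohort A cohort data.frame.
#' @param endpoint `"os"` or `"rfs"`.
#' @return Factor with levels `survivor`, `event_before_5y`, `lost_before_5y`.
#' @export
five_year_status <- function(cohort, endpoint = c("os", "rfs")) {
  endpoint <- match.arg(endpoint)
  time <- cohort[[paste0(endpoint, "_time_years")]]
  event <- cohort[[paste0(endpoint, "_event")]]
  status <- ifelse(event & time <= 5, "event_before_5y",
                   ifelse(time >= 5, "survivor", "lost_before_5y"))
  factor(status, levels = c("survivor", "event_before_5y", "lost_before_5y"))
}

#' Median follow-up among censored patients
#'
#' Median and interquartile range of OS follow-up time restricted to
#' patients still alive (OS-censored), the usual clinical summary of
#' follow-up maturity. (The reverse-KM alternative, which treats deaths as
#' censorings of follow-up, is not computed here.)
#'
#' @param cohort A cohort data.frame with at least one OS-censored patient.
#' @return Named list with `median`, `q1`, `q3`, `n_censored`.
#' @export
median_followup_censored <- function(cohort) {
  t <- cohort$os_time_years[!cohort$os_event]
  if (length(t) == 0L) stop("no censored patients", call. = FALSE)
  q <- stats::quantile(t, c(0.25, 0.5, 0.75), names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3], n_censored = length(t))
}

#' First-recurrence site table
#'
#' Tabulates first-recurrence sites among patients who recurred after R0 or
#' R1 resection. A patient with simultaneous first recurrence at several
#' sites counts once per site, so percentages (of recurrent patients) may sum
#' to more than 100. Also reports the fraction of recurrences occurring
#' within 2 years of surgery.
#'
#' @param cohort A cohort data.frame.
#' @return List with `table` (data.frame: site, count, pct), `n_recurrent`,
#'   and `pct_within_2y`. All percentages rounded half-up to one decimal.
#' @export
recurrence_table <- function(cohort) {
  rec <- !is.na(cohort$recurrence_time_years) &
    cohort$residual %in% c("R0", "R1")
  n_rec <- sum(rec)
  if (n_rec == 0L)
    return(list(table = data.frame(site = character(), count = integer(),
                                   pct = numeric(), stringsAsFactors = FALSE),
                n_recurrent = 0L, pct_within_2y = NA_real_))
  site_lists <- strsplit(cohort$recurrence_sites[rec], ";", fixed = TRUE)
  counts <- table(factor(unlist(site_lists),
                         levels = .recurrence_sites_levels()))
  counts <- counts[counts > 0]
  tab <- data.frame(site = names(counts), count = as.integer(counts),
                    pct = round_half_up(100 * as.integer(counts) / n_rec, 1),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$count, tab$site), , drop = FALSE]
  rownames(tab) <- NULL
  within2 <- sum(cohort$recurrence_time_years[rec] <= 2)
  list(table = tab, n_recurrent = n_rec,
       pct_within_2y = round_half_up(100 * within2 / n_rec, 1))
}

#' Multi-site recurrence percentage for a given site
#'
#' Among R0/R1 patients whose first recurrence involves `site`, the count
#' and percentage who simultaneously recurred at at least one other site.
#'
#' @param cohort A cohort data.frame.
#' @param site One of the recurrence-site tokens (e.g.
#'   `"lymph_node_paraaortic"`).
#' @return List with `n_site`, `n_multisite`, `pct_multisite` (half-up, one
#'   decimal; `NA` when no patient recurred at `site`).
#' @export
multisite_recurrence <- function(cohort, site) {
  if (!site %in% .recurrence_sites_levels())
    stop("unknown recurrence site: ", site, call. = FALSE)
  rec <- !is.na(cohort$recurrence_time_years) &
    cohort$residual %in% c("R0", "R1")
  site_lists <- strsplit(cohort$recurrence_sites[rec], ";", fixed = TRUE)
  has_site <- vapply(site_lists, function(s) site %in% s, logical(1))
  multi <- vapply(site_lists, function(s) site %in% s && length(s) > 1,
                  logical(1))
  n_site <- sum(has_site)
  list(n_site = n_site, n_multisite = sum(multi),
       pct_multisite = if (n_site > 0)
         round_half_up(100 * sum(multi) / n_site, 1) else NA_real_)
}

#' Survival after recurrence
#'
#' Kaplan-Meier estimate of survival measured from first recurrence, among
#' R0/R1 patients with a recorded recurrence; the event is death from any
#' cause.
#'
#' @param cohort A cohort data.frame with at least one recurrent patient.
#' @return List with `curve` (a `km_curve`), `median` (`NA` when not
#'   reached), and `n_recurrent`.
#' @export
survival_after_recurrence <- function(cohort) {
  rec <- !is.na(cohort$recurrence_time_years) &
    cohort$residual %in% c("R0", "R1")
  if (!any(rec)) stop("no recurrent patients", call. = FALSE)
  dt <- cohort$os_time_years[rec] - cohort$recurrence_time_years[rec]
  if (any(dt < -1e-9))
    stop("recurrence_time_years exceeds os_time_years; run validate_cohort()",
         call. = FALSE)
  curve <- km_estimate(pmax(dt, 0), cohort$os_event[rec])
  list(curve = curve, median = km_median(curve), n_recurrent = sum(rec))
}
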