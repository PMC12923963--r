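# Therapeutic efficacy index engine.
#
# TEI of a station = (metastasis rate at the station) x (5-year OS or RFS
# rate among the patients with metastasis at that station) x 100: the
# expected percentage-point gain in 5-year survival attributable to
# dissecting the station. The metastasis rate denominator is the set of
# eligible patients in whom the station was actually dissected, with two
# protocol-driven restrictions: upper/middle mediastinal stations are
# assessed only in right-transthoracic subtotal-esophagectomy patients, and
# left-greater-curvature / distal-perigastric stations only in
# total-gastrectomy patients.

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact interval obtained by inverting binomial tail tests, computed via
#' the beta-quantile closed form. The lower bound is 0 when `k = 0` and the
#' upper bound is 1 when `k = n`.
#'
#' @param k Number of successes (vectorized).
#' @param n Number of trials.
#' @param level Confidence level.
#' @return For scalar input, named vector `c(low, high)`; for vector input a
#'   two-column matrix.
#' @export
#' @examples
#' clopper_pearson(0, 10)   # upper bound 1 - 0.025^(1/10) = 0.3085
#' clopper_pearson(15, 100)
clopper_pearson <- function(k, n, level = 0.95) {
  if (any(n < 1) || any(k < 0) || any(k > n))
    stop("require 0 <= k <= n and n >= 1", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  a <- (1 - level) / 2
  low <- ifelse(k == 0, 0, stats::qbeta(a, k, n - k + 1))
  high <- ifelse(k == n, 1, stats::qbeta(1 - a, k + 1, n - k))
  if (length(k) == 1L && length(n) == 1L) c(low = low, high = high)
  else cbind(low = low, high = high)
}

#' TEI-eligible subset of a cohort
#'
#' Patients entering the TEI analysis: R0 or R1 resection, excluding those
#' lost to follow-up within 5 years without confirmation of recurrence. A
#' patient censored for OS before 5 years but with a documented recurrence
#' within 5 years is retained (the recurrence is confirmed, so the patient
#' is not "lost without confirmation of recurrence").
#'
#' @param cohort A cohort data.frame.
#' @param r0_only If `TRUE`, restrict to R0 resections (sensitivity
#'   analysis).
#' @return The eligible subset of `cohort`.
#' @export
tei_eligible <- function(cohort, r0_only = FALSE) {
  keep_res <- if (r0_only) "R0" else c("R0", "R1")
  resected <- cohort$residual %in% keep_res
  os_lost <- five_year_status(cohort, "os") == "lost_before_5y"
  confirmed_rec <- cohort$rfs_event & cohort$rfs_time_years <= 5
  cohort[resected & !(os_lost & !confirmed_rec), , drop = FALSE]
}

#' Station denominator
#'
#' Subset of eligible patients contributing to a station's metastasis-rate
#' denominator: those in whom the station was dissected, additionally
#' restricted to right-transthoracic subtotal-esophagectomy patients for
#' upper/middle mediastinal stations and to total-gastrectomy patients for
#' left-greater-curvature and distal-perigastric stations.
#'
#' @param eligible Eligible subset (see [tei_eligible()]).
#' @param station Station code.
#' @return The denominator subset of `eligible`.
#' @export
station_denominator <- function(eligible, station) {
  region <- station_region(station)
  keep <- isTRUE_vec(eligible[[paste0("dissected_", station)]])
  if (region %in% c("upper_mediastinal", "middle_mediastinal"))
    keep <- keep & eligible$approach == "right_transthoracic" &
      eligible$esophagectomy == "subtotal"
  if (region %in% c("left_greater_curvature", "distal_perigastric"))
    keep <- keep & eligible$gastrectomy == "total"
  eligible[keep, , drop = FALSE]
}

#' Threshold classification of a station's TEI pair
#'
#' A station qualifies on the OS axis when its 5-year-OS TEI strictly
#' exceeds 3 and on the RFS axis when its 5-year-RFS TEI strictly exceeds 2.
#'
#' @param tei_os,tei_rfs TEI values in percentage points (vectorized).
#' @return Character vector: `"both_exceed"`, `"single_exceed"` or
#'   `"neither"` (`NA` where either input is `NA`).
#' @export
#' @examples
#' classify_tei(17.6, 13.8)  # both_exceed
#' classify_tei(3.0, 2.0)    # neither (strict thresholds)
classify_tei <- function(tei_os, tei_rfs) {
  os_hit <- tei_os > 3
  rfs_hit <- tei_rfs > 2
  ifelse(is.na(os_hit) | is.na(rfs_hit), NA_character_,
         ifelse(os_hit & rfs_hit, "both_exceed",
                ifelse(os_hit | rfs_hit, "single_exceed", "neither")))
}

#' TEI for one station
#'
#' Computes the station's denominator, metastasis count and rate with
#' Clopper-Pearson 95% CI, the 5-year OS and RFS survivor counts among
#' metastatic patients (simple proportions -- eligibility guarantees
#' adequate follow-up), and the TEI for both endpoints, rounded half-up to
#' one decimal on the percentage-point scale. A station with no metastases
#' has TEI 0; a station with an empty denominator is flagged not evaluable.
#'
#' @param eligible Eligible subset (see [tei_eligible()]).
#' @param station Station code.
#' @param level Confidence level for the metastasis-rate CI.
#' @return One-row data.frame: `station`, `region`, `n` (denominator),
#'   `n_metastatic`, `metastasis_rate`, `ci_low`, `ci_high`,
#'   `n_survivor_5y_os`, `n_survivor_5y_rfs`, `tei_os`, `tei_rfs`,
#'   `classification`, `evaluable`.
#' @export
#' @examples
#' cohort <- fixture_station_cohort("108", 45, 5, 3,
#'                                  esophageal_involvement_cm = 3.5)
#' station_tei(tei_eligible(cohort), "108")
station_tei <- function(eligible, station, level = 0.95) {
  denom <- station_denominator(eligible, station)
  n <- nrow(denom)
  if (n == 0L) {
    return(data.frame(station = station, region = station_region(station),
                      n = 0L, n_metastatic = 0L, metastasis_rate = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_,
                      n_survivor_5y_os = NA_integer_,
                      n_survivor_5y_rfs = NA_integer_,
                      tei_os = NA_real_, tei_rfs = NA_real_,
                      classification = NA_character_, evaluable = FALSE,
                      stringsAsFactors = FALSE))
  }
  met <- isTRUE_vec(denom[[paste0("metastatic_", station)]])
  m <- sum(met)
  rate <- m / n
  ci <- clopper_pearson(m, n, level)

  tei_for <- function(endpoint) {
    if (m == 0L) return(list(surv = 0L, tei = 0))
    surv <- sum(five_year_status(denom[met, , drop = FALSE], endpoint)
                == "survivor")
    list(surv = surv, tei = round_half_up(100 * rate * surv / m, 1))
  }
  os <- tei_for("os")
  rfs <- tei_for("rfs")

  data.frame(station = station, region = station_region(station),
             n = n, n_metastatic = m, metastasis_rate = rate,
             ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
             n_survivor_5y_os = os$surv, n_survivor_5y_rfs = rfs$surv,
             tei_os = os$tei, tei_rfs = rfs$tei,
             classification = classify_tei(os$tei, rfs$tei),
             evaluable = TRUE, stringsAsFactors = FALSE)
}

#' TEI table over stations
#'
#' [station_tei()] applied to a set of stations, ordered by anatomical
#' region in report order.
#'
#' @param eligible Eligible subset (see [tei_eligible()]).
#' @param stations Station codes (default: all 26).
#' @param level Confidence level for metastasis-rate CIs.
#' @return Data.frame with one row per station.
#' @export
tei_table <- function(eligible, stations = station_codes(), level = 0.95) {
  rows <- lapply(stations, function(s) station_tei(eligible, s, level))
  out <- do.call(rbind, rows)
  out <- out[order(match(out$region, .region_report_order),
                   match(out$station, station_codes())), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# esophageal-involvement bins; upper/middle mediastinal stations use the
# coarse 2-bin split (their denominators are small), lower mediastinal and
# abdominal stations the 4-bin split. Half-open on the left, closed on the
# right, matching labels like "1.1-2.0" for lengths recorded to one decimal.
.involvement_bins <- function(x, region) {
  if (region %in% c("upper_mediastinal", "middle_mediastinal")) {
    cut(x, breaks = c(-Inf, 3, Inf), labels = c("<=3.0cm", ">3.0cm"))
  } else {
    cut(x, breaks = c(-Inf, 1, 2, 3, Inf),
        labels = c("<=1.0cm", "1.1-2.0cm", "2.1-3.0cm", ">3.0cm"))
  }
}

.stratifiers <- c("esophageal_involvement_bins", "histology", "neoadjuvant",
                  "adjuvant", "cN_upper_middle")

#' Stratified TEI table
#'
#' Recomputes station TEIs inside strata of a patient-level factor.
#' Denominators are re-derived within each stratum. The
#' `esophageal_involvement_bins` stratifier uses two bins (at 3 cm) for
#' upper/middle mediastinal stations and four bins (at 1, 2 and 3 cm) for
#' all other stations; the remaining stratifiers are `histology`
#' (adenocarcinoma vs squamous cell carcinoma), `neoadjuvant`, `adjuvant`
#' and `cN_upper_middle` (clinical upper/middle mediastinal nodal status).
#' Patients with a missing stratifier value are dropped; their count is
#' attached as attribute `n_excluded`.
#'
#' @param eligible Eligible subset (see [tei_eligible()]).
#' @param stratifier One of
#'   `"esophageal_involvement_bins"`, `"histology"`, `"neoadjuvant"`,
#'   `"adjuvant"`, `"cN_upper_middle"`.
#' @param stations Station codes (default: all 26).
#' @param level Confidence level for metastasis-rate CIs.
#' @return Data.frame with one row per station x stratum (columns of
#'   [station_tei()] plus `stratum`). Strata empty for a station appear with
#'   `evaluable = FALSE`.
#' @export
stratified_tei <- function(eligible, stratifier, stations = station_codes(),
                           level = 0.95) {
  if (!stratifier %in% .stratifiers)
    stop("unknown stratifier: ", stratifier, "; choose one of ",
         paste(.stratifiers, collapse = ", "), call. = FALSE)

  strat_values <- function(region) {
    switch(stratifier,
      esophageal_involvement_bins =
        .involvement_bins(eligible$esophageal_involvement_cm, region),
      histology = factor(eligible$histology,
                         levels = c("adenocarcinoma", "scc")),
      neoadjuvant = factor(ifelse(eligible$neoadjuvant, "yes", "no"),
                           levels = c("no", "yes")),
      adjuvant = factor(ifelse(eligible$adjuvant, "yes", "no"),
                        levels = c("no", "yes")),
      cN_upper_middle = factor(ifelse(eligible$cN_upper_middle_mediastinal,
                                      "cN_positive", "cN_negative"),
                               levels = c("cN_negative", "cN_positive")))
  }

  n_excluded <- 0L
  rows <- list()
  for (s in stations) {
    f <- strat_values(station_region(s))
    n_excluded <- max(n_excluded, sum(is.na(f)))
    for (lev in levels(f)) {
      sub <- eligible[!is.na(f) & f == lev, , drop = FALSE]
      r <- station_tei(sub, s, level)
      r$stratum <- lev
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("station", "region", "stratum",
                 setdiff(names(out), c("station", "region", "stratum")))]
  out <- out[order(match(out$region, .region_report_order),
                   match(out$station, station_codes())), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stratifier") <- stratifier
  attr(out, "n_excluded") <- n_excluded
  out
}
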