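# Cohort model: screening-flow accounting, patient-record construction and
# invariant validation.
#
# A cohort is an ordinary data.frame, one row per patient, with the scalar
# fields of cohort_columns() plus logical dissected_<code> / metastatic_<code>
# columns for each of the 26 stations. Multiple first-recurrence sites are
# stored as a single semicolon-separated string (NA when no recurrence).

#' Screening flow counts
#'
#' Accounting of a prospective study's patient flow from screening to the
#' eligible analysis population.
#'
#' @param screened Number of patients screened.
#' @param ineligible_at_screening Screened patients not meeting eligibility
#'   criteria.
#' @param declined Screened patients declining consent.
#' @param withdrew_consent Enrolled patients who later withdrew consent.
#' @param ineligible_post_enrollment Enrolled patients found ineligible after
#'   enrollment.
#' @return An object of class `screening_flow`.
#' @export
#' @examples
#' fl <- screening_flow(1065, 584, 110, 2, 6)
#' enrolled_count(fl)  # 371
#' eligible_count(fl)  # 363
screening_flow <- function(screened, ineligible_at_screening = 0, declined = 0,
                           withdrew_consent = 0, ineligible_post_enrollment = 0) {
  counts <- c(screened = screened,
              ineligible_at_screening = ineligible_at_screening,
              declined = declined,
              withdrew_consent = withdrew_consent,
              ineligible_post_enrollment = ineligible_post_enrollment)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("screening-flow counts must be non-negative integers", call. = FALSE)
  if (screened < ineligible_at_screening + declined)
    stop("screened must be at least ineligible_at_screening + declined",
         call. = FALSE)
  structure(as.list(counts), class = "screening_flow")
}

#' @export
print.screening_flow <- function(x, ...) {
  cat("Screening flow:\n")
  cat("  screened                  ", x$screened, "\n")
  cat("  ineligible at screening   ", x$ineligible_at_screening, "\n")
  cat("  declined consent          ", x$declined, "\n")
  cat("  enrolled                  ", enrolled_count(x), "\n")
  cat("  withdrew consent          ", x$withdrew_consent, "\n")
  cat("  ineligible post-enrollment", x$ineligible_post_enrollment, "\n")
  cat("  eligible                  ", eligible_count(x), "\n")
  invisible(x)
}

#' Number of patients enrolled
#'
#' Screened minus ineligible-at-screening minus declined.
#'
#' @param flow A [screening_flow()] object.
#' @return Integer count.
#' @export
enrolled_count <- function(flow) {
  stopifnot(inherits(flow, "screening_flow"))
  n <- flow$screened - flow$ineligible_at_screening - flow$declined
  if (n < 0) stop("invalid screening flow: negative enrolled count", call. = FALSE)
  as.integer(n)
}

#' Number of eligible patients
#'
#' Enrolled minus post-enrollment withdrawals and ineligibilities.
#'
#' @inheritParams enrolled_count
#' @return Integer count.
#' @export
eligible_count <- function(flow) {
  n <- enrolled_count(flow) - flow$withdrew_consent - flow$ineligible_post_enrollment
  if (n < 0) stop("invalid screening flow: negative eligible count", call. = FALSE)
  as.integer(n)
}

#' Skeleton cohort
#'
#' A consistent cohort of `n` placeholder patients (Siewert II adenocarcinoma,
#' transhiatal lower esophagectomy with proximal gastrectomy, R0, no
#' dissection, censored alive at 6 years). Useful as a starting point for
#' constructing fixtures; every invariant checked by [validate_cohort()]
#' holds.
#'
#' @param n Number of patients.
#' @return A cohort data.frame.
#' @export
new_cohort <- function(n) {
  stopifnot(n >= 0)
  d <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    histology = rep("adenocarcinoma", n),
    siewert = rep("II", n),
    esophageal_involvement_cm = rep(0, n),
    gastric_involvement_cm = rep(0, n),
    cT = rep("T3", n),
    cN_upper_middle_mediastinal = rep(FALSE, n),
    neoadjuvant = rep(FALSE, n),
    adjuvant = rep(FALSE, n),
    approach = rep("transhiatal", n),
    esophagectomy = rep("lower", n),
    gastrectomy = rep("proximal_or_upper", n),
    residual = rep("R0", n),
    os_time_years = rep(6, n),
    os_event = rep(FALSE, n),
    rfs_time_years = rep(6, n),
    rfs_event = rep(FALSE, n),
    recurrence_sites = rep(NA_character_, n),
    recurrence_time_years = rep(NA_real_, n),
    stringsAsFactors = FALSE
  )
  for (col in .dissected_cols()) d[[col]] <- rep(FALSE, n)
  for (col in .metastatic_cols()) d[[col]] <- rep(FALSE, n)
  d
}

# allowed factor levels for categorical cohort fields
.cohort_levels <- list(
  histology = c("adenocarcinoma", "scc"),
  siewert = c("I", "II", "III", "not_applicable"),
  cT = c("T2", "T3", "T4"),
  approach = c("transhiatal", "right_transthoracic", "left_transthoracic",
               "laparotomy_only"),
  esophagectomy = c("subtotal", "lower", "none"),
  gastrectomy = c("proximal_or_upper", "total", "none"),
  residual = c("R0", "R1", "R2", "no_resection")
)

#' Validate a cohort against its structural invariants
#'
#' Checks every patient record for internal consistency and returns a report
#' (not an error): metastasis recorded only in dissected stations, RFS time
#' not exceeding OS time, death without recurrence counted as an RFS event,
#' recurrence sites present exactly when a recurrence time is present (and
#' then flagged as an RFS event), Siewert type `not_applicable` if and only
#' if histology is squamous cell carcinoma, non-negative times and lengths,
#' and known categorical levels.
#'
#' @param cohort A cohort data.frame.
#' @return A data.frame with columns `patient_id`, `rule`, `detail`; zero
#'   rows when the cohort is clean.
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols) > 0L)
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  out <- list()
  flag <- function(idx, rule, detail) {
    if (any(idx)) {
      out[[length(out) + 1L]] <<- data.frame(
        patient_id = cohort$patient_id[idx], rule = rule,
        detail = if (length(detail) == 1L) rep(detail, sum(idx)) else detail[idx],
        stringsAsFactors = FALSE)
    }
  }

  for (s in station_codes()) {
    bad <- isTRUE_vec(cohort[[paste0("metastatic_", s)]]) &
      !isTRUE_vec(cohort[[paste0("dissected_", s)]])
    flag(bad, "metastasis_without_dissection",
         paste0("station ", s, " metastatic but not dissected"))
  }

  flag(cohort$rfs_time_years > cohort$os_time_years + 1e-9,
       "rfs_exceeds_os", "rfs_time_years > os_time_years")

  no_rec <- is.na(cohort$recurrence_time_years)
  flag(cohort$os_event & no_rec & !cohort$rfs_event,
       "death_without_rfs_event",
       "death without recurrence must be an RFS event")

  has_sites <- !is.na(cohort$recurrence_sites) & nzchar(cohort$recurrence_sites)
  flag(has_sites != !no_rec, "recurrence_site_time_mismatch",
       "recurrence_sites present iff recurrence_time_years present")
  flag(!no_rec & !cohort$rfs_event, "recurrence_without_rfs_event",
       "recurrence recorded but rfs_event is FALSE")
  flag(!no_rec & cohort$recurrence_time_years > cohort$os_time_years + 1e-9,
       "recurrence_after_os_time", "recurrence_time_years > os_time_years")

  flag((cohort$histology == "scc") != (cohort$siewert == "not_applicable"),
       "siewert_histology_mismatch",
       "siewert must be not_applicable iff histology is scc")

  for (col in c("esophageal_involvement_cm", "gastric_involvement_cm",
                "os_time_years", "rfs_time_years")) {
    flag(!is.finite(cohort[[col]]) | cohort[[col]] < 0,
         "negative_or_missing_value", paste0(col, " must be a non-negative number"))
  }

  for (col in names(.cohort_levels)) {
    bad <- !(cohort[[col]] %in% .cohort_levels[[col]])
    flag(bad, "unknown_level",
         paste0(col, " value '", cohort[[col]], "' not recognized"))
  }
  if (any(has_sites)) {
    sites <- strsplit(cohort$recurrence_sites[has_sites], ";", fixed = TRUE)
    bad_sites <- vapply(sites, function(s)
      length(setdiff(s, .recurrence_sites_levels())) > 0, logical(1))
    idx <- which(has_sites)[bad_sites]
    v <- rep(FALSE, nrow(cohort)); v[idx] <- TRUE
    flag(v, "unknown_recurrence_site", "unrecognized recurrence site token")
  }

  if (length(out) == 0L)
    return(data.frame(patient_id = character(), rule = character(),
                      detail = character(), stringsAsFactors = FALSE))
  rep <- do.call(rbind, out)
  rownames(rep) <- NULL
  rep
}

# treat NA as FALSE for logical indicator columns
isTRUE_vec <- function(x) !is.na(x) & x

#' Format a validation report as tab-separated lines
#'
#' One violation per line: `patient_id<TAB>rule<TAB>detail`.
#'
#' @param report Output of [validate_cohort()].
#' @return Character vector of lines (empty for a clean cohort).
#' @export
format_validation <- function(report) {
  if (nrow(report) == 0L) return(character())
  paste(report$patient_id, report$rule, report$detail, sep = "\t")
}

#' Construct a worked-example cohort for one station
#'
#' Builds a fully consistent cohort in which every patient is in the
#' denominator of `station` (dissected, with the surgical profile the
#' denominator restriction requires), `n_metastatic` patients have pathologic
#' metastasis at that station, and `n_survivor_5y` of those are alive at 5
#' years. All patients are followed at least 5 years (survivors censored
#' alive at 6 years; the remaining metastatic patients recur at 1.5 years and
#' die at 2), so the TEI decomposes exactly as
#' `100 * n_survivor_5y / n` for the OS endpoint.
#'
#' @param station Station code.
#' @param n Denominator size.
#' @param n_metastatic Number of patients with metastasis at `station`.
#' @param n_survivor_5y Number of metastatic patients alive at 5 years.
#' @param esophageal_involvement_cm Esophageal involvement assigned to every
#'   patient (controls stratification bins).
#' @param neoadjuvant,adjuvant Treatment flags assigned to every patient.
#' @param histology `"adenocarcinoma"` or `"scc"`.
#' @return A cohort data.frame of `n` patients.
#' @export
#' @examples
#' cohort <- fixture_station_cohort("108", n = 45, n_metastatic = 5,
#'                                  n_survivor_5y = 3,
#'                                  esophageal_involvement_cm = 3.5)
#' station_tei(tei_eligible(cohort), "108")$tei_os  # 6.7
fixture_station_cohort <- function(station, n, n_metastatic, n_survivor_5y,
                                   esophageal_involvement_cm = 2.5,
                                   neoadjuvant = FALSE, adjuvant = FALSE,
                                   histology = "adenocarcinoma") {
  stopifnot(n_metastatic <= n, n_survivor_5y <= n_metastatic)
  region <- station_region(station)
  d <- new_cohort(n)
  d$esophageal_involvement_cm <- esophageal_involvement_cm
  d$neoadjuvant <- neoadjuvant
  d$adjuvant <- adjuvant
  d$histology <- histology
  if (histology == "scc") d$siewert <- "not_applicable"

  mediastinal_um <- region %in% c("upper_mediastinal", "middle_mediastinal")
  if (mediastinal_um || histology == "scc" || esophageal_involvement_cm > 3) {
    d$approach <- "right_transthoracic"
    d$esophagectomy <- "subtotal"
  }
  if (region %in% c("left_greater_curvature", "distal_perigastric"))
    d$gastrectomy <- "total"

  # protocol dissection fields for the assigned surgery
  for (s in .core_dissection_set) d[[paste0("dissected_", s)]] <- TRUE
  if (d$approach[1] == "right_transthoracic")
    for (s in .rt_extra_set) d[[paste0("dissected_", s)]] <- TRUE
  if (d$gastrectomy[1] == "total")
    for (s in .total_gastrectomy_extra_set) d[[paste0("dissected_", s)]] <- TRUE
  d[[paste0("dissected_", station)]] <- TRUE

  met <- seq_len(n) <= n_metastatic
  d[[paste0("metastatic_", station)]] <- met

  # metastatic non-survivors: recurrence at 1.5y, death at 2y
  dead <- met & seq_len(n) > n_survivor_5y
  d$os_time_years[dead] <- 2
  d$os_event[dead] <- TRUE
  d$rfs_time_years[dead] <- 1.5
  d$rfs_event[dead] <- TRUE
  d$recurrence_sites[dead] <- "other"
  d$recurrence_time_years[dead] <- 1.5
  d
}
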