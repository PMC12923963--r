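# Small shared helpers.

#' Round half-up
#'
#' Decimal rounding with ties away from zero, matching the convention of
#' clinical report tables (so 2.25 -> 2.3 at one decimal, unlike banker's
#' rounding).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(2.25, 6.6667), 1)
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  # small epsilon guards against representation error in x * s (e.g. 2.35
  # stored as 2.34999...); values here are ratios of small integers.
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

# column names of the per-station indicator blocks in a cohort data.frame
.dissected_cols <- function() paste0("dissected_", station_codes())
.metastatic_cols <- function() paste0("metastatic_", station_codes())

.scalar_cohort_cols <- function() {
  c("patient_id", "histology", "siewert", "esophageal_involvement_cm",
    "gastric_involvement_cm", "cT", "cN_upper_middle_mediastinal",
    "neoadjuvant", "adjuvant", "approach", "esophagectomy", "gastrectomy",
    "residual", "os_time_years", "os_event", "rfs_time_years", "rfs_event",
    "recurrence_sites", "recurrence_time_years")
}

#' Cohort column names
#'
#' Full column set of the patient-level cohort table: scalar fields followed
#' by `dissected_<code>` and `metastatic_<code>` indicator columns for the 26
#' stations.
#'
#' @return Character vector of column names.
#' @export
cohort_columns <- function() {
  c(.scalar_cohort_cols(), .dissected_cols(), .metastatic_cols())
}

.recurrence_sites_levels <- function() {
  c("lymph_node_paraaortic", "lymph_node_mediastinal", "lymph_node_other",
    "liver", "peritoneum", "lung", "other")
}
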