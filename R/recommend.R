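# Dissection/approach recommendation engine.
#
# Encodes the threshold-based algorithm derived from the TEI analysis:
# proximal perigastric and suprapancreatic stations are always dissected;
# left greater curvature, distal perigastric and paraaortic stations are
# avoided; lower mediastinal dissection is added when esophageal involvement
# exceeds 2 cm and middle mediastinal when it exceeds 3 cm; upper mediastinal
# dissection is conditional, considered only for patients with clinical
# nodal positivity in the upper/middle mediastinal field or without
# neoadjuvant chemotherapy. Approach: transhiatal suffices at <= 2 cm without
# mediastinal cN+; right transthoracic is required above 3 cm or with
# mediastinal cN+; between 2 and 3 cm either approach is acceptable.
# Histology does not alter the recommendation.

#' Recommend surgical approach and dissection extent
#'
#' @param esophageal_involvement_cm Esophageal involvement length in cm
#'   (measured after neoadjuvant chemotherapy when it was given).
#' @param cN_upper_middle_mediastinal Clinical nodal positivity in the
#'   upper or middle mediastinal field.
#' @param neoadjuvant Whether neoadjuvant chemotherapy was given.
#' @param include_11d Keep station 11d in the always-dissect suprapancreatic
#'   group. The suprapancreatic field is recommended as a whole although 11d
#'   individually falls below both TEI thresholds; set `FALSE` to drop it.
#' @return An object of class `dissection_recommendation`: list with
#'   `approaches` (subset of `c("transhiatal", "right_transthoracic")`),
#'   `dissect_always`, `dissect_conditional`, `condition`,
#'   `condition_met`, `avoid`, `gastrectomy`, and the input `profile`.
#' @export
#' @examples
#' recommend_dissection(1.5)                      # transhiatal, no mediastinum
#' recommend_dissection(3.5, neoadjuvant = TRUE)  # RT, middle+lower mediastinal
recommend_dissection <- function(esophageal_involvement_cm,
                                 cN_upper_middle_mediastinal = FALSE,
                                 neoadjuvant = FALSE,
                                 include_11d = TRUE) {
  inv <- esophageal_involvement_cm
  if (!is.finite(inv) || inv < 0)
    stop("esophageal_involvement_cm must be a non-negative number",
         call. = FALSE)
  cn <- isTRUE(cN_upper_middle_mediastinal)

  always <- c(stations_in_region("proximal_perigastric"),
              stations_in_region("suprapancreatic"))
  if (!include_11d) always <- setdiff(always, "11d")
  if (inv > 2) always <- c(always, stations_in_region("lower_mediastinal"))
  if (inv > 3) always <- c(always, stations_in_region("middle_mediastinal"))

  conditional <- character()
  condition_met <- NA
  if (inv > 3 || cn) {
    conditional <- stations_in_region("upper_mediastinal")
    condition_met <- cn || !isTRUE(neoadjuvant)
  }

  avoid <- c(stations_in_region("left_greater_curvature"),
             stations_in_region("distal_perigastric"),
             stations_in_region("paraaortic"))

  approaches <- if (inv > 3 || cn) "right_transthoracic"
  else if (inv <= 2) "transhiatal"
  else c("transhiatal", "right_transthoracic")

  structure(list(
    approaches = approaches,
    dissect_always = always,
    dissect_conditional = conditional,
    condition = if (length(conditional) > 0L)
      "cN+ in upper/middle mediastinum OR no neoadjuvant chemotherapy"
    else NA_character_,
    condition_met = condition_met,
    avoid = avoid,
    gastrectomy = "proximal_preferred",
    profile = list(esophageal_involvement_cm = inv,
                   cN_upper_middle_mediastinal = cn,
                   neoadjuvant = isTRUE(neoadjuvant))),
    class = "dissection_recommendation")
}

#' Stations effectively dissected under a recommendation
#'
#' The always-dissect set plus the conditional set when its condition is
#' met for the given profile.
#'
#' @param rec A [recommend_dissection()] result.
#' @return Character vector of station codes.
#' @export
stations_to_dissect <- function(rec) {
  stopifnot(inherits(rec, "dissection_recommendation"))
  out <- rec$dissect_always
  if (length(rec$dissect_conditional) > 0L && isTRUE(rec$condition_met))
    out <- c(out, rec$dissect_conditional)
  out
}

#' @export
print.dissection_recommendation <- function(x, ...) {
  p <- x$profile
  cat(sprintf(
    "Tumor profile: esophageal involvement %.1f cm, mediastinal cN%s, %s\n",
    p$esophageal_involvement_cm,
    if (p$cN_upper_middle_mediastinal) "+" else "0",
    if (p$neoadjuvant) "neoadjuvant chemotherapy" else "no neoadjuvant chemotherapy"))
  cat("Approach:", paste(x$approaches, collapse = " or "), "\n")
  cat("Dissect: ", paste(x$dissect_always, collapse = ", "), "\n")
  if (length(x$dissect_conditional) > 0L) {
    cat("Conditional (", x$condition, "):\n  ",
        paste(x$dissect_conditional, collapse = ", "),
        if (isTRUE(x$condition_met)) " [condition met]"
        else " [condition not met]", "\n", sep = "")
  }
  cat("Avoid:   ", paste(x$avoid, collapse = ", "), "\n")
  cat("Gastrectomy: proximal preferred (total only if distal margin inadequate)\n")
  invisible(x)
}

#' Machine-readable key-value rendering of a recommendation
#'
#' @param rec A [recommend_dissection()] result.
#' @return Character vector of `key=value` lines.
#' @export
recommendation_keyvalues <- function(rec) {
  stopifnot(inherits(rec, "dissection_recommendation"))
  c(paste0("approaches=", paste(rec$approaches, collapse = ",")),
    paste0("dissect_always=", paste(rec$dissect_always, collapse = ",")),
    paste0("dissect_conditional=",
           paste(rec$dissect_conditional, collapse = ",")),
    paste0("condition_met=", ifelse(is.na(rec$condition_met), "NA",
                                    tolower(rec$condition_met))),
    paste0("avoid=", paste(rec$avoid, collapse = ",")),
    paste0("gastrectomy=", rec$gastrectomy))
}
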