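# Lymph-node station catalog for EGJ cancer surgery.
#
# Codes follow the Japanese Classification of Gastric Carcinoma (abdominal
# stations 1-20, 16a2) and the Japanese Classification of Esophageal Cancer
# (mediastinal stations 105-112). Exactly 26 stations are modelled; each
# belongs to exactly one anatomical region.

.station_region_map <- c(
  "1"    = "proximal_perigastric",
  "2"    = "proximal_perigastric",
  "3"    = "proximal_perigastric",
  "7"    = "proximal_perigastric",
  "4sa"  = "left_greater_curvature",
  "4sb"  = "left_greater_curvature",
  "4d"   = "distal_perigastric",
  "5"    = "distal_perigastric",
  "6"    = "distal_perigastric",
  "8a"   = "suprapancreatic",
  "9"    = "suprapancreatic",
  "11p"  = "suprapancreatic",
  "11d"  = "suprapancreatic",
  "19"   = "abdominal_hiatal",
  "20"   = "abdominal_hiatal",
  "16a2" = "paraaortic",
  "105"  = "upper_mediastinal",
  "106L" = "upper_mediastinal",
  "106R" = "upper_mediastinal",
  "107"  = "middle_mediastinal",
  "108"  = "middle_mediastinal",
  "109L" = "middle_mediastinal",
  "109R" = "middle_mediastinal",
  "110"  = "lower_mediastinal",
  "111"  = "lower_mediastinal",
  "112"  = "lower_mediastinal"
)

# Region ordering used when rendering report tables: mediastinal fields first
# (cranial to caudal), then abdominal fields.
.region_report_order <- c(
  "upper_mediastinal", "middle_mediastinal", "lower_mediastinal",
  "proximal_perigastric", "left_greater_curvature", "distal_perigastric",
  "suprapancreatic", "abdominal_hiatal", "paraaortic"
)

# Station sets used by the study protocol and the recommendation engine.
# All surgical approaches dissect the core field; the right transthoracic
# approach additionally dissects the upper/middle mediastinum; total
# gastrectomy additionally clears the left greater curvature and distal
# perigastric stations.
.core_dissection_set <- c("1", "2", "3", "7", "8a", "9", "11p", "11d",
                          "16a2", "19", "20", "110", "111", "112")
.rt_extra_set <- c("105", "106L", "106R", "107", "108", "109L", "109R")
.total_gastrectomy_extra_set <- c("4sa", "4sb", "4d", "5", "6")

#' Lymph-node station codes
#'
#' The closed set of 26 station codes used throughout the package.
#'
#' @return Character vector of 26 station codes.
#' @export
#' @examples
#' station_codes()
station_codes <- function() names(.station_region_map)

#' Anatomical region names
#'
#' @param report_order If `TRUE`, regions are returned in the order used for
#'   report tables (upper mediastinal first, paraaortic last); otherwise in
#'   catalog order.
#' @return Character vector of 9 region names.
#' @export
region_names <- function(report_order = FALSE) {
  if (report_order) .region_report_order else unique(unname(.station_region_map))
}

#' Station catalog
#'
#' One row per station with its anatomical region, ordered by region in the
#' report ordering.
#'
#' @return A data.frame with columns `code` and `region`.
#' @export
#' @examples
#' head(station_catalog())
station_catalog <- function() {
  d <- data.frame(code = station_codes(),
                  region = unname(.station_region_map),
                  stringsAsFactors = FALSE)
  d[order(match(d$region, .region_report_order)), , drop = FALSE]
}

#' Map a station code to its anatomical region
#'
#' @param code Character vector of station codes.
#' @return Character vector of region names, same length as `code`.
#' @export
#' @examples
#' station_region("106L")  # "upper_mediastinal"
#' station_region(c("4sa", "16a2"))
station_region <- function(code) {
  code <- as.character(code)
  bad <- setdiff(code, station_codes())
  if (length(bad) > 0L)
    stop("unknown station code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  unname(.station_region_map[code])
}

#' Stations belonging to a region
#'
#' @param region Character vector of region names.
#' @return Character vector of station codes.
#' @export
#' @examples
#' stations_in_region("lower_mediastinal")
stations_in_region <- function(region) {
  bad <- setdiff(region, region_names())
  if (length(bad) > 0L)
    stop("unknown region(s): ", paste(bad, collapse = ", "), call. = FALSE)
  names(.station_region_map)[.station_region_map %in% region]
}
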