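# Cohort CSV input/output and report rendering.
#
# CSV dialect: comma-separated, UTF-8, mandatory header, "." decimal
# separator, booleans serialized 0/1, missing numeric fields as empty cells,
# multiple recurrence sites joined with ";".

.bool_cols <- function() {
  c("cN_upper_middle_mediastinal", "neoadjuvant", "adjuvant", "os_event",
    "rfs_event", .dissected_cols(), .metastatic_cols())
}

#' Write a cohort to CSV
#'
#' @param cohort A cohort data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort[, cohort_columns(), drop = FALSE]
  for (col in .bool_cols()) out[[col]] <- as.integer(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Reads the patient-level CSV dialect written by [write_cohort()], checks
#' the header, parses types and runs [validate_cohort()]. Invariant
#' violations are reported as a warning (default) or abort the read
#' (`strict = TRUE`).
#'
#' @param path CSV file path.
#' @param strict Abort on any invariant violation.
#' @return A cohort data.frame with attribute `validation` holding the
#'   validation report.
#' @export
read_cohort <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(patient_id = "character"))
  missing_cols <- setdiff(cohort_columns(), names(d))
  if (length(missing_cols) > 0L)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  d <- d[, cohort_columns(), drop = FALSE]

  for (col in .bool_cols()) {
    v <- d[[col]]
    if (!all(v %in% c(0L, 1L, NA)))
      stop("column ", col, " must contain only 0/1", call. = FALSE)
    d[[col]] <- v == 1L
  }
  for (col in c("esophageal_involvement_cm", "gastric_involvement_cm",
                "os_time_years", "rfs_time_years", "recurrence_time_years")) {
    if (is.logical(d[[col]]) && all(is.na(d[[col]])))
      d[[col]] <- as.numeric(d[[col]])  # empty column read as logical NA
    if (!is.numeric(d[[col]]))
      stop("column ", col, " must be numeric", call. = FALSE)
  }
  if (is.logical(d$recurrence_sites))
    d$recurrence_sites <- as.character(d$recurrence_sites)
  d$recurrence_sites[!is.na(d$recurrence_sites) &
                       !nzchar(d$recurrence_sites)] <- NA_character_

  report <- validate_cohort(d)
  if (nrow(report) > 0L) {
    msg <- paste0(nrow(report), " invariant violation(s); first: ",
                  format_validation(report)[1L])
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  attr(d, "validation") <- report
  d
}

# "os/rfs" cell with one decimal, or an en-dash pair when not evaluable
.tei_cell <- function(tei_os, tei_rfs, evaluable) {
  ifelse(!evaluable | is.na(tei_os), "\u2013/\u2013",
         paste0(formatC(tei_os, format = "f", digits = 1), "/",
                formatC(tei_rfs, format = "f", digits = 1)))
}

#' Render a TEI results table to a file
#'
#' Writes a [tei_table()] or [stratified_tei()] result as CSV or as a
#' markdown table. Stations are grouped by anatomical region in report order
#' (upper, middle, lower mediastinal, then proximal perigastric, left
#' greater curvature, distal perigastric, suprapancreatic, abdominal hiatal,
#' paraaortic). TEI pairs are rendered `os/rfs` to one decimal;
#' non-evaluable cells as an en-dash pair; a marker column flags stations
#' whose TEI exceeds both thresholds (`**`) or a single threshold (`*`).
#' Output is deterministic: the same results produce byte-identical files.
#'
#' @param results Data.frame from [tei_table()] or [stratified_tei()].
#' @param path Output file path.
#' @param format `"csv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
render_report <- function(results, path, format = c("csv", "markdown")) {
  format <- match.arg(format)
  if (nrow(results) == 0L) stop("empty results", call. = FALSE)
  r <- results
  r <- r[order(match(r$region, .region_report_order),
               match(r$station, station_codes())), , drop = FALSE]
  marker <- ifelse(is.na(r$classification), "",
                   c(both_exceed = "**", single_exceed = "*",
                     neither = "")[r$classification])
  cell <- .tei_cell(r$tei_os, r$tei_rfs, r$evaluable)

  if (format == "csv") {
    out <- data.frame(
      station = r$station, region = r$region,
      stratum = if ("stratum" %in% names(r)) r$stratum else "all",
      n = r$n, n_metastatic = r$n_metastatic,
      metastasis_rate = round_half_up(100 * r$metastasis_rate, 1),
      ci_low = round_half_up(100 * r$ci_low, 1),
      ci_high = round_half_up(100 * r$ci_high, 1),
      tei_os = r$tei_os, tei_rfs = r$tei_rfs,
      tei = cell, class = ifelse(is.na(r$classification), "",
                                 r$classification),
      marker = unname(marker), stringsAsFactors = FALSE)
    utils::write.csv(out, path, row.names = FALSE, na = "")
  } else {
    has_stratum <- "stratum" %in% names(r)
    header <- c("station", "region", if (has_stratum) "stratum", "n",
                "n_met", "TEI (OS/RFS)", "flag")
    lines <- c(paste0("| ", paste(header, collapse = " | "), " |"),
               paste0("|", paste(rep("---", length(header)), collapse = "|"),
                      "|"))
    for (i in seq_len(nrow(r))) {
      row <- c(r$station[i], r$region[i],
               if (has_stratum) r$stratum[i],
               r$n[i], r$n_metastatic[i], cell[i], marker[i])
      lines <- c(lines, paste0("| ", paste(row, collapse = " | "), " |"))
    }
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

#' Export a Kaplan-Meier curve as CSV
#'
#' Columns: time, n_at_risk, n_events, survival, ci_low, ci_high.
#'
#' @param curve A [km_estimate()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_km_csv <- function(curve, path) {
  stopifnot(inherits(curve, "km_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
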