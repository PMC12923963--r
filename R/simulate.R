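# Seeded synthetic cohort generator.
#
# Emulates the data structure of a nationwide prospective EGJ-cancer surgical
# cohort: covariate marginals, the protocol rule linking tumor profile to
# surgical approach, approach-determined dissection fields, per-station
# metastasis indicators, and OS/RFS outcomes with administrative censoring
# and sporadic loss to follow-up. Defaults encode the study conditions
# (n = 363 eligible patients, 8.5% SCC, one-third neoadjuvant, minimum
# administrative follow-up above 5 years); per-station metastasis and
# conditional-survival parameters are illustrative since station-level
# survival is not published.

.default_station_base_prob <- c(
  "1" = 0.25, "2" = 0.12, "3" = 0.25, "7" = 0.12,
  "4sa" = 0.02, "4sb" = 0.01,
  "4d" = 0.01, "5" = 0.005, "6" = 0.01,
  "8a" = 0.06, "9" = 0.07, "11p" = 0.08, "11d" = 0.02,
  "19" = 0.02, "20" = 0.03,
  "16a2" = 0.02,
  "105" = 0.01, "106L" = 0.02, "106R" = 0.02,
  "107" = 0.01, "108" = 0.03, "109L" = 0.01, "109R" = 0.01,
  "110" = 0.05, "111" = 0.02, "112" = 0.01
)

.default_surv5_given_met <- function() {
  v <- c(proximal_perigastric = 0.45, suprapancreatic = 0.40,
         abdominal_hiatal = 0.35, left_greater_curvature = 0.20,
         distal_perigastric = 0.20, paraaortic = 0.15,
         upper_mediastinal = 0.30, middle_mediastinal = 0.30,
         lower_mediastinal = 0.30)
  stats::setNames(unname(v[.station_region_map]), names(.station_region_map))
}

#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. Defaults reproduce the
#' marginal structure of the study population: 8.5% squamous cell carcinoma,
#' one-third neoadjuvant chemotherapy, 53.4% adjuvant chemotherapy after
#' R0/R1 resection, esophageal involvement with median 2.0 cm (IQR roughly
#' 1.0-3.0) and gastric involvement with median 2.5 cm (IQR roughly 1.5-3.7)
#' from truncated log-normal distributions, R1/R2 fractions 4.1%/2.5%,
#' clinical upper/middle mediastinal nodal positivity 8.3%, administrative
#' censoring uniform on 5.5-8 years so that every patient not lost to
#' follow-up has at least 5 years of potential observation, and loss to
#' follow-up before 5 years at 1.1%.
#'
#' @param n_patients Cohort size.
#' @param seed Integer seed; the generator is a deterministic function of
#'   `(config, seed)`.
#' @param prop_scc Probability of squamous cell carcinoma histology.
#' @param prop_siewert_I Probability of Siewert type I among adenocarcinomas.
#' @param prop_neoadjuvant Probability of neoadjuvant chemotherapy.
#' @param prop_adjuvant_given_r0r1 Probability of adjuvant chemotherapy among
#'   R0/R1-resected patients.
#' @param eso_meanlog,eso_sdlog Log-normal parameters of esophageal
#'   involvement length (cm).
#' @param gastric_meanlog,gastric_sdlog Log-normal parameters of gastric
#'   involvement length (cm).
#' @param involvement_max_cm Truncation bound for involvement lengths.
#' @param station_base_prob Named vector (all 26 stations) of baseline
#'   metastasis probabilities.
#' @param mediastinal_slope Per-cm log-odds increment applied to mediastinal
#'   stations' metastasis probability as esophageal involvement grows.
#' @param surv5_given_station_met Named vector of conditional 5-year OS
#'   probabilities given metastasis at each station; a patient's survival is
#'   governed by the most favorable of their metastatic stations.
#' @param surv5_node_negative 5-year OS probability without nodal metastasis.
#' @param hazard_shape Weibull shape of the latent death-time distribution.
#' @param admin_censor_years_min,admin_censor_years_max Bounds of uniform
#'   administrative censoring; the minimum must be at least 5 so censoring
#'   before 5 years arises only through loss to follow-up.
#' @param loss_to_followup_prob Probability of loss to follow-up before 5
#'   years.
#' @param prop_cN_upper_middle Probability of clinical nodal positivity in
#'   the upper/middle mediastinal field.
#' @param prop_total_gastrectomy_th Fraction of transhiatal patients who
#'   undergo total (rather than proximal) gastrectomy.
#' @param prop_r1,prop_r2 Probabilities of R1 and R2 residual status.
#' @param prop_recurrence_before_death Fraction of deaths preceded by a
#'   recurrence.
#' @param mean_recurrence_lead_years Mean of the exponential lead time from
#'   recurrence to death.
#' @param site_probs Named per-site probabilities used to draw (possibly
#'   multiple) first-recurrence sites.
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 200, seed = 7)
#' cohort <- simulate_cohort(cfg)
#' nrow(cohort)
sim_config <- function(n_patients = 363,
                       seed = 1L,
                       prop_scc = 0.085,
                       prop_siewert_I = 31 / 332,
                       prop_neoadjuvant = 0.333,
                       prop_adjuvant_given_r0r1 = 0.534,
                       eso_meanlog = log(2),
                       eso_sdlog = log(3) / (2 * stats::qnorm(0.75)),
                       gastric_meanlog = log(2.5),
                       gastric_sdlog = log(3.7 / 1.5) / (2 * stats::qnorm(0.75)),
                       involvement_max_cm = 12,
                       station_base_prob = .default_station_base_prob,
                       mediastinal_slope = 0.35,
                       surv5_given_station_met = .default_surv5_given_met(),
                       surv5_node_negative = 0.80,
                       hazard_shape = 1.2,
                       admin_censor_years_min = 5.5,
                       admin_censor_years_max = 8,
                       loss_to_followup_prob = 0.011,
                       prop_cN_upper_middle = 0.083,
                       prop_total_gastrectomy_th = 0.78,
                       prop_r1 = 15 / 363,
                       prop_r2 = 9 / 363,
                       prop_recurrence_before_death = 0.85,
                       mean_recurrence_lead_years = 1.33,
                       site_probs = c(lymph_node_paraaortic = 0.275,
                                      lymph_node_mediastinal = 0.155,
                                      lymph_node_other = 0.12,
                                      liver = 0.261, peritoneum = 0.218,
                                      lung = 0.211, other = 0.10)) {
  cfg <- as.list(environment())

  probs <- c(prop_scc, prop_siewert_I, prop_neoadjuvant,
             prop_adjuvant_given_r0r1, loss_to_followup_prob,
             prop_cN_upper_middle, prop_total_gastrectomy_th, prop_r1, prop_r2,
             prop_recurrence_before_death, surv5_node_negative,
             unname(station_base_prob), unname(surv5_given_station_met),
             unname(site_probs))
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (prop_r1 + prop_r2 > 1)
    stop("prop_r1 + prop_r2 must not exceed 1", call. = FALSE)
  if (n_patients < 1 || n_patients != round(n_patients))
    stop("n_patients must be a positive integer", call. = FALSE)
  if (admin_censor_years_min < 5)
    stop("admin_censor_years_min must be >= 5 (loss to follow-up before 5 ",
         "years must come only from loss_to_followup_prob)", call. = FALSE)
  if (admin_censor_years_max < admin_censor_years_min)
    stop("admin_censor_years_max must be >= admin_censor_years_min", call. = FALSE)
  for (nm in c("station_base_prob", "surv5_given_station_met")) {
    missing_st <- setdiff(station_codes(), names(cfg[[nm]]))
    if (length(missing_st) > 0L)
      stop(nm, " is missing station(s): ", paste(missing_st, collapse = ", "),
           call. = FALSE)
  }
  if (length(setdiff(names(site_probs), .recurrence_sites_levels())) > 0L)
    stop("site_probs has unknown site names", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Simulate a synthetic EGJ-cancer cohort
#'
#' Draws a cohort from a [sim_config()]. Covariates are drawn first; the
#' surgical approach then follows the study protocol deterministically:
#' right transthoracic for squamous cell carcinoma, for adenocarcinoma with
#' esophageal involvement over 3 cm, or for clinical nodal positivity in the
#' upper/middle mediastinal field, otherwise transhiatal. Dissection fields
#' follow the approach (plus the distal stations for total gastrectomy);
#' metastasis indicators are drawn independently per dissected station, with
#' a logistic esophageal-involvement adjustment for mediastinal stations.
#' Latent death times are Weibull with the 5-year survivor fraction set by
#' nodal status; recurrence precedes a configurable fraction of deaths by an
#' exponential lead time; censoring is the minimum of administrative
#' censoring and, for patients lost to follow-up, a uniform time below 5
#' years. Identical `(config, seed)` yields an identical cohort.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer overriding `config$seed`.
#' @return A cohort data.frame of `config$n_patients` rows.
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  n <- as.integer(config$n_patients)
  d <- new_cohort(n)
  d$patient_id <- sprintf("S%05d", seq_len(n))

  # --- covariates -----------------------------------------------------------
  scc <- stats::runif(n) < config$prop_scc
  d$histology <- ifelse(scc, "scc", "adenocarcinoma")
  siewert1 <- stats::runif(n) < config$prop_siewert_I
  d$siewert <- ifelse(scc, "not_applicable", ifelse(siewert1, "I", "II"))
  # involvement recorded to one decimal, as on a pathology form
  d$esophageal_involvement_cm <- round(pmin(
    stats::rlnorm(n, config$eso_meanlog, config$eso_sdlog),
    config$involvement_max_cm), 1)
  d$gastric_involvement_cm <- round(pmin(
    stats::rlnorm(n, config$gastric_meanlog, config$gastric_sdlog),
    config$involvement_max_cm), 1)
  d$cT <- sample(c("T2", "T3", "T4"), n, replace = TRUE,
                 prob = c(0.237, 0.444, 0.320))
  d$cN_upper_middle_mediastinal <- stats::runif(n) < config$prop_cN_upper_middle
  d$neoadjuvant <- stats::runif(n) < config$prop_neoadjuvant

  # --- protocol: approach, resection, dissection fields ---------------------
  rt <- scc | (!scc & d$esophageal_involvement_cm > 3) |
    d$cN_upper_middle_mediastinal
  d$approach <- ifelse(rt, "right_transthoracic", "transhiatal")
  d$esophagectomy <- ifelse(rt, "subtotal", "lower")
  total_gx <- !rt & (stats::runif(n) < config$prop_total_gastrectomy_th)
  d$gastrectomy <- ifelse(rt, "proximal_or_upper",
                          ifelse(total_gx, "total", "proximal_or_upper"))

  u_res <- stats::runif(n)
  d$residual <- ifelse(u_res < config$prop_r1, "R1",
                       ifelse(u_res < config$prop_r1 + config$prop_r2,
                              "R2", "R0"))

  for (s in .core_dissection_set) d[[paste0("dissected_", s)]] <- TRUE
  for (s in .rt_extra_set) d[[paste0("dissected_", s)]] <- rt
  for (s in .total_gastrectomy_extra_set) d[[paste0("dissected_", s)]] <- total_gx

  # --- per-station metastasis ----------------------------------------------
  mediastinal <- stations_in_region(c("upper_mediastinal", "middle_mediastinal",
                                      "lower_mediastinal"))
  for (s in station_codes()) {
    p0 <- config$station_base_prob[[s]]
    p <- if (s %in% mediastinal) {
      stats::plogis(stats::qlogis(p0) +
                      config$mediastinal_slope * d$esophageal_involvement_cm)
    } else rep(p0, n)
    p[!is.finite(p)] <- p0  # qlogis(0)/qlogis(1) propagate to exact 0/1
    d[[paste0("metastatic_", s)]] <-
      d[[paste0("dissected_", s)]] & (stats::runif(n) < p)
  }

  # --- outcomes -------------------------------------------------------------
  met_mat <- as.matrix(d[, .metastatic_cols()])
  surv5 <- matrix(rep(config$surv5_given_station_met[station_codes()],
                      each = n), nrow = n)
  surv5[!met_mat] <- -Inf
  best <- apply(surv5, 1L, max)
  p5 <- ifelse(is.finite(best), best, config$surv5_node_negative)
  p5 <- pmin(pmax(p5, 1e-6), 1 - 1e-6)
  shape <- config$hazard_shape
  scale <- 5 / (-log(p5))^(1 / shape)
  t_death <- stats::rweibull(n, shape = shape, scale = scale)

  lost <- stats::runif(n) < config$loss_to_followup_prob
  c_admin <- stats::runif(n, config$admin_censor_years_min,
                          config$admin_censor_years_max)
  c_loss <- stats::runif(n, 0, 5)
  cens <- ifelse(lost, pmin(c_admin, c_loss), c_admin)

  d$os_time_years <- pmin(t_death, cens)
  d$os_event <- t_death <= cens

  rec_flag <- stats::runif(n) < config$prop_recurrence_before_death
  lead <- stats::rexp(n, rate = 1 / config$mean_recurrence_lead_years)
  t_rec <- ifelse(rec_flag, pmin(pmax(t_death - lead, 0.05), t_death), Inf)
  rec_observed <- t_rec < cens
  d$recurrence_time_years <- ifelse(rec_observed, t_rec, NA_real_)
  d$rfs_time_years <- ifelse(rec_observed, t_rec, d$os_time_years)
  d$rfs_event <- rec_observed | (d$os_event & !rec_observed)

  site_mat <- matrix(stats::runif(n * length(config$site_probs)),
                     nrow = n) < matrix(rep(config$site_probs, each = n),
                                        nrow = n)
  fallback <- sample(names(config$site_probs), n, replace = TRUE,
                     prob = config$site_probs)
  sites <- vapply(seq_len(n), function(i) {
    if (!rec_observed[i]) return(NA_character_)
    s <- names(config$site_probs)[site_mat[i, ]]
    if (length(s) == 0L) s <- fallback[i]
    paste(s, collapse = ";")
  }, character(1))
  d$recurrence_sites <- sites

  d$adjuvant <- d$residual %in% c("R0", "R1") &
    (stats::runif(n) < config$prop_adjuvant_given_r0r1)
  d
}

#' Realized marginals of a cohort
#'
#' Summary of the quantities a simulation configuration controls, for
#' checking a generated (or real) cohort against its target marginals.
#'
#' @param cohort A cohort data.frame.
#' @return Named list of proportions, medians and IQRs.
#' @export
marginal_report <- function(cohort) {
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  n <- nrow(cohort)
  r0r1 <- cohort$residual %in% c("R0", "R1")
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  eso <- qs(cohort$esophageal_involvement_cm)
  gas <- qs(cohort$gastric_involvement_cm)
  list(
    n = n,
    prop_scc = mean(cohort$histology == "scc"),
    prop_neoadjuvant = mean(cohort$neoadjuvant),
    prop_adjuvant = mean(cohort$adjuvant),
    prop_adjuvant_given_r0r1 = if (any(r0r1)) mean(cohort$adjuvant[r0r1]) else NA_real_,
    esophageal_involvement = c(q1 = eso[1], median = eso[2], q3 = eso[3]),
    gastric_involvement = c(q1 = gas[1], median = gas[2], q3 = gas[3]),
    prop_right_transthoracic = mean(cohort$approach == "right_transthoracic"),
    prop_total_gastrectomy = mean(cohort$gastrectomy == "total"),
    prop_r0 = mean(cohort$residual == "R0"),
    prop_r1 = mean(cohort$residual == "R1"),
    prop_r2 = mean(cohort$residual == "R2"),
    prop_cN_upper_middle = mean(cohort$cN_upper_middle_mediastinal)
  )
}
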