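test_that("Clopper-Pearson closed-form bounds match the textbook cases", {
  ci0 <- clopper_pearson(0, 10)
  expect_equal(unname(ci0["low"]), 0)
  expect_equal(unname(ci0["high"]), 1 - 0.025^(1 / 10), tolerance = 1e-12)
  ci1 <- clopper_pearson(10, 10)
  expect_equal(unname(ci1["low"]), 0.025^(1 / 10), tolerance = 1e-12)
  expect_equal(unname(ci1["high"]), 1)
  ci <- clopper_pearson(15, 100)
  expect_lte(ci["high"] - ci["low"], 0.15)
  expect_error(clopper_pearson(5, 4), "k <= n")
  expect_error(clopper_pearson(0, 0), "n >= 1")
})

test_that("Clopper-Pearson equals the tail-inversion oracle for all k <= n <= 40", {
  for (n in 1:40) for (k in 0:n) {
    expect_equal(unname(clopper_pearson(k, n)), unname(cp_oracle(k, n)),
                 tolerance = 1e-8)
  }
})

test_that("TEI eligibility keeps R0/R1 patients not lost without confirmed recurrence", {
  d <- new_cohort(12)
  d$residual[1:2] <- "R2"                       # excluded outright
  d$os_time_years[3] <- 3                       # lost before 5y, no recurrence
  d$rfs_time_years[3] <- 3
  d$os_time_years[4] <- 3                       # censored at 3y but recurred at 2y
  d$rfs_time_years[4] <- 2
  d$rfs_event[4] <- TRUE
  d$recurrence_time_years[4] <- 2
  d$recurrence_sites[4] <- "liver"
  d$residual[5] <- "R1"
  el <- tei_eligible(d)
  expect_identical(nrow(el), 9L)
  expect_false("P00003" %in% el$patient_id)
  expect_true("P00004" %in% el$patient_id)      # confirmed recurrence retained
  expect_true("P00005" %in% el$patient_id)      # R1 included
  expect_identical(nrow(tei_eligible(d, r0_only = TRUE)), 8L)
  all_r2 <- new_cohort(3); all_r2$residual <- "R2"
  expect_identical(nrow(tei_eligible(all_r2)), 0L)
})

test_that("denominators are restricted by approach and gastrectomy type", {
  rt <- fixture_station_cohort("108", 117, 0, 0, esophageal_involvement_cm = 3.5)
  th <- new_cohort(100)
  th$dissected_108 <- TRUE   # dissected but transhiatal: excluded for 108
  for (s in c("1", "110")) th[[paste0("dissected_", s)]] <- TRUE
  combined <- rbind(rt, th)
  combined$patient_id <- sprintf("Q%04d", seq_len(nrow(combined)))
  el <- tei_eligible(combined)
  expect_identical(nrow(station_denominator(el, "108")), 117L)
  expect_identical(nrow(station_denominator(el, "110")), 217L)

  tg <- fixture_station_cohort("4d", 174, 0, 0)
  pg <- new_cohort(50)
  pg$dissected_4d <- TRUE    # proximal gastrectomy: excluded for 4d
  both <- rbind(tg, pg)
  both$patient_id <- sprintf("R%04d", seq_len(nrow(both)))
  el2 <- tei_eligible(both)
  expect_identical(nrow(station_denominator(el2, "4d")), 174L)
  # nobody dissected station 5 in a bare cohort: empty denominator
  expect_identical(nrow(station_denominator(tei_eligible(new_cohort(10)), "5")),
                   0L)
})

test_that("station TEI reproduces the worked examples at printed denominators", {
  f108 <- fixture_station_cohort("108", 45, 5, 3, esophageal_involvement_cm = 3.5)
  r108 <- station_tei(tei_eligible(f108), "108")
  expect_equal(r108$tei_os, 6.7)
  expect_identical(r108$n, 45L)

  f110 <- fixture_station_cohort("110", 81, 8, 4, esophageal_involvement_cm = 2.5)
  expect_equal(station_tei(tei_eligible(f110), "110")$tei_os, 4.9)

  f106 <- fixture_station_cohort("106L", 39, 2, 2, neoadjuvant = FALSE)
  expect_equal(station_tei(tei_eligible(f106), "106L")$tei_os, 5.1)

  # no metastases: TEI 0, not undefined
  f0 <- fixture_station_cohort("9", 30, 0, 0)
  r0 <- station_tei(tei_eligible(f0), "9")
  expect_equal(r0$tei_os, 0)
  expect_equal(r0$tei_rfs, 0)
  expect_true(r0$evaluable)

  # empty denominator flagged, no division
  rempty <- station_tei(tei_eligible(new_cohort(5)), "5")
  expect_false(rempty$evaluable)
  expect_true(is.na(rempty$tei_os))
})

test_that("eligibility exclusions flow through the TEI arithmetic", {
  # 10 patients, 1 lost before 5y; of the remaining 9, 3 metastatic with 1
  # five-year survivor: TEI = (3/9) * (1/3) * 100 = 11.1
  d <- fixture_station_cohort("110", 10, 4, 1)
  # patient 4 (metastatic non-survivor) becomes lost to follow-up instead
  d$os_time_years[4] <- 3; d$os_event[4] <- FALSE
  d$rfs_time_years[4] <- 3; d$rfs_event[4] <- FALSE
  d$recurrence_sites[4] <- NA_character_
  d$recurrence_time_years[4] <- NA_real_
  el <- tei_eligible(d)
  expect_identical(nrow(el), 9L)
  r <- station_tei(el, "110")
  expect_identical(r$n_metastatic, 3L)
  expect_equal(r$tei_os, 11.1)
})

test_that("TEI decomposes as survivors over denominator and is order/duplication invariant", {
  set.seed(55)
  for (i in 1:10) {
    n <- sample(20:80, 1)
    m <- sample(0:min(n, 12), 1)
    s <- if (m > 0) sample(0:m, 1) else 0
    f <- fixture_station_cohort("110", n, m, s)
    el <- tei_eligible(f)
    r <- station_tei(el, "110")
    expect_equal(r$tei_os, round_half_up(100 * s / n, 1))
    # permutation invariance
    perm <- el[sample(nrow(el)), , drop = FALSE]
    expect_equal(station_tei(perm, "110")$tei_os, r$tei_os)
    # duplicating the cohort changes neither rate nor TEI
    dup <- rbind(el, el)
    rd <- station_tei(dup, "110")
    expect_equal(rd$metastasis_rate, r$metastasis_rate)
    expect_equal(rd$tei_os, r$tei_os)
  }
})

test_that("threshold classification uses strict inequalities at 3 (OS) and 2 (RFS)", {
  expect_identical(classify_tei(17.6, 13.8), "both_exceed")
  expect_identical(classify_tei(3.1, 1.5), "single_exceed")
  expect_identical(classify_tei(1.0, 2.5), "single_exceed")
  expect_identical(classify_tei(3.0, 2.0), "neither")
  expect_identical(classify_tei(0, 0), "neither")
  expect_identical(classify_tei(c(4, 3), c(3, 2)),
                   c("both_exceed", "neither"))
})

test_that("stratified TEI re-derives denominators inside strata", {
  f <- fixture_station_cohort("110", 60, 6, 3)
  f$neoadjuvant[1:20] <- TRUE
  el <- tei_eligible(f)
  st <- stratified_tei(el, "neoadjuvant", stations = "110")
  expect_identical(sum(st$n), nrow(el))   # strata partition the denominator
  full <- station_tei(el, "110")
  expect_identical(sum(st$n_metastatic), full$n_metastatic)

  # all-adenocarcinoma cohort: SCC stratum present but not evaluable
  sc <- stratified_tei(el, "histology", stations = "110")
  scc_row <- sc[sc$stratum == "scc", ]
  expect_false(scc_row$evaluable)
  expect_identical(scc_row$n, 0L)

  expect_error(stratified_tei(el, "tumor_size"), "unknown stratifier")
})

test_that("involvement bins are region-specific and left-open/right-closed", {
  mk <- function(inv) fixture_station_cohort("110", 10, 0, 0,
                                             esophageal_involvement_cm = inv)
  d <- do.call(rbind, lapply(c(1.0, 1.1, 2.0, 2.1, 3.0, 3.1), mk))
  d$patient_id <- sprintf("B%04d", seq_len(nrow(d)))
  el <- tei_eligible(d)
  st <- stratified_tei(el, "esophageal_involvement_bins", stations = "110")
  expect_identical(st$n[st$stratum == "<=1.0cm"], 10L)     # 1.0 in first bin
  expect_identical(st$n[st$stratum == "1.1-2.0cm"], 20L)   # 1.1 and 2.0
  expect_identical(st$n[st$stratum == "2.1-3.0cm"], 20L)   # 2.1 and 3.0
  expect_identical(st$n[st$stratum == ">3.0cm"], 10L)

  # upper/middle mediastinal stations use the two-bin split
  f108 <- fixture_station_cohort("108", 20, 0, 0, esophageal_involvement_cm = 2.5)
  st2 <- stratified_tei(tei_eligible(f108), "esophageal_involvement_bins",
                        stations = "108")
  expect_setequal(st2$stratum, c("<=3.0cm", ">3.0cm"))
})

test_that("a metastasis gradient in involvement surfaces as a TEI gradient at station 110", {
  cfg <- sim_config(n_patients = 20000, seed = 31, mediastinal_slope = 0.8)
  el <- tei_eligible(simulate_cohort(cfg))
  st <- stratified_tei(el, "esophageal_involvement_bins", stations = "110")
  tei_first <- st$tei_os[st$stratum == "<=1.0cm"]
  tei_last <- st$tei_os[st$stratum == ">3.0cm"]
  expect_gt(tei_last, tei_first)
})
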