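---
title: "The therapeutic efficacy index for EGJ-cancer lymphadenectomy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The therapeutic efficacy index for EGJ-cancer lymphadenectomy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodalTEI)
```

## The problem

Esophagogastric junction (EGJ) cancer sits at the boundary between the
thoracic and abdominal cavities, so its lymphatic spread reaches both
mediastinal and abdominal node basins, and surgeons must decide — station by
station — whether dissecting a basin is worth its morbidity. Metastasis rates
alone cannot answer this: removing a metastatic node is futile if the disease
has already disseminated. The **therapeutic efficacy index (TEI)** addresses
this by combining how often a station harbors metastasis with how well
patients with metastasis at that station actually fare:

$$
\mathrm{TEI}_s \;=\; \underbrace{\frac{m_s}{n_s}}_{\text{metastasis rate}}
\;\times\;
\underbrace{\frac{k_s}{m_s}}_{\substack{\text{5-year survival}\\\text{among metastatic}}}
\;\times\; 100 \;=\; 100\,\frac{k_s}{n_s},
$$

where $n_s$ is the number of eligible patients in whom station $s$ was
dissected, $m_s$ the number with pathologic metastasis there, and $k_s$ the
number of those alive (OS) or recurrence-free (RFS) at 5 years. The TEI is
the expected percentage-point gain in 5-year survival attributable to
dissecting the station — a descriptive index, not a causal estimate. The
collapsed form $100\,k_s/n_s$ holds exactly because survival among metastatic
patients is a simple proportion (see below); it explains why printed indices
are ratios of small integers (e.g. $6.7 = 100 \times 3/45$).

A station is judged to merit dissection when its TEI exceeds **3** for
5-year OS and **2** for 5-year RFS (strict inequalities; the thresholds
express the consensus that a gain of at least 3 OS percentage points, or 2
RFS points, justifies the added morbidity).

## Eligibility and denominators

Three rules shape every computation:

1. **Eligibility.** TEI is computed among patients with R0 or R1 resection,
   excluding those lost to follow-up within 5 years *without confirmation of
   recurrence*. A patient censored for OS at 3 years who had a documented
   recurrence at 2 years is retained: the recurrence is confirmed. One
   eligibility set (OS-based, with recurrence counting as confirmation) is
   used for both endpoints; for the OS endpoint such a retained-but-censored
   patient counts as a non-survivor at 5 years, which is conservative and
   rare (loss to follow-up is ~1%). An `r0_only` switch reproduces the
   R0-restricted sensitivity analysis.
2. **Denominator restriction.** The metastasis-rate denominator of a station
   is the set of eligible patients in whom it was *actually dissected* —
   additionally restricted to right-transthoracic subtotal-esophagectomy
   patients for upper/middle mediastinal stations, and to total-gastrectomy
   patients for left-greater-curvature and distal-perigastric stations,
   because only those operations expose the station systematically. This is
   what makes a prospective, protocol-driven cohort essential: in
   retrospective series the decision to dissect is confounded with suspected
   metastasis.
3. **Simple proportion, not Kaplan–Meier, among metastatic cases.** Because
   lost-to-follow-up patients are excluded up front, every remaining
   metastatic patient has determinate 5-year status, so the survival factor
   is an exact binomial proportion. This preserves the integer identity
   above and matches how printed indices decompose.

Metastasis rates carry **Clopper–Pearson exact 95% intervals**, computed from
the beta-quantile closed form: lower bound
$B_{\alpha/2}(k,\,n-k+1)$, upper bound $B_{1-\alpha/2}(k+1,\,n-k)$, with the
bounds pinned to 0 and 1 at $k=0$ and $k=n$. The test suite verifies this
against a brute-force inversion of binomial tail probabilities for all
$k \le n \le 40$ and checks simulated coverage at $p=0.15$, $n=100$
(the design point of the study's sample-size rationale: the 95% CI width for
15/100 is at most 15 percentage points).

## Survival machinery

The package implements its own product-limit estimator and log-rank test
(the `survival` package serves as an independent cross-check in the tests,
never as the implementation):

* **Kaplan–Meier.** $\hat S(t)=\prod_{t_i\le t}(1-d_i/n_i)$ over distinct
  event times; ties between events and censorings at the same time are
  resolved events-first (censored subjects remain at risk at their own
  time). Variance by Greenwood's formula; 95% pointwise bands on the
  complementary log-log scale, which keeps them inside $[0,1]$; where
  $\hat S$ is exactly 0 or 1 the band degenerates to the point. The median
  is the smallest event time with $\hat S \le 0.5$, reported as not reached
  when the curve stays above 0.5.
* **Log-rank.** Unstratified two-group observed-minus-expected statistic
  with hypergeometric variance, referred to $\chi^2_1$; no continuity
  correction. Calibration is property-tested: under identical exponential
  groups ($n=50$ each, 2000 replicates) the rejection rate at $\alpha=0.05$
  must lie in $[0.035, 0.065]$.
* **5-year landmark.** An event at exactly $t=5.0$ counts as an event before
  5 years; censoring at exactly 5.0 counts as adequate follow-up (the closed
  reading of "within 5 years"). Every record falls in exactly one of
  survivor / event-before-5y / lost-before-5y.
* **Follow-up maturity** is summarized as the median (and IQR) of OS time
  among censored patients. The reverse-KM estimator is a recognized
  alternative; the censored-subset median is what is implemented, and the
  choice is surfaced rather than silently assumed.
* **Recurrence.** First-recurrence sites are counted with multiplicity per
  patient (percentages may exceed 100 in total); survival after recurrence
  is KM on time from recurrence to death among R0/R1 recurrent patients.

## Stratified tables

`stratified_tei()` re-derives denominators inside strata of esophageal
involvement, histology, neoadjuvant or adjuvant treatment, or clinical
upper/middle mediastinal nodal status. Esophageal-involvement bins are
half-open on the left and closed on the right — $(1.0, 2.0]$ renders as
"1.1–2.0" for lengths recorded to one decimal — with a coarse split at 3 cm
for upper/middle mediastinal stations (small denominators) and cut points at
1, 2 and 3 cm for all other stations. Gastric-involvement bins are not
hard-coded: no canonical edges exist for the abdominal analysis, so any such
stratification must be supplied explicitly.

## The dissection recommendation engine

`recommend_dissection()` encodes the decision algorithm implied by the TEI
thresholds:

* always dissect proximal perigastric {1, 2, 3, 7} and suprapancreatic
  {8a, 9, 11p, 11d};
* never dissect left greater curvature {4sa, 4sb}, distal perigastric
  {4d, 5, 6} or paraaortic {16a2};
* add lower mediastinal {110, 111, 112} when esophageal involvement
  exceeds 2 cm, middle mediastinal {107, 108, 109L, 109R} when it exceeds
  3 cm (post-neoadjuvant measurement when applicable);
* upper mediastinal {105, 106L, 106R} is *conditional*: considered only
  with clinical nodal positivity in the upper/middle mediastinal field or
  without neoadjuvant chemotherapy;
* approach: transhiatal suffices at ≤ 2 cm without mediastinal cN+; right
  transthoracic is required above 3 cm or with mediastinal cN+; in between,
  either approach is acceptable. Histology does not alter the
  recommendation, and proximal gastrectomy is preferred (total only when
  the distal margin would be inadequate).

Station 11d is kept in the always-dissect set although its individual TEI
falls below both thresholds, because the suprapancreatic field is
recommended as a whole; `include_11d = FALSE` exposes the tension. Both
involvement thresholds are strict: exactly 2.0 cm stays on the
transhiatal-sufficient branch and exactly 3.0 cm on the either-approach
branch.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure the analysis assumes, so the
entire pipeline is exercised without patient data. Defaults are the study
conditions: 363 patients; 8.5% SCC (Siewert type recorded as not applicable
for SCC, and split I/II for adenocarcinoma); esophageal involvement from a
log-normal with median 2.0 cm, scale chosen so the quartile ratio is 3
(IQR ≈ 1.0–3.0; a two-parameter log-normal cannot match both quartiles and
the median exactly, so the median and the IQR *ratio* are matched and the
mild skew mismatch accepted), truncated at 12 cm and recorded to one
decimal; gastric involvement analogous with median 2.5 cm; one-third
neoadjuvant; adjuvant 53.4% of R0/R1; R1 4.1% and R2 2.5%; clinical
upper/middle mediastinal nodal positivity 8.3%; 78% of transhiatal patients
undergo total gastrectomy.

The surgical approach follows the protocol rule deterministically (right
transthoracic iff SCC, adenocarcinoma with involvement > 3 cm, or
mediastinal cN+), and the dissection fields follow the approach, so the
structural confounding between approach and nodal detectability that the
real study design carries is reproduced faithfully. Metastasis indicators
are independent across stations given covariates, with a logistic
involvement adjustment (log-odds slope per cm) for mediastinal stations.
Death times are Weibull (shape 1.2) with the 5-year survivor fraction set to
the most favorable conditional-survival value among the patient's metastatic
stations, or the node-negative value otherwise; recurrence precedes 85% of
deaths by an exponential lead time with mean 1.33 years (≈ 16 months median
post-recurrence survival); administrative censoring is uniform on 5.5–8
years — consistent with a trial whose accrual closed more than five years
before database lock, giving median follow-up near 6 years — so censoring
before 5 years arises only through the 1.1% loss-to-follow-up mechanism.
Per-station metastasis probabilities and conditional 5-year survival
defaults are **illustrative**: station-level conditional survival is not
published anywhere, so these are plausibility-ranked values (perigastric
highest, paraaortic lowest), not calibrated estimates.

One RNG stream is seeded once per cohort and all fields are drawn
vectorized in a fixed order, so identical `(config, seed)` gives
byte-identical cohorts regardless of platform iteration quirks; the
generator restores the caller's RNG state on exit.

What passing tests on synthetic data do **not** show: cross-station
dependence of metastasis (real nodal spread is strongly correlated along
lymphatic pathways), covariate-dependent censoring, recurrence in patients
who remain alive at database lock, and any fidelity of the illustrative
station-level parameters. Tests on this generator validate the *machinery*
(denominators, exclusions, estimators, thresholds), not clinical claims.

## Numerical choices

* All percentages and TEIs are reported half-up to one decimal (2.25 → 2.3),
  the convention of clinical tables; internal computation is at full
  precision, and threshold classification is applied to the rounded
  (printed-scale) values because the thresholds annotate printed tables.
* TEI is defined as 0 (not undefined) when a station has no metastases, and
  a station with an empty denominator is flagged not-evaluable rather than
  dividing by zero; report cells render as "–/–".
* Medians of even-sized sets are midpoints of the central order statistics.
* Test problem sizes were chosen to keep Monte-Carlo tolerances meaningful
  at interactive runtimes: 5,000 patients for parameter recovery (binomial
  3σ ≈ 0.9 TEI points at the 4.5-point target), 10,000 for marginal checks,
  20,000 for the involvement-gradient check, 2,000 replicates for coverage
  and type-I-error calibration.

## Parameter recovery

The acceptance property closing the loop: simulate 5,000 patients with
station-1 metastasis probability 0.15 and conditional 5-year OS 0.30 for all
stations (so the true TEI is $0.15 \times 0.30 \times 100 = 4.5$), run the
full pipeline — validation, eligibility, denominator, TEI — and require the
estimate within 3 binomial standard errors,
$3\sqrt{0.045 \times 0.955 / n_s} \times 100$, of 4.5.

## Known limitations

* The TEI is descriptive; it cannot replace a randomized comparison of
  dissection extents, and no multiplicity adjustment is applied across the
  26 stations (none is standard for this index).
* Upper/middle mediastinal denominators are intrinsically small (only
  right-transthoracic patients contribute), so their TEIs are exploratory.
* The single OS-based eligibility set for both endpoints is one defensible
  reading; an RFS-specific exclusion set would differ for patients lost
  after recurrence.
* Sub-splitting of station 3 (3a vs 3b) in proximal-gastrectomy patients is
  not modelled; the catalog records a single station 3, and the paraaortic
  station is recorded as 16a2 without lateral qualification.
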