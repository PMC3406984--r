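#' Configuration for the synthetic linked-cohort generator
#'
#' Builds and validates the parameter set controlling [generate_cohort()].
#' Defaults emulate a provincial colorectal-cancer cohort diagnosed over a
#' six-year span in which about 85% of patients have a registry-recorded
#' primary-tumor resection, stage I-III surgery is near universal, stage IV
#' surgery is recorded by the registry for about 60% of patients while
#' administrative sources indicate surgery for 66-74%, some stage I
#' surgeries are registry-only (outpatient polypectomy leaves no inpatient
#' or billing surgery claim), and administrative sources record palliative
#' de-bulking or stoma operations the registry does not count as
#' primary-tumor removal.
#'
#' @param n_patients Number of registry records to generate (before
#'   exclusions).
#' @param year_range Length-2 integer vector, first and last calendar year
#'   of diagnosis; diagnosis dates are uniform over the span.
#' @param stage_distribution Named probabilities over stages
#'   `I, II, III, IV, missing` for stageable records.
#' @param site_distribution Named probabilities over `colon, rectum`.
#' @param registry_surgery_prob Named per-stage probability that the
#'   registry records a primary-tumor-removal surgery.
#' @param source_capture_prob Named per-source (`billing`, `hospital`)
#'   probability that a registry-true surgery yields a qualifying claim
#'   inside the linkage window.
#' @param false_positive_prob Named per-stage probability that a patient
#'   without a registry surgery nevertheless undergoes an operation visible
#'   to the administrative sources (palliative surgery mechanism); each
#'   source then captures that event with its `source_capture_prob`.
#' @param fp_correlation Probability in `[0, 1]` that the two sources see
#'   the *same* latent false-positive event (1 = fully correlated event
#'   with independent capture, 0 = independent events per source).
#' @param registry_only_prob Named per-stage probability that a registry
#'   surgery has no administrative counterpart in either source
#'   (polypectomy mechanism).
#' @param date_jitter_prob Probability an administrative claim date differs
#'   from the registry surgery date.
#' @param date_jitter_range Length-2 integer vector of day offsets; jitter
#'   is drawn uniformly from the non-zero offsets in this range and the
#'   resulting date is clamped to the linkage window.
#' @param missing_uli_rate,unstageable_rate,stage0_rate Probabilities that
#'   a record is seeded for exclusion (missing identifier, unstageable
#'   histology, in-situ disease); mutually exclusive per record.
#' @param delay_distribution Distribution of days from diagnosis to
#'   surgery, a list with `type = "gamma"` (`shape`, `scale`) or
#'   `type = "uniform"` (`min`, `max`); draws are rounded to whole days and
#'   clamped to `[-7, 548]`.
#' @param noise_claim_rate Probability per patient per source of one extra
#'   non-surgical claim (a code outside the qualifying code list).
#' @param rng_seed Integer seed making generation bit-for-bit reproducible.
#'
#' @return A validated list of class `generator_config`.
#' @seealso [generate_cohort()], [read_generator_config()]
#' @export
generator_config <- function(n_patients = 8533L,
                             year_range = c(2000L, 2005L),
                             stage_distribution = c(
                               I = 1387, II = 2207, III = 1902,
                               IV = 1953, missing = 859) / 8308,
                             site_distribution = c(
                               colon = 5303, rectum = 3005) / 8308,
                             registry_surgery_prob = c(
                               I = 1379 / 1387, II = 2166 / 2207,
                               III = 1875 / 1902, IV = 1164 / 1953,
                               missing = 482 / 859),
                             source_capture_prob = c(
                               billing = 0.99, hospital = 0.96),
                             false_positive_prob = c(
                               I = 0.12, II = 0.55, III = 0.30,
                               IV = 0.36, missing = 0.22),
                             fp_correlation = 1,
                             registry_only_prob = c(
                               I = 0.09, II = 0, III = 0,
                               IV = 0, missing = 0),
                             date_jitter_prob = 0.05,
                             date_jitter_range = c(-14L, 14L),
                             missing_uli_rate = 2 / 8533,
                             unstageable_rate = 140 / 8533,
                             stage0_rate = 83 / 8533,
                             delay_distribution = list(
                               type = "gamma", shape = 2, scale = 15),
                             noise_claim_rate = 0.3,
                             rng_seed = 1L) {
  stages <- c("I", "II", "III", "IV", "missing")
  assert_that(is.numeric(n_patients) && length(n_patients) == 1 &&
                n_patients >= 0 && n_patients == trunc(n_patients),
              "'n_patients' must be a single non-negative integer")
  assert_that(is.numeric(year_range) && length(year_range) == 2 &&
                year_range[1] <= year_range[2],
              "'year_range' must be two calendar years, first <= last")
  check_distribution(stage_distribution, "stage_distribution", stages)
  check_distribution(site_distribution, "site_distribution",
                     c("colon", "rectum"))
  check_prob(registry_surgery_prob, "registry_surgery_prob")
  assert_that(setequal(names(registry_surgery_prob), stages),
              "'registry_surgery_prob' must be named per stage")
  check_prob(source_capture_prob, "source_capture_prob")
  assert_that(setequal(names(source_capture_prob), c("billing", "hospital")),
              "'source_capture_prob' must be named billing/hospital")
  check_prob(false_positive_prob, "false_positive_prob")
  assert_that(setequal(names(false_positive_prob), stages),
              "'false_positive_prob' must be named per stage")
  check_prob(fp_correlation, "fp_correlation")
  check_prob(registry_only_prob, "registry_only_prob")
  assert_that(setequal(names(registry_only_prob), stages),
              "'registry_only_prob' must be named per stage")
  check_prob(date_jitter_prob, "date_jitter_prob")
  assert_that(is.numeric(date_jitter_range) && length(date_jitter_range) == 2 &&
                date_jitter_range[1] <= date_jitter_range[2] &&
                any(setdiff(seq(date_jitter_range[1], date_jitter_range[2]), 0L)
                    != 0L),
              "'date_jitter_range' must span at least one non-zero offset")
  check_prob(missing_uli_rate, "missing_uli_rate")
  check_prob(unstageable_rate, "unstageable_rate")
  check_prob(stage0_rate, "stage0_rate")
  check_prob(noise_claim_rate, "noise_claim_rate")
  assert_that(missing_uli_rate + unstageable_rate + stage0_rate <= 1,
              "exclusion-seeding rates must sum to at most 1")
  assert_that(is.list(delay_distribution) &&
                delay_distribution$type %in% c("gamma", "uniform"),
              "'delay_distribution' must have type 'gamma' or 'uniform'")
  if (delay_distribution$type == "uniform") {
    assert_that(delay_distribution$min >= -7 && delay_distribution$max <= 548 &&
                  delay_distribution$min <= delay_distribution$max,
                "uniform delay support must lie within [-7, 548]")
  }
  assert_that(is.numeric(rng_seed) && length(rng_seed) == 1 &&
                is.finite(rng_seed),
              "'rng_seed' must be a single integer")

  structure(list(
    n_patients = as.integer(n_patients),
    year_range = as.integer(year_range),
    stage_distribution = stage_distribution[stages],
    site_distribution = site_distribution[c("colon", "rectum")],
    registry_surgery_prob = registry_surgery_prob[stages],
    source_capture_prob = source_capture_prob[c("billing", "hospital")],
    false_positive_prob = false_positive_prob[stages],
    fp_correlation = fp_correlation,
    registry_only_prob = registry_only_prob[stages],
    date_jitter_prob = date_jitter_prob,
    date_jitter_range = as.integer(date_jitter_range),
    missing_uli_rate = missing_uli_rate,
    unstageable_rate = unstageable_rate,
    stage0_rate = stage0_rate,
    delay_distribution = delay_distribution,
    noise_claim_rate = noise_claim_rate,
    rng_seed = as.integer(rng_seed)
  ), class = "generator_config")
}

#' Read a generator configuration from a YAML file
#'
#' Any field of [generator_config()] may appear in the file; omitted fields
#' keep their defaults. Named vectors are given as YAML mappings.
#'
#' @param path Path to a YAML configuration file.
#' @return A `generator_config` object.
#' @export
read_generator_config <- function(path) {
  assert_that(file.exists(path), sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  assert_that(is.list(raw), "config file must contain a YAML mapping")
  vec_fields <-c("stage_distribution", "site_distribution",
                  "registry_surgery_prob", "source_capture_prob",
                  "false_positive_prob", "registry_only_prob")
  for (f in vec_fields) if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  do.call(generator_config, raw)
}

# Internal: draw diagnosis-to-surgery delays in whole days, clamped to the
# linkage window so the administrative extraction can in principle see them.
draw_delays <- function(n, dist) {
  if (n == 0) return(integer(0))
  d <- switch(dist$type,
    gamma = round(stats::rgamma(n, shape = dist$shape, scale = dist$scale)),
    uniform = round(stats::runif(n, dist$min, dist$max))
  )
  as.integer(pmin(548, pmax(-7, d)))
}

# Internal: synthetic qualifying procedure codes per coding system.
qualifying_codes <- function(system) {
  switch(system,
    CCP = c("SURG01", "SURG02", "SURG03"),
    ICD9CM = c("4510", "4571", "4841"),
    CCI = c("1NM87", "1NM89", "1NQ87")
  )
}

#' Default qualifying-procedure code list
#'
#' The synthetic code list matching [generate_cohort()] output: a few
#' synthetic surgery codes per coding system (billing claims use CCP;
#' hospital abstracts use ICD-9-CM before April 2002 and CCI after).
#' Real published code lists can be substituted via [read_code_list()].
#'
#' @return Tibble with columns `coding_system`, `code`.
#' @export
default_code_list <- function() {
  tibble::tibble(
    coding_system = rep(c("CCP", "ICD9CM", "CCI"), each = 3L),
    code = c(qualifying_codes("CCP"), qualifying_codes("ICD9CM"),
             qualifying_codes("CCI"))
  )
}

#' Generate a synthetic linked registry + claims cohort
#'
#' Simulates the three linked datasets the validation pipeline consumes:
#' a cancer-registry extract (one row per diagnosis with the
#' primary-tumor-removal surgery date when one exists), physician billing
#' claims, and hospital inpatient procedure records. The latent state of
#' every patient (true surgery status, per-source capture, jitter,
#' false-positive events, exclusion seeding) is returned in `truth_log` so
#' tests can score the pipeline against known truth.
#'
#' The observation model, per patient: stage and site are drawn from the
#' configured distributions; the registry records a surgery with the
#' per-stage probability, dated `diagnosis + delay`; a registry surgery is
#' administratively invisible with the per-stage `registry_only_prob`
#' (polypectomy mechanism); otherwise each source captures it with its
#' `source_capture_prob`, with the claim date jittered away from the
#' registry date with probability `date_jitter_prob` (clamped to the
#' `[-7, 548]`-day window). Patients without a registry surgery undergo an
#' administratively visible operation with the per-stage
#' `false_positive_prob` (palliative de-bulking/stoma mechanism), shared
#' between sources with probability `fp_correlation` and captured
#' independently by each source.
#'
#' @param config A [generator_config()].
#' @return A list of class `linked_datasets` with tibbles `registry`
#'   (`uli`, `dx_date`, `site_code`, `stage`, `histology_stageable`,
#'   `surgery_date`), `billing` and `hospital` (`uli`, `service_date`,
#'   `proc_code`, `coding_system`), and `truth_log`.
#' @examples
#' cfg <- generator_config(n_patients = 200, rng_seed = 42)
#' ds <- generate_cohort(cfg)
#' nrow(ds$registry)
#' @export
generate_cohort <- function(config) {
  assert_that(inherits(config, "generator_config"),
              "'config' must be a generator_config object")
  set.seed(config$rng_seed)
  n <- config$n_patients
  stages <- c("I", "II", "III", "IV", "missing")

  empty_claims <- tibble::tibble(
    uli = character(0), service_date = as.Date(character(0)),
    proc_code = character(0), coding_system = character(0)
  )
  if (n == 0) {
    out <- list(
      registry = tibble::tibble(
        uli = character(0), dx_date = as.Date(character(0)),
        site_code = character(0), stage = character(0),
        histology_stageable = logical(0),
        surgery_date = as.Date(character(0))),
      billing = empty_claims, hospital = empty_claims,
      truth_log = tibble::tibble(patient = integer(0))
    )
    class(out) <- "linked_datasets"
    return(out)
  }

  uli <- sprintf("U%07d", seq_len(n))

  # Exclusion seeding: one uniform draw gives mutually exclusive buckets.
  u <- stats::runif(n)
  r1 <- config$missing_uli_rate
  r2 <- r1 + config$unstageable_rate
  r3 <- r2 + config$stage0_rate
  excl <- dplyr::case_when(u < r1 ~ "missing_uli",
                           u < r2 ~ "unstageable",
                           u < r3 ~ "stage0",
                           TRUE ~ "none")

  d0 <- as.Date(sprintf("%d-01-01", config$year_range[1]))
  d1 <- as.Date(sprintf("%d-12-31", config$year_range[2]))
  dx_date <- d0 + sample.int(as.integer(d1 - d0) + 1L, n, replace = TRUE) - 1L

  latent_stage <- sample(stages, n, replace = TRUE,
                         prob = config$stage_distribution)
  site <- sample(c("colon", "rectum"), n, replace = TRUE,
                 prob = config$site_distribution)
  colon_codes <- c("c18.0", paste0("c18.", 2:9))
  site_code <- ifelse(site == "colon",
                      sample(colon_codes, n, replace = TRUE),
                      sample(c("c19.9", "c20.9"), n, replace = TRUE))

  surgery <- stats::runif(n) < config$registry_surgery_prob[latent_stage]
  delay <- draw_delays(n, config$delay_distribution)
  surgery_date <- dplyr::if_else(surgery, dx_date + delay,
                                 as.Date(NA_character_))

  registry_only <- surgery &
    stats::runif(n) < config$registry_only_prob[latent_stage]

  cap_b <- surgery & !registry_only &
    stats::runif(n) < config$source_capture_prob[["billing"]]
  cap_h <- surgery & !registry_only &
    stats::runif(n) < config$source_capture_prob[["hospital"]]

  # Administrative-only (false-positive) surgical events among patients the
  # registry records no surgery for; a shared latent event with independent
  # capture by default, independent per-source events as correlation -> 0.
  fp_shared <- !surgery & stats::runif(n) < config$false_positive_prob[latent_stage]
  fp_ind_b <- !surgery & stats::runif(n) < config$false_positive_prob[latent_stage]
  fp_ind_h <- !surgery & stats::runif(n) < config$false_positive_prob[latent_stage]
  use_shared <- stats::runif(n) < config$fp_correlation
  fp_event_b <- ifelse(use_shared, fp_shared, fp_ind_b)
  fp_event_h <- ifelse(use_shared, fp_shared, fp_ind_h)
  fp_delay <- draw_delays(n, config$delay_distribution)
  fp_date <- dx_date + fp_delay
  fp_cap_b <- fp_event_b & stats::runif(n) < config$source_capture_prob[["billing"]]
  fp_cap_h <- fp_event_h & stats::runif(n) < config$source_capture_prob[["hospital"]]

  # Date jitter applies to captured true-surgery claims; jittered dates stay
  # inside the linkage window (window exclusion is tested with fixtures).
  offsets <- setdiff(seq(config$date_jitter_range[1],
                         config$date_jitter_range[2]), 0L)
  jit_b <- cap_b & stats::runif(n) < config$date_jitter_prob
  jit_h <- cap_h & stats::runif(n) < config$date_jitter_prob
  off_b <- ifelse(jit_b, sample(offsets, n, replace = TRUE), 0L)
  off_h <- ifelse(jit_h, sample(offsets, n, replace = TRUE), 0L)
  clamp <- function(dates, dx) pmin(dx + 548L, pmax(dx - 7L, dates))

  billing_date <- rep(as.Date(NA_character_), n)
  billing_date[cap_b] <- clamp(surgery_date[cap_b] + off_b[cap_b], dx_date[cap_b])
  billing_date[fp_cap_b] <- fp_date[fp_cap_b]
  hospital_date <- rep(as.Date(NA_character_), n)
  hospital_date[cap_h] <- clamp(surgery_date[cap_h] + off_h[cap_h], dx_date[cap_h])
  hospital_date[fp_cap_h] <- fp_date[fp_cap_h]

  stage <- latent_stage
  stage[stage == "missing"] <- NA_character_
  histology_stageable <- excl != "unstageable"
  stage[excl == "unstageable"] <- NA_character_
  stage[excl == "stage0"] <- "0"
  uli_out <- ifelse(excl == "missing_uli", NA_character_, uli)

  registry <- tibble::tibble(
    uli = uli_out, dx_date = dx_date, site_code = site_code, stage = stage,
    histology_stageable = histology_stageable, surgery_date = surgery_date
  )

  make_claims <- function(event_date, source) {
    keep <- !is.na(event_date) & !is.na(uli_out)
    sys <- if (source == "billing") {
      rep("CCP", sum(keep))
    } else {
      as.character(ifelse(event_date[keep] < as.Date("2002-04-01"),
                          "ICD9CM", "CCI"))
    }
    code <- vapply(sys, function(s) sample(qualifying_codes(s), 1L), "")
    surg <- tibble::tibble(uli = uli_out[keep], service_date = event_date[keep],
                           proc_code = code, coding_system = sys)
    # Non-surgical noise claims exercise the code filter downstream.
    noisy <- !is.na(uli_out) & stats::runif(n) < config$noise_claim_rate
    noise_date <- dx_date[noisy] +
      sample.int(549L, sum(noisy), replace = TRUE) - 1L
    noise_sys <- if (source == "billing") {
      rep("CCP", sum(noisy))
    } else {
      as.character(ifelse(noise_date < as.Date("2002-04-01"),
                          "ICD9CM", "CCI"))
    }
    noise <- tibble::tibble(uli = uli_out[noisy], service_date = noise_date,
                            proc_code = "NOTSURG1", coding_system = noise_sys)
    dplyr::arrange(dplyr::bind_rows(surg, noise), .data$uli,
                   .data$service_date, .data$proc_code)
  }

  billing <- make_claims(billing_date, "billing")
  hospital <- make_claims(hospital_date, "hospital")

  truth_log <- tibble::tibble(
    patient = seq_len(n), uli = uli_out, excluded = excl,
    dx_date = dx_date, stage = latent_stage, site = site,
    surgery = surgery, surgery_date = surgery_date,
    registry_only = registry_only,
    billing_captured = cap_b, hospital_captured = cap_h,
    billing_jittered = jit_b, hospital_jittered = jit_h,
    fp_event_billing = fp_event_b, fp_event_hospital = fp_event_h,
    fp_captured_billing = fp_cap_b, fp_captured_hospital = fp_cap_h
  )

  out <- list(registry = registry, billing = billing, hospital = hospital,
              truth_log = truth_log)
  class(out) <- "linked_datasets"
  out
}

#' @export
print.linked_datasets <- function(x, ...) {
  cat("Synthetic linked datasets\n")
  cat(sprintf("  registry: %d records\n", nrow(x$registry)))
  cat(sprintf("  billing:  %d claims\n", nrow(x$billing)))
  cat(sprintf("  hospital: %d claims\n", nrow(x$hospital)))
  invisible(x)
}

#' Write the three linked datasets as CSV files
#'
#' Dates are written ISO-8601 (`YYYY-MM-DD`); missing values are empty
#' fields. Files are named `registry.csv`, `billing.csv`, `hospital.csv`
#' (and `truth_log.csv` when requested).
#'
#' @param datasets A `linked_datasets` object from [generate_cohort()].
#' @param dir Output directory, created if absent.
#' @param truth_log Also write the latent truth log (default `FALSE`).
#' @return Invisibly, the paths written.
#' @export
write_datasets <- function(datasets, dir, truth_log = FALSE) {
  assert_that(inherits(datasets, "linked_datasets"),
              "'datasets' must come from generate_cohort()")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  parts <- c("registry", "billing", "hospital",
             if (truth_log) "truth_log")
  paths <- file.path(dir, paste0(parts, ".csv"))
  for (i in seq_along(parts)) {
    readr::write_csv(datasets[[parts[i]]], paths[i], na = "")
  }
  invisible(paths)
}
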