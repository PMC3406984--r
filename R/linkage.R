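# Diagnosis-anchored first-surgery linkage.

#' Diagnosis-anchored linkage window
#'
#' Administrative claims qualify when their service date lies within a
#' closed interval around the diagnosis date. The default window runs from
#' 7 days before diagnosis (to absorb small date inaccuracies in billing
#' claims) to 548 days (1.5 years) after.
#'
#' @param lower_offset Integer lower bound in days (default `-7`).
#' @param upper_offset Integer upper bound in days (default `548`).
#' @return A list of class `linkage_window`.
#' @export
linkage_window <- function(lower_offset = -7L, upper_offset = 548L) {
  assert_that(is.numeric(lower_offset) && is.numeric(upper_offset) &&
                lower_offset < upper_offset,
              "'lower_offset' must be strictly less than 'upper_offset'")
  structure(list(lower_offset = as.integer(lower_offset),
                 upper_offset = as.integer(upper_offset)),
            class = "linkage_window")
}

#' Read a qualifying-procedure code list from CSV
#'
#' The file must have columns `coding_system` and `code`; published surgery
#' code lists can be supplied in this form.
#'
#' @param path Path to the code-list CSV.
#' @return Tibble with columns `coding_system`, `code`.
#' @export
read_code_list <- function(path) {
  assert_that(file.exists(path), sprintf("code list not found: %s", path))
  codes <- readr::read_csv(path, col_types = readr::cols(
    coding_system = readr::col_character(),
    code = readr::col_character()))
  assert_that(nrow(codes) > 0, "code list is empty")
  codes
}

#' Select a patient's first qualifying surgery in one source
#'
#' Returns the earliest claim whose procedure code is on the qualifying
#' list for its coding system and whose service date falls inside the
#' closed window `[dx_date + lower_offset, dx_date + upper_offset]`. Ties
#' on the same date are broken by procedure code (lexicographic), so the
#' result does not depend on input row order.
#'
#' @param claims Tibble of claims for one patient and source (`uli`,
#'   `service_date`, `proc_code`, `coding_system`).
#' @param dx_date The patient's diagnosis date.
#' @param window A [linkage_window()].
#' @param codes Code list tibble (`coding_system`, `code`).
#' @return A one-row tibble (`uli`, `date`, `proc_code`) or `NULL` when no
#'   claim qualifies.
#' @examples
#' cl <- tibble::tibble(uli = "A", service_date = as.Date("2003-06-03"),
#'                      proc_code = "SURG01", coding_system = "CCP")
#' identify_first_surgery(cl, as.Date("2003-06-10"), linkage_window(),
#'                        default_code_list())
#' @export
identify_first_surgery <- function(claims, dx_date, window = linkage_window(),
                                   codes = default_code_list()) {
  assert_that(length(unique(claims$uli)) <= 1,
              "claims must belong to a single patient")
  if (anyNA(claims$service_date)) {
    stop(sprintf("unparseable claim date at row %d",
                 which(is.na(claims$service_date))[1]), call. = FALSE)
  }
  ok <- dplyr::semi_join(
    claims,
    dplyr::rename(codes, proc_code = "code"),
    by = c("coding_system", "proc_code"))
  ok <- ok[ok$service_date >= dx_date + window$lower_offset &
             ok$service_date <= dx_date + window$upper_offset, , drop = FALSE]
  if (nrow(ok) == 0) return(NULL)
  ok <- ok[order(ok$service_date, ok$proc_code), , drop = FALSE]
  tibble::tibble(uli = ok$uli[1], date = ok$service_date[1],
                 proc_code = ok$proc_code[1])
}

#' Combine billing and hospital surgery events into one indicator
#'
#' Rules for the combined administrative dataset: an event present in only
#' one source is taken as is; when both sources have events with different
#' dates the earlier date is used; equal dates yield that date with the
#' source tagged `"combined"`.
#'
#' @param billing_event,hospital_event One-row tibbles (`uli`, `date`) or
#'   `NULL`.
#' @return A one-row tibble (`uli`, `date`, `source`) or `NULL` when
#'   neither source has an event.
#' @export
combine_sources <- function(billing_event, hospital_event) {
  if (is.null(billing_event) && is.null(hospital_event)) return(NULL)
  if (!is.null(billing_event) && !is.null(hospital_event)) {
    assert_that(billing_event$uli == hospital_event$uli,
                "events belong to different patients")
    if (billing_event$date < hospital_event$date) {
      src <- "billing"; d <- billing_event$date
    } else if (hospital_event$date < billing_event$date) {
      src <- "hospital"; d <- hospital_event$date
    } else {
      src <- "combined"; d <- billing_event$date
    }
    return(tibble::tibble(uli = billing_event$uli, date = d, source = src))
  }
  ev <- if (is.null(billing_event)) hospital_event else billing_event
  src <- if (is.null(billing_event)) "hospital" else "billing"
  tibble::tibble(uli = ev$uli, date = ev$date, source = src)
}

# Internal: vectorised first-surgery selection for a whole claims file
# against the cohort; same semantics as identify_first_surgery().
first_surgery_table <- function(claims, cohort, window, codes) {
  lookup <- dplyr::select(cohort, "uli", "dx_date")
  q <- dplyr::inner_join(
    dplyr::semi_join(claims, dplyr::rename(codes, proc_code = "code"),
                     by = c("coding_system", "proc_code")),
    lookup, by = "uli")
  q <- q[q$service_date >= q$dx_date + window$lower_offset &
           q$service_date <= q$dx_date + window$upper_offset, , drop = FALSE]
  q <- q[order(q$uli, q$service_date, q$proc_code), , drop = FALSE]
  q <- q[!duplicated(q$uli), , drop = FALSE]
  tibble::tibble(uli = q$uli, date = q$service_date)
}

#' Link a cohort to its administrative surgery events
#'
#' Builds the per-patient linkage table underlying every validation
#' measure: exactly one row per cohort patient carrying the registry truth
#' (surgery yes/no and date) and the first qualifying surgery event, if
#' any, in billing, hospital, and the combined administrative dataset.
#' Claims whose identifier is not in the cohort are dropped. The registry
#' indicator is not windowed: a recorded registry surgery counts as truth
#' regardless of its offset from diagnosis.
#'
#' @param cohort Cohort tibble from [apply_inclusion()].
#' @param billing,hospital Claims tibbles.
#' @param window A [linkage_window()].
#' @param codes Code list tibble (`coding_system`, `code`).
#' @return Tibble with one row per patient: `uli`, `dx_date`, `dx_year`,
#'   `stage`, `tumor_site`, `registry_flag`, `registry_date`,
#'   `billing_flag`, `billing_date`, `hospital_flag`, `hospital_date`,
#'   `combined_flag`, `combined_date`, `combined_source`.
#' @export
link_cohort <- function(cohort, billing, hospital,
                        window = linkage_window(),
                        codes = default_code_list()) {
  assert_that(!anyDuplicated(cohort$uli),
              "cohort identifiers must be unique")
  b <- dplyr::rename(first_surgery_table(billing, cohort, window, codes),
                     billing_date = "date")
  h <- dplyr::rename(first_surgery_table(hospital, cohort, window, codes),
                     hospital_date = "date")
  out <- dplyr::select(cohort, "uli", "dx_date", "dx_year", "stage",
                       "tumor_site", registry_date = "surgery_date")
  out <- dplyr::left_join(out, b, by = "uli")
  out <- dplyr::left_join(out, h, by = "uli")
  out$registry_flag <- !is.na(out$registry_date)
  out$billing_flag <- !is.na(out$billing_date)
  out$hospital_flag <- !is.na(out$hospital_date)
  out$combined_flag <- out$billing_flag | out$hospital_flag
  out$combined_date <- pmin(out$billing_date, out$hospital_date, na.rm = TRUE)
  out$combined_source <- dplyr::case_when(
    !out$combined_flag ~ NA_character_,
    out$billing_flag & !out$hospital_flag ~ "billing",
    !out$billing_flag & out$hospital_flag ~ "hospital",
    out$billing_date < out$hospital_date ~ "billing",
    out$hospital_date < out$billing_date ~ "hospital",
    TRUE ~ "combined"
  )
  dplyr::select(out, "uli", "dx_date", "dx_year", "stage", "tumor_site",
                "registry_flag", "registry_date",
                "billing_flag", "billing_date",
                "hospital_flag", "hospital_date",
                "combined_flag", "combined_date", "combined_source")
}
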