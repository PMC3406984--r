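# Cohort inclusion and exclusion rules.

# ICD-O topography codes defining the cohort. Note c18.1 (appendix) is
# deliberately absent from the colon list.
colon_site_codes <- c("c18.0", paste0("c18.", 2:9))
rectum_site_codes <- c("c19.9", "c20.9")

#' Classify ICD-O topography codes as colon, rectum, or neither
#'
#' Colon is `c18.0, c18.2-c18.9` (the appendix, `c18.1`, does not qualify);
#' rectum is `c19.9` and `c20.9`. Matching is case-insensitive.
#'
#' @param site_code Character vector of ICD-O topography codes.
#' @return Character vector with values `"colon"`, `"rectum"`, or `NA` for
#'   non-qualifying codes.
#' @examples
#' classify_tumor_site(c("C18.0", "c18.1", "c20.9"))
#' @export
classify_tumor_site <- function(site_code) {
  sc <- tolower(trimws(site_code))
  dplyr::case_when(
    sc %in% colon_site_codes ~ "colon",
    sc %in% rectum_site_codes ~ "rectum",
    TRUE ~ NA_character_
  )
}

#' Read a registry extract from CSV
#'
#' Expects columns `uli`, `dx_date`, `site_code`, `stage`,
#' `histology_stageable`, `surgery_date`; dates ISO-8601, empty fields
#' missing.
#'
#' @param path Path to the registry CSV file.
#' @return Tibble of registry records.
#' @export
read_registry <- function(path) {
  assert_that(file.exists(path), sprintf("registry file not found: %s", path))
  readr::read_csv(path, col_types = readr::cols(
    uli = readr::col_character(),
    dx_date = readr::col_date(),
    site_code = readr::col_character(),
    stage = readr::col_character(),
    histology_stageable = readr::col_logical(),
    surgery_date = readr::col_date()
  ))
}

#' Read an administrative claims file from CSV
#'
#' Expects columns `uli`, `service_date`, `proc_code`, `coding_system`.
#'
#' @param path Path to the claims CSV file.
#' @return Tibble of claims.
#' @export
read_claims <- function(path) {
  assert_that(file.exists(path), sprintf("claims file not found: %s", path))
  readr::read_csv(path, col_types = readr::cols(
    uli = readr::col_character(),
    service_date = readr::col_date(),
    proc_code = readr::col_character(),
    coding_system = readr::col_character()
  ))
}

#' Apply cohort inclusion and exclusion rules to registry records
#'
#' Keeps records with a qualifying colorectal topography code, a
#' non-missing unique lifetime identifier (ULI), a stageable histology,
#' and a stage other than 0 (in-situ). Records whose stage is missing for
#' reasons other than unstageable histology are retained and later form
#' the "Missing" stage stratum. Exclusions are counted once each with
#' fixed priority: non-qualifying site (out-of-scope input, tallied
#' separately), then missing ULI, then unstageable histology, then
#' stage 0.
#'
#' @param records Tibble of registry records (`uli`, `dx_date`,
#'   `site_code`, `stage`, `histology_stageable`, `surgery_date`).
#' @return List with `cohort` (included records plus derived `tumor_site`
#'   and `dx_year` columns) and `tally`, a one-row tibble with `n_input`,
#'   `n_nonqualifying_site`, `n_missing_uli`, `n_unstageable`, `n_stage0`,
#'   `n_included`.
#' @examples
#' recs <- tibble::tibble(
#'   uli = c("A", NA, "C"), dx_date = as.Date("2003-01-01") + 0:2,
#'   site_code = c("c18.0", "c18.2", "c20.9"),
#'   stage = c("II", "III", "0"), histology_stageable = TRUE,
#'   surgery_date = as.Date(NA))
#' apply_inclusion(recs)$tally
#' @export
apply_inclusion <- function(records) {
  needed <- c("uli", "dx_date", "site_code", "stage", "histology_stageable",
              "surgery_date")
  assert_that(all(needed %in% names(records)),
              paste("registry records must have columns:",
                    paste(needed, collapse = ", ")))

  stage_chr <- trimws(toupper(as.character(records$stage)))
  stage_chr[stage_chr == ""] <- NA_character_
  bad_stage <- which(!is.na(stage_chr) &
                       !stage_chr %in% c("0", "I", "II", "III", "IV"))
  if (length(bad_stage) > 0) {
    stop(sprintf("unparseable stage value '%s' at row %d",
                 records$stage[bad_stage[1]], bad_stage[1]), call. = FALSE)
  }

  site <- classify_tumor_site(records$site_code)
  reason <- dplyr::case_when(
    is.na(site) ~ "nonqualifying_site",
    is.na(records$uli) | trimws(records$uli) == "" ~ "missing_uli",
    !records$histology_stageable ~ "unstageable",
    !is.na(stage_chr) & stage_chr == "0" ~ "stage0",
    TRUE ~ "included"
  )

  tally <- tibble::tibble(
    n_input = nrow(records),
    n_nonqualifying_site = sum(reason == "nonqualifying_site"),
    n_missing_uli = sum(reason == "missing_uli"),
    n_unstageable = sum(reason == "unstageable"),
    n_stage0 = sum(reason == "stage0"),
    n_included = sum(reason == "included")
  )

  cohort <- records[reason == "included", , drop = FALSE]
  cohort$stage <- stage_chr[reason == "included"]
  cohort$tumor_site <- site[reason == "included"]
  cohort$dx_year <- as.integer(format(cohort$dx_date, "%Y"))

  message(sprintf(
    "cohort: %d of %d records included (%d non-site, %d missing ULI, %d unstageable, %d stage 0)",
    tally$n_included, tally$n_input, tally$n_nonqualifying_site,
    tally$n_missing_uli, tally$n_unstageable, tally$n_stage0))

  list(cohort = tibble::as_tibble(cohort), tally = tally)
}
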