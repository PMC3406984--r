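# Shared fixtures: all test data are built in code.

# A noiseless generator configuration: every registry surgery is captured
# by both sources on the registry date, no false positives, no exclusions.
perfect_config <- function(n = 500, seed = 11) {
  generator_config(
    n_patients = n,
    source_capture_prob = c(billing = 1, hospital = 1),
    false_positive_prob = c(I = 0, II = 0, III = 0, IV = 0, missing = 0),
    registry_only_prob = c(I = 0, II = 0, III = 0, IV = 0, missing = 0),
    date_jitter_prob = 0,
    missing_uli_rate = 0, unstageable_rate = 0, stage0_rate = 0,
    noise_claim_rate = 0,
    rng_seed = seed
  )
}

make_claims <- function(uli, service_date, proc_code = "SURG01",
                        coding_system = "CCP") {
  tibble::tibble(uli = uli, service_date = as.Date(service_date),
                 proc_code = proc_code, coding_system = coding_system)
}

make_registry <- function(uli, dx_date, site_code = "c18.0", stage = "II",
                          histology_stageable = TRUE, surgery_date = NA) {
  tibble::tibble(uli = uli, dx_date = as.Date(dx_date),
                 site_code = site_code, stage = stage,
                 histology_stageable = histology_stageable,
                 surgery_date = as.Date(surgery_date))
}

# A deterministic registry mirroring the published exclusion seeding:
# within n records, the stated numbers are missing the identifier, have an
# unstageable histology, or are stage 0; everything else is includable.
seeded_registry <- function(n = 8533, n_missing_uli = 2, n_unstageable = 140,
                            n_stage0 = 83) {
  uli <- sprintf("U%05d", seq_len(n))
  uli[seq_len(n_missing_uli)] <- NA_character_
  stageable <- rep(TRUE, n)
  stageable[n_missing_uli + seq_len(n_unstageable)] <- FALSE
  stage <- rep(c("I", "II", "III", "IV"), length.out = n)
  stage[n_missing_uli + seq_len(n_unstageable)] <- NA_character_
  stage[n_missing_uli + n_unstageable + seq_len(n_stage0)] <- "0"
  tibble::tibble(
    uli = uli, dx_date = as.Date("2003-01-01"),
    site_code = rep(c("c18.0", "c20.9"), length.out = n),
    stage = stage, histology_stageable = stageable,
    surgery_date = as.Date(NA)
  )
}
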