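# End-to-end pipeline orchestration and stratified reporting.

#' Render a count as a whole percentage of a denominator
#'
#' Uses half-up rounding, the convention of printed frequency tables.
#'
#' @param count,denom Counts, `denom >= 1`.
#' @return Integer whole percent.
#' @examples
#' render_percent(7066, 8308)
#' @export
render_percent <- function(count, denom) {
  assert_that(all(denom >= 1), "'denom' must be at least 1")
  as.integer(round_half_up(100 * count / denom))
}

# Internal: enumerate report strata in fixed order:
# all -> year (ascending) -> stage (I, II, III, IV, Missing) -> site.
stratum_table <- function(linkage) {
  stage_levels <- c("I", "II", "III", "IV")
  rows <- list(tibble::tibble(factor = "all", level = "all"))
  yrs <- sort(unique(linkage$dx_year))
  rows <- c(rows, list(tibble::tibble(factor = "year",
                                      level = as.character(yrs))))
  st <- c(stage_levels[stage_levels %in% linkage$stage],
          if (anyNA(linkage$stage)) "Missing")
  rows <- c(rows, list(tibble::tibble(factor = "stage", level = st)))
  si <- c("colon", "rectum")[c("colon", "rectum") %in% linkage$tumor_site]
  rows <- c(rows, list(tibble::tibble(factor = "site", level = si)))
  dplyr::bind_rows(rows)
}

# Internal: logical row selector for one stratum.
stratum_rows <- function(linkage, factor, level) {
  switch(factor,
    all = rep(TRUE, nrow(linkage)),
    year = linkage$dx_year == as.integer(level),
    stage = if (level == "Missing") is.na(linkage$stage)
            else !is.na(linkage$stage) & linkage$stage == level,
    site = linkage$tumor_site == level,
    stop(sprintf("unknown stratum factor '%s'", factor), call. = FALSE)
  )
}

#' Run the validation pipeline end to end
#'
#' Applies cohort inclusion rules, links the cohort to its first
#' qualifying surgery per administrative source, and produces the two
#' standard reports: a count report (patients with surgery per source,
#' with whole percentages) and a stratified measure report (sensitivity,
#' specificity, PPV, NPV, observed agreement per source), both overall
#' and by year of diagnosis, stage, and tumor site, plus date-agreement
#' summaries.
#'
#' @param registry Registry tibble (see [read_registry()]) or a path to
#'   its CSV.
#' @param billing,hospital Claims tibbles (see [read_claims()]) or paths.
#' @param codes Code list tibble or path (default [default_code_list()]).
#' @param window A [linkage_window()].
#' @param ci_method `"wilson"` (default) or `"wald"`.
#' @return List with `tally` (exclusion counts), `linkage` (per-patient
#'   table), `table1` (counts and percents per stratum and source),
#'   `table2` (tidy measures: `stratum_factor`, `stratum_level`, `source`,
#'   `measure`, `estimate_pct`, `ci_low_pct`, `ci_high_pct`, `unstable`,
#'   `defined`), and `date_report`.
#' @export
run_pipeline <- function(registry, billing, hospital,
                         codes = default_code_list(),
                         window = linkage_window(),
                         ci_method = c("wilson", "wald")) {
  ci_method <- match.arg(ci_method)
  if (is.character(registry)) registry <- read_registry(registry)
  if (is.character(billing)) billing <- read_claims(billing)
  if (is.character(hospital)) hospital <- read_claims(hospital)
  if (is.character(codes)) codes <- read_code_list(codes)

  built <- apply_inclusion(registry)
  linkage <- link_cohort(built$cohort, billing, hospital, window, codes)
  strata <- stratum_table(linkage)
  sources <- c("registry", "billing", "hospital", "combined")

  table1 <- dplyr::bind_rows(lapply(seq_len(nrow(strata)), function(i) {
    rows <- stratum_rows(linkage, strata$factor[i], strata$level[i])
    sub <- linkage[rows, , drop = FALSE]
    out <- tibble::tibble(stratum_factor = strata$factor[i],
                          stratum_level = strata$level[i], n = nrow(sub))
    for (s in sources) {
      cnt <- sum(sub[[paste0(s, "_flag")]])
      out[[paste0(s, "_n")]] <- cnt
      out[[paste0(s, "_pct")]] <- if (nrow(sub) > 0)
        render_percent(cnt, nrow(sub)) else NA_integer_
    }
    out
  }))

  table2 <- dplyr::bind_rows(lapply(seq_len(nrow(strata)), function(i) {
    rows <- stratum_rows(linkage, strata$factor[i], strata$level[i])
    if (!any(rows)) return(NULL)
    dplyr::bind_rows(lapply(c("billing", "hospital", "combined"),
                            function(s) {
      meas <- compute_measures(cross_tabulate(linkage, s, rows),
                               ci_method = ci_method)
      tibble::tibble(
        stratum_factor = strata$factor[i], stratum_level = strata$level[i],
        source = s, measure = meas$measure,
        estimate_pct = ifelse(meas$defined,
                              render_percent_safe(meas$estimate), NA_integer_),
        ci_low_pct = round(100 * meas$ci_low, 1),
        ci_high_pct = round(100 * meas$ci_high, 1),
        unstable = meas$unstable, defined = meas$defined)
    }))
  }))

  date_report <- dplyr::bind_rows(lapply(c("billing", "hospital", "combined"),
                                         function(s) {
    da <- date_agreement(linkage, s)
    tibble::tibble(source = s, n_pairs = da$n_pairs,
                   exact_match_fraction = da$exact_match_fraction)
  }))

  list(tally = built$tally, linkage = linkage, table1 = table1,
       table2 = table2, date_report = date_report)
}

# Internal: half-up whole-percent of a proportion, NA-safe.
render_percent_safe <- function(p) {
  out <- rep(NA_integer_, length(p))
  ok <- !is.na(p)
  out[ok] <- as.integer(round_half_up(100 * p[ok]))
  out
}

#' Write pipeline reports as CSV files
#'
#' Writes `tally.csv`, `table1_counts.csv`, `table2_measures.csv`,
#' `date_agreement.csv`, and the per-patient `linkage.csv` to a
#' directory. Re-running on identical inputs yields byte-identical files
#' (row order is fixed: all, then year, stage, site strata).
#'
#' @param result The list returned by [run_pipeline()].
#' @param dir Output directory, created if absent.
#' @return Invisibly, the paths written.
#' @export
write_reports <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(tally = "tally.csv", table1 = "table1_counts.csv",
             table2 = "table2_measures.csv",
             date_report = "date_agreement.csv", linkage = "linkage.csv")
  paths <- file.path(dir, files)
  for (i in seq_along(files)) {
    readr::write_csv(result[[names(files)[i]]], paths[i], na = "")
  }
  invisible(paths)
}
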