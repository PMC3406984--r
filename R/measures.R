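# Diagnostic accuracy measures against registry truth.

#' Construct a 2x2 contingency table against registry truth
#'
#' Cell conventions: `tp` = registry surgery and administrative event,
#' `fp` = administrative event only, `fn` = registry surgery only,
#' `tn` = neither.
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  assert_that(all(is.finite(cells)) && all(cells >= 0) &&
                all(cells == trunc(cells)),
              "cell counts must be non-negative integers")
  structure(as.list(as.integer(cells)) |> stats::setNames(names(cells)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(source = c("surgery", "no surgery"),
                              registry = c("surgery", "no surgery")))
  print(m)
  invisible(x)
}

#' Cross-tabulate an administrative source against registry truth
#'
#' Counts true/false positives and negatives for one source over the rows
#' of a linkage table, optionally restricted to a stratum.
#'
#' @param linkage Linkage table from [link_cohort()].
#' @param source One of `"billing"`, `"hospital"`, `"combined"`.
#' @param rows Optional logical vector selecting the stratum (default all
#'   rows).
#' @return A [contingency_table()].
#' @export
cross_tabulate <- function(linkage, source, rows = NULL) {
  assert_that(source %in% c("billing", "hospital", "combined"),
              sprintf("unknown source '%s'", source))
  if (!is.null(rows)) {
    assert_that(is.logical(rows) && length(rows) == nrow(linkage),
                "'rows' must be a logical vector over the linkage rows")
    linkage <- linkage[rows & !is.na(rows), , drop = FALSE]
  }
  truth <- linkage$registry_flag
  test <- linkage[[paste0(source, "_flag")]]
  contingency_table(tp = sum(truth & test), fp = sum(!truth & test),
                    fn = sum(truth & !test), tn = sum(!truth & !test))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' The Wilson interval keeps sensible coverage near 0 and 1, which the
#' near-degenerate strata of a validation study (e.g. stage I-III surgery
#' prevalence above 98%) require. A Wald interval is available for
#' comparison.
#'
#' @param successes,n Integer counts, `0 <= successes <= n`, `n >= 1`.
#' @param level Confidence level (default 0.95).
#' @param method `"wilson"` (default) or `"wald"`.
#' @return Named numeric vector `c(lower, upper)` with bounds in `[0, 1]`.
#' @examples
#' proportion_ci(50, 100)
#' @export
proportion_ci <- function(successes, n, level = 0.95,
                          method = c("wilson", "wald")) {
  method <- match.arg(method)
  assert_that(is.numeric(successes) && is.numeric(n) && length(n) == 1 &&
                length(successes) == 1 && n >= 1 && successes >= 0 &&
                successes <= n && n == trunc(n) &&
                successes == trunc(successes),
              "'successes' and 'n' must be counts with 0 <= successes <= n")
  assert_that(level > 0 && level < 1, "'level' must be in (0, 1)")
  p <- successes / n
  z <- stats::qnorm((1 + level) / 2)
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    return(c(lower = max(0, p - half), upper = min(1, p + half)))
  }
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Flag unstable estimates
#'
#' An estimate is flagged unstable when its 95% confidence interval is
#' wider than 15 percentage points (strict), or its width is 40% or more
#' of the estimate (inclusive). Both arguments are on the percentage
#' scale.
#'
#' @param estimate_percent Point estimate in percent.
#' @param ci_percent Length-2 numeric, CI bounds in percent.
#' @return Logical.
#' @export
flag_instability <- function(estimate_percent, ci_percent) {
  width <- ci_percent[2] - ci_percent[1]
  unname(width > 15 | width >= 0.40 * estimate_percent)
}

#' Compute validation measures from a 2x2 table
#'
#' Computes sensitivity, specificity, positive and negative predictive
#' value, and observed agreement of an administrative source against
#' registry truth, each with a confidence interval and an instability
#' flag. A measure whose denominator is zero is undefined: its estimate
#' and interval are `NA` and `defined` is `FALSE` (never reported as 0 or
#' 100).
#'
#' @param table A [contingency_table()].
#' @param ci_method `"wilson"` (default) or `"wald"`.
#' @param level Confidence level (default 0.95).
#' @return Tibble with one row per measure: `measure`, `numerator`,
#'   `denominator`, `estimate` (proportion), `ci_low`, `ci_high`,
#'   `defined`, `unstable`.
#' @examples
#' compute_measures(contingency_table(10, 0, 0, 5))
#' @export
compute_measures <- function(table, ci_method = c("wilson", "wald"),
                             level = 0.95) {
  ci_method <- match.arg(ci_method)
  assert_that(inherits(table, "contingency_table"),
              "'table' must be a contingency_table")
  n <- table$tp + table$fp + table$fn + table$tn
  assert_that(n >= 1, "table must contain at least one observation")
  spec_rows <- list(
    sensitivity = c(table$tp, table$tp + table$fn),
    specificity = c(table$tn, table$tn + table$fp),
    ppv = c(table$tp, table$tp + table$fp),
    npv = c(table$tn, table$tn + table$fn),
    agreement = c(table$tp + table$tn, n)
  )
  rows <- lapply(names(spec_rows), function(m) {
    num <- spec_rows[[m]][1]
    den <- spec_rows[[m]][2]
    if (den == 0) {
      return(tibble::tibble(measure = m, numerator = num, denominator = den,
                            estimate = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, defined = FALSE,
                            unstable = NA))
    }
    est <- num / den
    ci <- proportion_ci(num, den, level = level, method = ci_method)
    tibble::tibble(measure = m, numerator = num, denominator = den,
                   estimate = est, ci_low = ci[["lower"]],
                   ci_high = ci[["upper"]], defined = TRUE,
                   unstable = flag_instability(100 * est, 100 * ci))
  })
  dplyr::bind_rows(rows)
}

#' Agreement between administrative and registry surgery dates
#'
#' Among true positives (patients with both a registry surgery date and an
#' event in the source), tabulates the day difference administrative minus
#' registry date and the fraction matching exactly.
#'
#' @param linkage Linkage table from [link_cohort()].
#' @param source One of `"billing"`, `"hospital"`, `"combined"`.
#' @return List with `n_pairs`, `exact_match_fraction` (`NA` when there
#'   are no pairs), and `difference_histogram`, a tibble
#'   (`day_offset`, `count`).
#' @export
date_agreement <- function(linkage, source) {
  assert_that(source %in% c("billing", "hospital", "combined"),
              sprintf("unknown source '%s'", source))
  d <- linkage[[paste0(source, "_date")]]
  keep <- !is.na(d) & !is.na(linkage$registry_date)
  diffs <- as.integer(d[keep] - linkage$registry_date[keep])
  hist <- tibble::tibble(day_offset = as.integer(names(table(diffs))),
                         count = as.integer(table(diffs)))
  list(
    n_pairs = length(diffs),
    exact_match_fraction = if (length(diffs) == 0) NA_real_
                           else mean(diffs == 0),
    difference_histogram = hist
  )
}
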