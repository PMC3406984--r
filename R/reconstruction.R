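# Reconstruction of integer 2x2 tables from published marginal counts and
# rounded whole-percent measures.

#' Marginal specification of a 2x2 table
#'
#' The three counts a published frequency table typically provides: the
#' analysis denominator, the number positive by the gold standard, and the
#' number positive by the source under evaluation.
#'
#' @param n Total count.
#' @param truth_pos Gold-standard positives (`<= n`).
#' @param test_pos Source positives (`<= n`).
#' @return A list of class `marginal_spec`.
#' @export
marginal_spec <- function(n, truth_pos, test_pos) {
  assert_that(all(c(n, truth_pos, test_pos) >= 0) &&
                all(c(n, truth_pos, test_pos) ==
                      trunc(c(n, truth_pos, test_pos))) &&
                truth_pos <= n && test_pos <= n,
              "marginals must be counts with truth_pos <= n, test_pos <= n")
  structure(list(n = as.integer(n), truth_pos = as.integer(truth_pos),
                 test_pos = as.integer(test_pos)), class = "marginal_spec")
}

# Internal: expand a tp value and marginals to the four cells (may be
# negative; caller checks feasibility).
cells_from_tp <- function(m, tp) {
  fp <- m$test_pos - tp
  fn <- m$truth_pos - tp
  tn <- m$n - tp - fp - fn
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Reconstruct a 2x2 table from marginals and one rounded measure
#'
#' Published validation tables report marginal counts and whole-percent
#' measures but not the underlying cross-tabulation. Given the marginals
#' and a single seed measure, the table is determined: the seed percentage
#' is converted back to a count with the stated rounding convention, and
#' the remaining cells follow from the marginals.
#'
#' Seed conversions (half-up rounding by default):
#' * `sensitivity` -> `tp = round(seed/100 * truth_pos)`
#' * `specificity` -> `tn = round(seed/100 * (n - truth_pos))`
#' * `ppv` -> `tp = round(seed/100 * test_pos)`
#' * `npv` -> `tn = round(seed/100 * (n - test_pos))`
#' * `agreement` -> `tp + tn = round(seed/100 * n)`, split using
#'   `tp - tn = test_pos - (n - truth_pos)`; when the implied split is odd
#'   the half is floored (`tp` takes the smaller part).
#'
#' @param m A [marginal_spec()].
#' @param seed_measure One of `"sensitivity"`, `"specificity"`, `"ppv"`,
#'   `"npv"`, `"agreement"`.
#' @param seed_percent The printed whole-percent value.
#' @param rounding `"half-up"` (default, the convention of printed
#'   tables) or `"half-even"`.
#' @return A [contingency_table()], or `NULL` with a warning when the seed
#'   implies a negative cell (infeasible).
#' @examples
#' m <- marginal_spec(8308, 7066, 7173)
#' reconstruct_from_seed(m, "specificity", 72)
#' @export
reconstruct_from_seed <- function(m, seed_measure, seed_percent,
                                  rounding = c("half-up", "half-even")) {
  rounding <- match.arg(rounding)
  assert_that(inherits(m, "marginal_spec"), "'m' must be a marginal_spec")
  seed_measure <- match.arg(seed_measure,
                            c("sensitivity", "specificity", "ppv", "npv",
                              "agreement"))
  assert_that(is.numeric(seed_percent) && seed_percent >= 0 &&
                seed_percent <= 100,
              "'seed_percent' must be in [0, 100]")
  truth_neg <- m$n - m$truth_pos
  test_neg <- m$n - m$test_pos
  frac <- seed_percent / 100

  cells <- switch(seed_measure,
    sensitivity = cells_from_tp(m, round_percent(frac * m$truth_pos, rounding)),
    ppv = cells_from_tp(m, round_percent(frac * m$test_pos, rounding)),
    specificity = {
      tn <- round_percent(frac * truth_neg, rounding)
      cells_from_tp(m, m$test_pos - (truth_neg - tn))
    },
    npv = {
      tn <- round_percent(frac * test_neg, rounding)
      cells_from_tp(m, m$truth_pos - (test_neg - tn))
    },
    agreement = {
      s <- round_percent(frac * m$n, rounding)   # tp + tn
      d <- m$test_pos - truth_neg                # tp - tn
      tp <- floor((s + d) / 2)                   # odd split: floor the half
      cells_from_tp(m, tp)
    }
  )
  if (any(cells < 0)) {
    warning(sprintf(
      "seed %s = %s%% is infeasible for these marginals (negative cell)",
      seed_measure, format(seed_percent)), call. = FALSE)
    return(NULL)
  }
  contingency_table(cells[["tp"]], cells[["fp"]], cells[["fn"]],
                    cells[["tn"]])
}

#' Enumerate all tables consistent with a set of rounded measures
#'
#' Exhaustively scans every feasible `tp` given the marginals and returns
#' those for which each supplied measure, computed at full precision and
#' rounded to whole percent, equals its stated value. An empty result
#' means the published measures are jointly inconsistent with the
#' marginals under the chosen rounding convention.
#'
#' @param m A [marginal_spec()].
#' @param measures Named numeric vector or list with any of
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `agreement`, each a
#'   whole-percent integer in `[0, 100]`.
#' @param rounding `"half-up"` (default) or `"half-even"`.
#' @return Integer vector of feasible `tp` values (possibly empty).
#' @examples
#' feasible_tp_set(marginal_spec(10, 5, 5),
#'                 c(sensitivity = 100, specificity = 100))
#' @export
feasible_tp_set <- function(m, measures,
                            rounding = c("half-up", "half-even")) {
  rounding <- match.arg(rounding)
  assert_that(inherits(m, "marginal_spec"), "'m' must be a marginal_spec")
  measures <- unlist(measures)
  known <- c("sensitivity", "specificity", "ppv", "npv", "agreement")
  assert_that(length(measures) >= 1 && all(names(measures) %in% known),
              "supply at least one named measure")
  assert_that(all(measures == trunc(measures)) &&
                all(measures >= 0 & measures <= 100),
              "measures must be whole-percent values in [0, 100]")

  tp <- 0:min(m$truth_pos, m$test_pos)
  fp <- m$test_pos - tp
  fn <- m$truth_pos - tp
  tn <- m$n - tp - fp - fn
  keep <- tn >= 0
  tp <- tp[keep]; fp <- fp[keep]; fn <- fn[keep]; tn <- tn[keep]
  feasible <- rep(TRUE, length(tp))
  ratio <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  computed <- list(
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    agreement = (tp + tn) / m$n
  )
  for (mm in names(measures)) {
    r <- round_percent(100 * computed[[mm]], rounding)
    feasible <- feasible & !is.na(r) & r == measures[[mm]]
  }
  tp[feasible]
}
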