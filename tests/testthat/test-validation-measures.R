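test_that("cross_tabulate classifies rows against registry truth", {
  reg <- make_registry("A", "2003-01-01", surgery_date = "2003-02-01")
  cohort <- suppressMessages(apply_inclusion(reg))$cohort
  tab <- link_cohort(cohort, make_claims("A", "2003-02-01"),
                     make_claims(character(0), as.Date(character(0))))
  t1 <- cross_tabulate(tab, "billing")
  expect_equal(unlist(t1[c("tp", "fp", "fn", "tn")]),
               c(tp = 1L, fp = 0L, fn = 0L, tn = 0L))
  expect_error(cross_tabulate(tab, "registry"), "unknown source")
})

test_that("cross_tabulate agrees with per-row brute-force classification", {
  ds <- generate_cohort(generator_config(n_patients = 200, rng_seed = 23))
  res <- suppressMessages(run_pipeline(ds$registry, ds$billing, ds$hospital))
  for (s in c("billing", "hospital", "combined")) {
    tab <- cross_tabulate(res$linkage, s)
    # independent oracle: classify each row one by one
    counts <- c(tp = 0, fp = 0, fn = 0, tn = 0)
    for (i in seq_len(nrow(res$linkage))) {
      truth <- res$linkage$registry_flag[i]
      test <- res$linkage[[paste0(s, "_flag")]][i]
      cell <- if (truth && test) "tp" else if (!truth && test) "fp"
              else if (truth) "fn" else "tn"
      counts[cell] <- counts[cell] + 1
    }
    expect_equal(unlist(tab[c("tp", "fp", "fn", "tn")]),
                 counts[c("tp", "fp", "fn", "tn")],
                 ignore_attr = TRUE)
  }
})

test_that("measures match the reconstructed overall billing table", {
  m <- compute_measures(contingency_table(6825, 348, 241, 894))
  pct <- stats::setNames(round_half_up(100 * m$estimate), m$measure)
  expect_equal(pct, c(sensitivity = 97, specificity = 72, ppv = 95,
                      npv = 79, agreement = 93))
})

test_that("degenerate denominators are undefined, never 0 or 100", {
  perfect <- compute_measures(contingency_table(10, 0, 0, 5))
  expect_true(all(perfect$estimate == 1))
  allneg <- compute_measures(contingency_table(0, 0, 0, 25))
  sens <- allneg[allneg$measure == "sensitivity", ]
  ppv <- allneg[allneg$measure == "ppv", ]
  expect_false(sens$defined)
  expect_false(ppv$defined)
  expect_true(is.na(sens$estimate) && is.na(ppv$estimate))
  rest <- allneg[allneg$measure %in% c("specificity", "npv", "agreement"), ]
  expect_true(all(rest$estimate == 1))
  expect_error(compute_measures(contingency_table(0, 0, 0, 0)),
               "at least one")
})

test_that("Wilson intervals match the score-test inversion", {
  # independent oracle: prop.test without continuity correction inverts the
  # same score test
  grid <- expand.grid(x = c(0, 1, 7, 50, 99, 100), n = c(100, 250))
  for (i in seq_len(nrow(grid))) {
    x <- grid$x[i]; n <- grid$n[i]
    ours <- proportion_ci(x, n)
    ref <- stats::prop.test(x, n, correct = FALSE)$conf.int
    expect_equal(unname(ours), as.numeric(ref), tolerance = 1e-10)
  }
  expect_equal(proportion_ci(0, 50)[["lower"]], 0)
  expect_equal(proportion_ci(50, 50)[["upper"]], 1)
  ci <- proportion_ci(50, 100)
  expect_equal(unname(ci), c(0.404, 0.596), tolerance = 5e-3)
  # point estimate always inside its interval
  expect_true(ci[["lower"]] <= 0.5 && 0.5 <= ci[["upper"]])
  # Wald option is symmetric about the estimate
  w <- proportion_ci(30, 100, method = "wald")
  expect_equal(mean(w), 0.3, tolerance = 1e-12)
  expect_error(proportion_ci(5, 3), "counts")
})

test_that("instability flags follow the two published clauses", {
  expect_true(flag_instability(86, c(78, 94)))   # width 16 > 15 points
  expect_true(flag_instability(30, c(25, 37)))   # width 12 >= 0.4 * 30
  expect_false(flag_instability(95, c(93, 97)))  # width 4, stable
  expect_false(flag_instability(50, c(43, 57.5)))  # width 14.5, ratio 0.29
})

test_that("Bayes and complement identities hold on random tables", {
  set.seed(42)
  for (i in 1:50) {
    cells <- stats::rmultinom(1, size = sample(50:5000, 1),
                              prob = stats::runif(4, 0.05, 1))
    t <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    m <- compute_measures(t)
    est <- stats::setNames(m$estimate, m$measure)
    if (any(!m$defined)) next
    n <- sum(cells)
    prev <- (t$tp + t$fn) / n
    expect_equal(est[["ppv"]],
                 est[["sensitivity"]] * prev /
                   (est[["sensitivity"]] * prev +
                      (1 - est[["specificity"]]) * (1 - prev)),
                 tolerance = 1e-12)
    expect_equal(est[["agreement"]],
                 est[["sensitivity"]] * prev +
                   est[["specificity"]] * (1 - prev),
                 tolerance = 1e-12)
  }
})

test_that("adding a true positive never decreases sens, PPV, agreement", {
  set.seed(7)
  for (i in 1:25) {
    cells <- as.integer(stats::runif(4, 0, 200))
    t0 <- contingency_table(cells[1], cells[2], cells[3], cells[4] + 1)
    t1 <- contingency_table(cells[1] + 1, cells[2], cells[3], cells[4] + 1)
    m0 <- compute_measures(t0)
    m1 <- compute_measures(t1)
    for (meas in c("sensitivity", "ppv", "agreement")) {
      e0 <- m0$estimate[m0$measure == meas]
      e1 <- m1$estimate[m1$measure == meas]
      if (!is.na(e0) && !is.na(e1)) expect_gte(e1, e0)
    }
  }
})

test_that("date agreement counts day differences among true positives", {
  reg <- make_registry(sprintf("P%02d", 1:10), "2003-01-01",
                       surgery_date = "2003-03-01")
  cohort <- suppressMessages(apply_inclusion(reg))$cohort
  dates <- rep(as.Date("2003-03-01"), 10)
  dates[10] <- dates[10] + 3
  tab <- link_cohort(cohort, make_claims(reg$uli, dates),
                     make_claims(character(0), as.Date(character(0))))
  da <- date_agreement(tab, "billing")
  expect_equal(da$n_pairs, 10)
  expect_equal(da$exact_match_fraction, 0.9)
  expect_equal(da$difference_histogram$count[da$difference_histogram$day_offset == 0], 9L)
  # no pairs: fraction undefined
  empty <- date_agreement(tab[0, ], "billing")
  expect_equal(empty$n_pairs, 0)
  expect_true(is.na(empty$exact_match_fraction))
})
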