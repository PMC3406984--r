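test_that("seeding with a specificity recovers the full table", {
  m <- marginal_spec(8308, 7066, 7173)
  t <- reconstruct_from_seed(m, "specificity", 72)
  expect_equal(unlist(t[c("tp", "fp", "fn", "tn")]),
               c(tp = 6825L, fp = 348L, fn = 241L, tn = 894L))
})

test_that("seeding with an agreement splits the diagonal as specified", {
  m <- marginal_spec(8308, 7066, 6905)
  t <- reconstruct_from_seed(m, "agreement", 92)
  expect_equal(t$tp, 6653L)
  expect_equal(t$tn, 990L)
})

test_that("a perfect sensitivity seed yields the perfect table", {
  t <- reconstruct_from_seed(marginal_spec(100, 50, 50), "sensitivity", 100)
  expect_equal(unlist(t[c("tp", "fp", "fn", "tn")]),
               c(tp = 50L, fp = 0L, fn = 0L, tn = 50L))
})

test_that("infeasible seeds warn and return NULL rather than crash", {
  # sensitivity 100 forces tp = 90 > test_pos = 50, i.e. fp < 0
  expect_warning(
    out <- reconstruct_from_seed(marginal_spec(100, 90, 50),
                                 "sensitivity", 100),
    "infeasible")
  expect_null(out)
})

test_that("perfect rounded measures force the unique perfect table", {
  f <- feasible_tp_set(marginal_spec(10, 5, 5),
                       c(sensitivity = 100, specificity = 100, ppv = 100,
                         npv = 100, agreement = 100))
  expect_equal(f, 5L)
})

test_that("the published overall billing row is jointly feasible", {
  m <- marginal_spec(8308, 7066, 7173)
  stated <- c(sensitivity = 97, specificity = 72, ppv = 95, npv = 79,
              agreement = 93)
  f <- feasible_tp_set(m, stated)
  expect_gt(length(f), 0)
  # contiguous range, and every member reproduces all five roundings
  expect_equal(f, seq(min(f), max(f)))
  for (tp in f) {
    t <- contingency_table(tp, m$test_pos - tp, m$truth_pos - tp,
                           m$n - m$test_pos - m$truth_pos + tp)
    mm <- compute_measures(t)
    pct <- stats::setNames(round_half_up(100 * mm$estimate), mm$measure)
    expect_equal(pct[names(stated)], stated)
  }
})

test_that("the published overall hospital row is jointly infeasible", {
  f <- feasible_tp_set(marginal_spec(8308, 7066, 6905),
                       c(sensitivity = 94, specificity = 80, ppv = 96,
                         npv = 72, agreement = 92))
  expect_length(f, 0)
  # dropping the NPV row restores feasibility: the inconsistency is local
  f4 <- feasible_tp_set(marginal_spec(8308, 7066, 6905),
                        c(sensitivity = 94, specificity = 80, ppv = 96,
                          agreement = 92))
  expect_gt(length(f4), 0)
})

test_that("enumeration matches an independent brute force on random marginals", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(20:500, 1)
    truth_pos <- sample(0:n, 1)
    test_pos <- sample(0:n, 1)
    m <- marginal_spec(n, truth_pos, test_pos)
    # pick a realisable measure set from a random true table
    tp0 <- sample(max(0, truth_pos + test_pos - n):min(truth_pos, test_pos), 1)
    t0 <- contingency_table(tp0, test_pos - tp0, truth_pos - tp0,
                            n - test_pos - truth_pos + tp0)
    m0 <- compute_measures(t0)
    avail <- m0$measure[m0$defined]
    chosen <- sample(avail, sample(seq_along(avail), 1))
    stated <- stats::setNames(
      round_half_up(100 * m0$estimate[match(chosen, m0$measure)]), chosen)

    got <- feasible_tp_set(m, stated)
    # independent oracle: loop over all candidate tables, recompute each
    # measure from its defining ratio, and round via sprintf-free arithmetic
    oracle <- integer(0)
    for (tp in max(0, truth_pos + test_pos - n):min(truth_pos, test_pos)) {
      fp <- test_pos - tp; fn <- truth_pos - tp; tn <- n - tp - fp - fn
      vals <- c(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA,
                specificity = if (tn + fp > 0) tn / (tn + fp) else NA,
                ppv = if (tp + fp > 0) tp / (tp + fp) else NA,
                npv = if (tn + fn > 0) tn / (tn + fn) else NA,
                agreement = (tp + tn) / n)
      ok <- TRUE
      for (nm in names(stated)) {
        v <- vals[[nm]]
        if (is.na(v) || floor(100 * v + 0.5 + 1e-9) != stated[[nm]]) ok <- FALSE
      }
      if (ok) oracle <- c(oracle, tp)
    }
    expect_equal(got, oracle)
    expect_true(tp0 %in% got)
  }
})

test_that("a feasible seed reproduces its own measure on re-rounding", {
  set.seed(123)
  measures <- c("sensitivity", "specificity", "ppv", "npv", "agreement")
  # denominators of a few hundred or more: below that a whole-percent value
  # need not be attainable by any integer cell at all
  for (rep in 1:40) {
    n <- sample(300:5000, 1)
    truth_pos <- sample(100:(n - 100), 1)
    test_pos <- sample(100:(n - 100), 1)
    m <- marginal_spec(n, truth_pos, test_pos)
    seed_m <- sample(measures, 1)
    seed_v <- sample(5:95, 1)
    t <- suppressWarnings(reconstruct_from_seed(m, seed_m, seed_v))
    if (is.null(t)) next
    mm <- compute_measures(t)
    got <- round_half_up(100 * mm$estimate[mm$measure == seed_m])
    expect_equal(got, seed_v)
  }
})

test_that("half-even rounding is available as a sensitivity probe", {
  m <- marginal_spec(1000, 500, 500)
  # 0.125 * 400 -> 50.0; direct check that the convention switch matters
  t_up <- reconstruct_from_seed(m, "sensitivity", 50)
  expect_equal(t_up$tp, 250L)
  expect_s3_class(reconstruct_from_seed(m, "sensitivity", 50,
                                        rounding = "half-even"),
                  "contingency_table")
  f_even <- feasible_tp_set(marginal_spec(8308, 7066, 6905),
                            c(sensitivity = 94, specificity = 80, ppv = 96,
                              npv = 72, agreement = 92),
                            rounding = "half-even")
  expect_type(f_even, "integer")
})
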