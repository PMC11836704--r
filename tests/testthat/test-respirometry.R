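test_that("moving-window smoothing averages and drops edges", {
  tr <- data.frame(time_h = 0:3, po2_kpa = c(5, 5, 5, 5))
  out <- smooth_trace(tr)
  expect_equal(out$po2_kpa, c(5, 5))
  expect_equal(out$time_h, c(1, 2))

  tr <- data.frame(time_h = 0:4, po2_kpa = 1:5)
  expect_equal(smooth_trace(tr, 3)$po2_kpa, c(2, 3, 4))

  expect_error(smooth_trace(tr[1:2, ], 3), "window")
})

test_that("smoothing a white-noise trace reduces variance by the window", {
  set.seed(101)
  tr <- data.frame(time_h = seq_len(3000), po2_kpa = rnorm(3000, 20, 1))
  sm <- smooth_trace(tr, 3)
  v <- var(sm$po2_kpa - 20)
  expect_lt(abs(v - 1 / 3), 0.15 / 3)
})

test_that("hypoxia truncation keeps the maximal prefix only", {
  tr <- data.frame(time_h = 0:4, po2_kpa = c(20, 18, 16, 15.9, 15))
  out <- truncate_hypoxia(tr, frac = 0.8)
  expect_equal(nrow(out), 3)          # threshold 16: 15.9 is the first below
  expect_true(!attr(out, "usable"))   # only 3 points survive

  # recovery after a crossing is not re-admitted
  rec <- data.frame(time_h = 0:4, po2_kpa = c(20, 15, 17, 18, 19))
  out2 <- truncate_hypoxia(rec, frac = 0.8)
  expect_equal(nrow(out2), 1)
  expect_false(attr(out2, "usable"))

  # never below threshold: identity
  ok <- make_trace(-0.05)
  expect_equal(nrow(truncate_hypoxia(ok)), nrow(ok))

  # property: output is always a prefix of the input
  set.seed(5)
  for (i in 1:20) {
    tr <- data.frame(time_h = 1:30, po2_kpa = 20 + cumsum(rnorm(30, -0.3)))
    tr$po2_kpa <- pmax(tr$po2_kpa, 0.1)
    out <- truncate_hypoxia(tr)
    expect_identical(out$po2_kpa, tr$po2_kpa[seq_len(nrow(out))])
  }
})

test_that("slope fitting is exact on exact lines", {
  tr <- make_trace(-0.5, intercept = 21)
  sl <- fit_po2_slope(tr)
  expect_equal(sl$slope, -0.5, tolerance = 1e-12)
  expect_lt(sl$se, 1e-10)

  const <- make_trace(0)
  expect_equal(fit_po2_slope(const)$slope, 0, tolerance = 1e-12)

  expect_error(fit_po2_slope(tr[1:3, ]), "4 points")
})

test_that("noisy slopes are recovered within their standard errors", {
  set.seed(11)
  hits <- 0
  for (i in 1:300) {
    tr <- make_trace(-0.2, noise = 0.05)
    sl <- fit_po2_slope(tr)
    if (abs(sl$slope + 0.2) <= 3 * sl$se) hits <- hits + 1
  }
  expect_gte(hits / 300, 0.95)
})

test_that("STP conversion follows the mole-fraction formula", {
  expect_equal(slope_to_vo2(0, 1000, 1, 20), 0)

  # ratios cancel: dry pressure 101.325 kPa at 0 C, 1000 ul, 1 seed
  v <- slope_to_vo2(-0.101325, 1000, 1, 0,
                    pressure_kpa = 101.325 + svp_buck(0))
  expect_equal(v, 1.0, tolerance = 1e-12)

  # independent hand computation at 20 C, 98 kPa ambient
  slope <- -0.3; vol <- 1500; ns <- 12; tc <- 20; p <- 98
  hand <- (0.3 / (98 - 0.61121 * exp((18.678 - 20 / 234.5) *
                                       (20 / (257.14 + 20))))) *
    1500 * (273.15 / 293.15) / 12
  expect_equal(slope_to_vo2(slope, vol, ns, tc, pressure_kpa = p), hand,
               tolerance = 1e-12)

  expect_warning(slope_to_vo2(0.1, 1000, 1, 20), "positive")
  expect_error(slope_to_vo2(-0.1, -5, 1, 20))
})

test_that("replicate outlier screen flags contaminated slopes once", {
  expect_true(all(filter_outlier_replicates(rep(-1, 5))))

  kept <- filter_outlier_replicates(c(-1, -1, -1, -1, -10))
  expect_equal(kept, c(TRUE, TRUE, TRUE, TRUE, FALSE))

  # permutation invariance
  set.seed(3)
  sl <- c(rnorm(8, -1, 0.05), -5, -5.2)
  perm <- sample(seq_along(sl))
  expect_identical(filter_outlier_replicates(sl)[perm],
                   filter_outlier_replicates(sl[perm]))

  expect_error(filter_outlier_replicates(c(-1, -2)), "3 replicates")
})

test_that("outlier screen exclusion rate on clean gaussian replicates is small", {
  set.seed(21)
  excl <- replicate(1000, sum(!filter_outlier_replicates(rnorm(10, -1, 0.1))))
  # roughly the two-sided 2-sigma tail of 10 draws (~0.45 expected)
  expect_gt(mean(excl), 0.1)
  expect_lt(mean(excl), 0.9)
})

test_that("Q10 standardization matches its closed form and inverts", {
  expect_equal(q10_correct(1, 20), 1)
  expect_equal(q10_correct(1, 30), 0.4)
  expect_equal(q10_correct(1, 18), 2.5^0.2)

  # invertibility and monotonicity
  for (tt in c(18, 23.7, 30)) {
    expect_equal(q10_correct(q10_correct(2, tt, 20), 20, tt), 2,
                 tolerance = 1e-12)
  }
  temps <- seq(30, 18, by = -2)   # colder measurements standardize upward
  expect_true(all(diff(q10_correct(1, temps)) > 0))
  expect_error(q10_correct(1, 20, q10 = -1), "q10")
})

test_that("noiseless traces return the generating VO2 exactly", {
  # build a trace from a known per-seed rate by inverting the conversion
  vo2_true <- 0.05
  tc <- 25; vol <- 1500; ns <- 20; p <- 101.325
  p_dry <- p - svp_buck(tc)
  slope <- -vo2_true * ns * p_dry / (vol * 273.15 / (273.15 + tc))
  traces <- rbind(make_trace(slope, chamber_id = "c1", temp_c = tc,
                             n_seeds = ns),
                  make_trace(slope, chamber_id = "c2", temp_c = tc,
                             n_seeds = ns),
                  make_trace(slope, chamber_id = "c3", temp_c = tc,
                             n_seeds = ns))
  smr <- process_respirometry(traces)
  expect_equal(smr$smr_t, vo2_true, tolerance = 1e-10)
  expect_equal(smr$smr20, q10_correct(vo2_true, tc), tolerance = 1e-10)
  expect_equal(smr$n_replicates_kept, 3)
})
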