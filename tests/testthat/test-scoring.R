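test_that("heat pain threshold reads the ramp at the first report of pain", {
  # CoVAS leaves zero exactly at 38.0 degC in all three trials
  tr <- thermal_trace(c(0, 20, 21, 30), c(0, 0, 10, 100),
                      temperature_c = c(32, 38, 38.3, 41), phase = "PRETEST_1")
  expect_equal(heat_pain_threshold(list(tr, tr, tr)), 38.0, tolerance = 0.01)

  # crossing between samples: strictly inside the bracketing temperatures
  # and within 0.05 degC of a dense-grid oracle
  th <- heat_pain_threshold(list(tr))
  expect_gt(th, 38.0)
  expect_lt(th, 38.3)
  dense_t <- seq(0, 30, by = 0.01)
  dense_v <- stats::approx(tr$time_s, tr$covas, dense_t)$y
  dense_temp <- stats::approx(tr$time_s, tr$temperature_c, dense_t)$y
  oracle <- dense_temp[which(dense_v > 0)[1]]
  expect_lt(abs(th - oracle), 0.05)

  # a trial that never reports pain is excluded; all-silent is undefined
  silent <- thermal_trace(c(0, 30), c(0, 0), temperature_c = c(32, 41),
                          phase = "PRETEST_2")
  expect_equal(heat_pain_threshold(list(tr, silent)), th)
  expect_true(is.na(heat_pain_threshold(list(silent))))
})

test_that("T50 averages the first upward crossings of CoVAS 50", {
  mk <- function(t50) fix_pretest_trace(t50_c = t50)
  expect_equal(pretest_t50(list(mk(43.0), mk(43.2), mk(43.4))), 43.2,
               tolerance = 1e-6)
  # trial peaking below 50 is excluded from the mean
  low <- thermal_trace(c(0, 10, 40), c(0, 20, 40),
                       temperature_c = c(32, 35, 44), phase = "PRETEST_3")
  expect_equal(pretest_t50(list(mk(43.0), mk(43.4), low)), 43.2,
               tolerance = 1e-6)
  expect_true(is.na(pretest_t50(list(low))))
  # off-grid crossing agrees with a 100 Hz dense-grid oracle within 0.05 degC
  tr <- thermal_trace(c(0, 30, 33, 40), c(0, 42, 61, 90),
                      temperature_c = 32 + 0.3 * c(0, 30, 33, 40),
                      phase = "PRETEST_1")
  dense_t <- seq(0, 40, by = 0.01)
  dense_v <- stats::approx(tr$time_s, tr$covas, dense_t)$y
  oracle <- (32 + 0.3 * dense_t)[which(dense_v >= 50)[1]]
  expect_lt(abs(pretest_t50(list(tr)) - oracle), 0.05)
})

test_that("mean trace intensity is the time-weighted mean of the interpolant", {
  expect_equal(mean_trace_intensity(fix_ts_trace(plateau = 50)), 50)
  # linear 40 -> 60 over the window: symmetric, mean 50
  lin <- thermal_trace(c(0, 120), c(40, 60), phase = "TS1")
  expect_equal(mean_trace_intensity(lin, c(0, 120)), 50)
  # irregular grid vs a 1000-point Riemann-sum oracle
  set.seed(11)
  tt <- sort(c(0, 120, runif(25, 0, 120)))
  vv <- runif(length(tt), 0, 100)
  tr <- thermal_trace(tt, vv, phase = "TS1")
  grid <- seq(0, 120, length.out = 1001)
  mids <- (grid[-1] + grid[-1001]) / 2
  oracle <- mean(stats::approx(tt, vv, mids)$y)
  expect_equal(mean_trace_intensity(tr, c(0, 120)), oracle, tolerance = 1e-3)
  # trapezoid equals exact integral of the interpolant (knot-aware oracle)
  exact <- sum(diff(tt) * (vv[-1] + vv[-length(vv)]) / 2) / 120
  expect_equal(mean_trace_intensity(tr, c(0, 120)), exact, tolerance = 1e-9)
  expect_error(mean_trace_intensity(tr, c(0, 130)), "outside")
})

test_that("temporal summation is the signed endpoint change over the last 60 s", {
  expect_equal(temporal_summation(fix_ts_trace(plateau = 50, tsp = 0)), 0)
  expect_equal(temporal_summation(fix_ts_trace(plateau = 50, tsp = 20)), 20)
  expect_equal(temporal_summation(fix_ts_trace(plateau = 60, tsp = -20)), -20)
  short <- thermal_trace(c(0, 90), c(50, 50), phase = "TS1")
  expect_error(temporal_summation(short), "120")
})

test_that("TSP categories use inclusive 20/100 cutoffs", {
  expect_equal(classify_tsp(c(20, 19.9, -19.9, -20, 0)),
               c("INCREASE", "CONSTANT", "CONSTANT", "DECREASE", "CONSTANT"))
})

test_that("cold-pressor mean imputes 10/10 on early withdrawal", {
  expect_equal(cs_mean_intensity(fix_cs(c(5, 6, 6, 7, 7, 8, 8, 8))), 6.875)
  expect_equal(cs_mean_intensity(fix_cs(c(5, 6, 7), withdrawal = 45)), 10.0)
  expect_equal(cs_mean_intensity(fix_cs(3)), 3.0)
  expect_error(cs_mean_intensity(cold_pressor_series(numeric(0), numeric(0))),
               "no ratings")
})

test_that("CPM efficiency is the percent change of the test-stimulus means", {
  expect_equal(cpm_efficiency(50, 35), -30)
  expect_equal(cpm_efficiency(50, 50), 0)
  expect_equal(cpm_efficiency(40, 60), 50)
  expect_warning(res <- cpm_efficiency(0, 10), "undefined")
  expect_true(is.na(res))
})

test_that("CPM categories assign each cutoff to the more-inhibitory class", {
  expect_equal(classify_cpm(c(-30, -10, 0, -29.99, -100, 100)),
               c("OPTIMAL", "SUBOPTIMAL", "INEFFICIENT", "SUBOPTIMAL",
                 "OPTIMAL", "INEFFICIENT"))
  # the three classes partition [-100, 100] exhaustively and exclusively
  grid <- seq(-100, 100, by = 0.1)
  cls <- classify_cpm(grid)
  expect_true(all(cls %in% c("OPTIMAL", "SUBOPTIMAL", "INEFFICIENT")))
  expect_true(all(diff(match(cls, c("OPTIMAL", "SUBOPTIMAL",
                                    "INEFFICIENT"))) >= 0))
})

test_that("score_session composes the per-participant quantities", {
  flat <- fix_session("A", ts1 = fix_ts_trace("TS1", 50, 0),
                      ts2 = fix_ts_trace("TS2", 50, 0))
  r <- score_session(flat)
  expect_equal(r$cpm_pct, 0)
  expect_equal(r$tsp1, 0)
  expect_equal(r$tsp2, 0)
  expect_equal(r$cpm_class, "INEFFICIENT")

  wd <- fix_session("B", cs = fix_cs(c(8, 9), withdrawal = 40))
  rw <- score_session(wd)
  expect_equal(rw$cs_mean, 10.0)
  expect_true(rw$withdrawal)

  expect_error(score_session(fix_session("C", cs = NULL)), "not complete")
})

test_that("CPM efficiency is insensitive to the sampling grid", {
  for (tsp in c(-15, 0, 25)) {
    s1 <- fix_session("A", ts1 = fix_ts_trace("TS1", 50, tsp, rate = 1),
                      ts2 = fix_ts_trace("TS2", 35, -tsp, rate = 1))
    s10 <- fix_session("A", ts1 = fix_ts_trace("TS1", 50, tsp, rate = 10),
                       ts2 = fix_ts_trace("TS2", 35, -tsp, rate = 10))
    expect_lt(abs(score_session(s1)$cpm_pct - score_session(s10)$cpm_pct),
              0.1)
  }
})
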