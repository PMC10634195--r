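test_that("bead calibration solves the log-log regression", {
  # identity response
  cal <- fit_calibration(data.frame(assigned_value = c(100, 1000),
                                    measured_intensity = c(100, 1000)))
  expect_equal(cal$slope, 1, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  # two-point hand oracle: (200 au -> 100 ERF), (2000 au -> 1000 ERF)
  cal2 <- fit_calibration(data.frame(assigned_value = c(100, 1000),
                                     measured_intensity = c(200, 2000)))
  expect_equal(cal2$slope, 1, tolerance = 1e-12)
  expect_equal(cal2$intercept, -log10(2), tolerance = 1e-12)
  ev <- apply_calibration(data.frame(fl_au = 500), cal2)
  expect_equal(ev$fl_erf, 250, tolerance = 1e-9)
  # single bead (or equal intensities) is an error
  expect_error(fit_calibration(data.frame(assigned_value = 100,
                                          measured_intensity = 200)),
               "2 beads")
})

test_that("calibration application is monotone with an inclusive threshold", {
  cal <- fit_calibration(data.frame(assigned_value = c(100, 1000),
                                    measured_intensity = c(100, 1000)))
  ev <- apply_calibration(data.frame(fl_au = c(0, 50, 100, 200)), cal,
                          threshold = 100)
  expect_equal(ev$fl_erf, c(0, 50, 100, 200))
  expect_equal(ev$above_threshold, c(FALSE, FALSE, TRUE, TRUE))
  # slope 1: doubling fl_au doubles fl_erf; ranking preserved
  cal2 <- fit_calibration(data.frame(assigned_value = c(100, 1000),
                                     measured_intensity = c(130, 1300)))
  x <- data.frame(fl_au = c(30, 60, 500, 1000))
  out <- apply_calibration(x, cal2)
  expect_equal(out$fl_erf[2] / out$fl_erf[1], 2, tolerance = 1e-9)
  expect_equal(order(out$fl_erf), order(x$fl_au))
  expect_equal(invert_calibration(out$fl_erf, cal2), x$fl_au,
               tolerance = 1e-9)
})

test_that("time-based concentration follows the dilution-corrected event rate", {
  expect_equal(concentration(0, 30, 1, 20), 0)
  expect_equal(concentration(300, 30, 1, 20), 200)
  # 50 uL diluted into 950 uL is a 20-fold dilution
  expect_equal((50 + 950) / 50, 20)
  expect_error(concentration(10, 0, 1), "must be > 0")
  # linear in events and dilution, inverse in time and flow
  set.seed(20)
  for (i in 1:20) {
    n <- rpois(1, 500); t <- runif(1, 1, 60)
    f <- runif(1, 0.1, 5); dil <- runif(1, 1, 50)
    c0 <- concentration(n, t, f, dil)
    expect_equal(concentration(2 * n, t, f, dil), 2 * c0, tolerance = 1e-12)
    expect_equal(concentration(n, 2 * t, f, dil), c0 / 2, tolerance = 1e-12)
    expect_equal(concentration(n, t, 2 * f, dil), c0 / 2, tolerance = 1e-12)
    expect_equal(concentration(n, t, f, 2 * dil), 2 * c0, tolerance = 1e-12)
  }
})

test_that("density windows pool with inclusive bounds and conserve events", {
  ev <- data.frame(fraction_density = rep(1.14, 25))
  fs <- fraction_summaries(ev)
  w <- fs$windows
  expect_equal(w$n_events[w$window == "ev_rich"], 25)
  expect_equal(w$n_events[w$window == "lpp_rich"], 0)
  # 1.10 sits on the inclusive upper bound of the LPP-rich window
  fs2 <- fraction_summaries(data.frame(fraction_density = 1.10))
  expect_equal(fs2$windows$n_events[fs2$windows$window == "lpp_rich"], 1)
  # conservation on random tables: windows + other = total
  set.seed(4)
  for (i in 1:10) {
    dens <- round(runif(200, 1.00, 1.30), 2)
    fs3 <- fraction_summaries(data.frame(fraction_density = dens))
    w3 <- fs3$windows
    expect_equal(w3$n_events[w3$window == "ev_rich"] +
                   w3$n_events[w3$window == "lpp_rich"] +
                   w3$n_events[w3$window == "other"],
                 fs3$n_total)
    expect_equal(sum(fs3$per_fraction$n_events), fs3$n_total)
  }
})

test_that("spike-in comparison reports fold changes with zero handling", {
  a <- fraction_summaries(data.frame(fraction_density = rep(c(1.14, 1.08),
                                                            c(100, 40))))
  self <- spike_in_compare(a, a)
  expect_equal(self$fold_change[self$n_a > 0], rep(1, 3))
  expect_true(is.na(self$fold_change[self$window == "other"]))  # 0/0
  b <- fraction_summaries(data.frame(fraction_density = rep(c(1.14, 1.08),
                                                            c(50, 80))))
  cmp <- spike_in_compare(a, b)
  expect_equal(cmp$fold_change[cmp$window == "ev_rich"], 0.5)
  expect_equal(cmp$fold_change[cmp$window == "lpp_rich"], 2)
  expect_equal(cmp$difference[cmp$window == "ev_rich"], -50)
  # zero reference: infinite flag
  z <- fraction_summaries(data.frame(fraction_density = 1.14))
  cmp2 <- spike_in_compare(z, b)
  expect_true(cmp2$infinite_flag[cmp2$window == "lpp_rich"])
  expect_true(is.infinite(cmp2$fold_change[cmp2$window == "lpp_rich"]))
})

test_that("detergent sensitivity reports percent lost per gate with anomaly flags", {
  out <- detergent_sensitivity(c(g1 = 1000, g2 = 400, g3 = 100, g4 = 0),
                               c(g1 = 250, g2 = 0, g3 = 150, g4 = 5))
  expect_equal(out$pct_lost[1], 75)
  expect_equal(out$pct_lost[2], 100)
  expect_equal(out$pct_lost[3], 0)        # post > pre clipped at zero
  expect_true(out$anomaly_flag[3])
  expect_true(is.na(out$pct_lost[4]))     # pre = 0 undefined
  expect_true(out$anomaly_flag[4])
  expect_error(detergent_sensitivity(c(a = 1), c(b = 1)), "match")
})

test_that("the swarm-risk check warns only above the rate limit", {
  expect_silent(check_event_rate(300, 30))
  expect_warning(check_event_rate(1e6, 30), "swarm")
})
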