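test_that("rayleigh traces come from the stored channel or an elastic-scatter window", {
  cy <- make_step_cycle(n = 64, start = 30, step = 0)
  expect_equal(compute_rayleigh_trace(cy), rep(100, 64))
  expect_length(compute_rayleigh_trace(cy), nrow(cy$raman))
  # derived from the spectral stack over a window
  ax <- cy$axis
  tr <- compute_rayleigh_trace(cy, window = c(ax[1], ax[5]))
  expect_equal(tr, rowMeans(cy$raman[, 1:5]))
  expect_error(compute_rayleigh_trace(cy, window = c(5000, 6000)), "window")
})

test_that("the difference statistic localizes an injected step", {
  cy <- make_step_cycle(n = 256, start = 100, step = 10, noise_sd = 1,
                        seed = 4)
  tr <- compute_rayleigh_trace(cy)
  d <- diff(tr)
  expect_equal(which.max(d), 99)  # jump between index 99 and 100
})

test_that("step detection is exact on noise-free traces and silent on flat ones", {
  # flat noisy trace, noise well below min_step
  set.seed(8)
  expect_equal(nrow(detect_steps(100 + rnorm(256, 0, 0.1), min_step = 5)), 0)
  # trace shorter than min_duration: empty result, not an error
  expect_equal(nrow(detect_steps(c(1, 2), min_step = 1, min_duration = 5)), 0)
  # noise-free step-and-hold: boundaries equal ground truth exactly
  cy <- make_step_cycle(n = 256, start = 83, step = 10, noise_sd = 0)
  det <- detect_steps(compute_rayleigh_trace(cy), min_step = 3)
  expect_equal(det$start, 83)
  expect_equal(det$end, 256)
  expect_true(det$truncated)
  expect_equal(det$step_height, 10, tolerance = 1e-9)
})

test_that("multiple steps at SNR 10 are found within one index of truth", {
  set.seed(12)
  n <- 600
  trace <- 100 + rnorm(n, 0, 1)
  truth <- data.frame(start = c(101, 301, 501), end = c(200, 400, 560))
  for (i in seq_len(3)) {
    idx <- truth$start[i]:truth$end[i]
    trace[idx] <- trace[idx] + 10
  }
  det <- detect_steps(trace, min_step = 3)
  expect_equal(nrow(det), 3)
  expect_true(all(abs(det$start - truth$start) <= 1))
  expect_true(all(abs(det$end - truth$end) <= 1))
  expect_true(all(diff(det$start) > 0))
})

test_that("steps below the detection threshold are not reported", {
  set.seed(3)
  n <- 300
  min_step <- 6
  trace <- 100 + rnorm(n, 0, 0.5)
  trace[150:n] <- trace[150:n] + min_step / 2
  # brute-force oracle: largest level change between any split of the trace
  true_jump <- max(diff(stats::filter(trace, rep(1 / 5, 5))), na.rm = TRUE)
  expect_lt(true_jump, min_step)
  expect_equal(nrow(detect_steps(trace, min_step = min_step)), 0)
})

test_that("event spectra are background-subtracted means of the event rows", {
  ax <- fingerprint_axis()
  spec <- 5 * exp(-0.5 * ((ax - 1438) / 7)^2)
  cy <- make_step_cycle(n = 128, start = 60, step = 10, spectrum = spec,
                        noise_sd = 0)
  ev <- extract_event_spectrum(cy, 60, 128)
  expect_equal(ev$spectrum, spec, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(ev$step_height, 10, tolerance = 1e-12)
  # pre-event background policy: last background_n baseline spectra
  expect_equal(ev$background_idx, 40:59)
  # event spanning all but the first 10 spectra uses those 10
  ev2 <- extract_event_spectrum(cy, 11, 128, background_n = 10)
  expect_equal(ev2$background_idx, 1:10)
})

test_that("background subtraction removes a constant offset exactly", {
  ax <- fingerprint_axis()
  spec <- 3 * exp(-0.5 * ((ax - 698) / 7)^2)
  cy <- make_step_cycle(n = 128, start = 60, step = 10, spectrum = spec,
                        noise_sd = 0.5, seed = 31)
  shifted <- cy
  shifted$raman <- cy$raman + 42
  a <- extract_event_spectrum(cy, 60, 128)
  b <- extract_event_spectrum(shifted, 60, 128)
  expect_equal(a$spectrum, b$spectrum, tolerance = 1e-9)
})

test_that("events with no pre-event baseline fall back to post-release spectra", {
  ax <- fingerprint_axis(8)
  cy <- make_step_cycle(n = 64, start = 2, step = 10, noise_sd = 0, axis = ax)
  # event starting at the first spectrum: only post-event background remains
  ev <- extract_event_spectrum(cy, 1, 50)
  expect_equal(ev$background_idx, 51:64)
  # whole-cycle event has no background at all
  expect_error(extract_event_spectrum(cy, 1, 64), "background")
})

test_that("campaign segmentation recovers seeded events and is order-invariant", {
  cc <- campaign_config(cycles_per_sample = 40, arrival_rate = 0.6,
                        axis = fingerprint_axis(8), seed = 14)
  cam <- simulate_campaign(cc)
  ev <- run_campaign_segmentation(cam$cycles)
  sc <- score_segmentation(ev$events, cam$truth)
  expect_gte(sc$recall, 0.95)
  expect_gte(sc$precision, 0.95)
  expect_equal(nrow(ev$events), nrow(ev$spectra))
  # permutation invariance of the event count
  ev2 <- run_campaign_segmentation(rev(cam$cycles))
  expect_equal(nrow(ev2$events), nrow(ev$events))
  # arrival rate zero gives an empty table
  cc0 <- campaign_config(cycles_per_sample = 5, arrival_rate = 0,
                         axis = fingerprint_axis(40), seed = 2)
  ev0 <- run_campaign_segmentation(simulate_campaign(cc0)$cycles)
  expect_equal(nrow(ev0$events), 0)
  # axis mismatch across cycles is an error
  bad <- cam$cycles
  bad[[2]]$axis <- bad[[2]]$axis + 1
  expect_error(run_campaign_segmentation(bad), "axis")
})
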