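acfg <- analysis_config()

tiny_epochs <- function(data, times = NULL, montage = mini_montage()) {
  nt <- dim(data)[3]
  if (is.null(times)) times <- seq(-100, by = 1, length.out = nt)
  structure(list(data = data, labels = data.frame(
    condition = rep("harmonic", dim(data)[1]),
    role = rep("standard", dim(data)[1]),
    deviant_order = rep(NA_integer_, dim(data)[1]),
    shift_hz = rep(NA_real_, dim(data)[1])
  ), times = times, srate = 1000, montage = montage, subject_id = 1L),
  class = "epoch_set")
}

test_that("low-pass keeps the passband and kills the stopband", {
  t <- seq(-0.1, 0.45, by = 1e-3)
  slow <- sin(2 * pi * 5 * t)
  fast <- sin(2 * pi * 100 * t)
  d <- array(0, c(2, 6, length(t)))
  for (ch in 1:6) {
    d[1, ch, ] <- slow
    d[2, ch, ] <- fast
  }
  ep <- lowpass_epochs(tiny_epochs(d), acfg)
  core <- 100:450  # avoid edge transients
  expect_gt(max(abs(ep$data[1, 1, core])) / max(abs(slow[core])), 0.99)
  expect_lt(max(abs(ep$data[2, 1, core])) / max(abs(fast[core])), 0.1)
  # near-idempotent for passband content
  twice <- lowpass_epochs(ep, acfg)
  expect_lt(max(abs(twice$data[1, 1, core] - ep$data[1, 1, core])) /
              max(abs(ep$data[1, 1, core])), 0.02)
  # DC preserved
  dc <- tiny_epochs(array(2, c(1, 6, length(t))))
  expect_equal(lowpass_epochs(dc, acfg)$data[1, 1, 200], 2, tolerance = 1e-6)
})

test_that("baseline correction zeroes the pre-stimulus mean and is idempotent", {
  set.seed(2)
  d <- array(stats::rnorm(4 * 6 * 551), c(4, 6, 551)) + 5
  ep <- tiny_epochs(d)
  bc <- baseline_correct(ep, acfg)
  bl <- ep$times >= -100 & ep$times <= 0
  expect_lt(max(abs(apply(bc$data[, , bl], c(1, 2), mean))), 1e-12)
  again <- baseline_correct(bc, acfg)
  expect_equal(again$data, bc$data, tolerance = 1e-12)
  # shift invariance
  shifted <- ep
  shifted$data <- ep$data + 5
  expect_equal(baseline_correct(shifted, acfg)$data, bc$data, tolerance = 1e-12)
  # constant-offset epochs come out all zero
  const <- tiny_epochs(array(3, c(2, 6, 551)))
  expect_true(all(abs(baseline_correct(const, acfg)$data) < 1e-12))
})

test_that("averaging is linear and respects selectors", {
  set.seed(3)
  d <- array(stats::rnorm(6 * 6 * 20), c(6, 6, 20))
  ep <- tiny_epochs(d)
  ep$labels$role <- rep(c("standard", "deviant"), 3)
  avg <- average_erp(ep, function(l) l$role == "standard")
  expect_equal(avg$n_trials, 3)
  expect_equal(avg$data, apply(d[c(1, 3, 5), , ], c(2, 3), mean),
               ignore_attr = TRUE)
  one <- average_erp(ep, c(TRUE, rep(FALSE, 5)))
  expect_equal(one$data, d[1, , ], ignore_attr = TRUE)
  # two opposite trials cancel
  d2 <- d
  d2[2, , ] <- -d2[1, , ]
  cancel <- average_erp(tiny_epochs(d2), c(TRUE, TRUE, rep(FALSE, 4)))
  expect_lt(max(abs(cancel$data)), 1e-12)
  expect_error(average_erp(ep, function(l) l$role == "nope"), "empty selection")
  # ROI of the mean equals the mean of ROI traces
  roi <- c("F3", "Fz", "F4")
  tr1 <- roi_trace(avg, roi)
  tr2 <- rowMeans(sapply(c(1, 3, 5), function(i) {
    colMeans(d[i, match(roi, ep$montage$names), ])
  }))
  expect_equal(unname(tr1), tr2, tolerance = 1e-12)
})

test_that("difference waves subtract elementwise and invert", {
  set.seed(4)
  d <- array(stats::rnorm(4 * 6 * 15), c(4, 6, 15))
  ep <- tiny_epochs(d)
  a <- average_erp(ep, c(TRUE, TRUE, FALSE, FALSE))
  b <- average_erp(ep, c(FALSE, FALSE, TRUE, TRUE))
  dw <- difference_wave(a, b)
  expect_equal(dw$data, a$data - b$data, tolerance = 1e-12)
  expect_lt(max(abs(difference_wave(a, a)$data)), 1e-15)
  # (dev - std) + std recovers dev
  expect_equal(dw$data + b$data, a$data, tolerance = 1e-12)
  short <- a
  short$data <- short$data[, 1:10]
  short$times <- a$times[1:10]
  expect_error(difference_wave(a, short), "mismatch")
})

test_that("roi_trace validates channels and ignores ordering", {
  m <- matrix(stats::rnorm(6 * 10), 6, 10,
              dimnames = list(mini_montage()$names, NULL))
  expect_equal(roi_trace(m, c("Fz", "F3")), roi_trace(m, c("F3", "Fz")))
  expect_equal(roi_trace(m, "Cz"), m["Cz", ])
  expect_error(roi_trace(m, c("Fz", "XX")), "unknown channels")
})

test_that("peak extraction finds Gaussian bumps and matches brute force", {
  times <- seq(-100, 450, by = 1)
  trace <- -1.3 * exp(-(times - 150)^2 / (2 * 25^2))
  pm <- peak_and_mean_amplitude(trace, times, "mmn", acfg)
  expect_equal(pm$latency_ms, 150)
  expect_gt(pm$mean_amp, pm$peak_amp)  # window mean shallower than the trough
  expect_false(pm$clipped)

  # brute-force scan over every sample in the window
  set.seed(6)
  for (i in 1:25) {
    tr <- stats::rnorm(length(times))
    for (comp in c("mmn", "p3a")) {
      win <- if (comp == "mmn") acfg$mmn_window else acfg$p3a_window
      sel <- which(times >= win[1] & times <= win[2])
      k <- if (comp == "mmn") sel[which.min(tr[sel])] else sel[which.max(tr[sel])]
      wsel <- times >= times[k] - 25 & times <= times[k] + 25
      pm <- peak_and_mean_amplitude(tr, times, comp, acfg)
      expect_equal(pm$latency_ms, times[k])
      expect_equal(pm$mean_amp, mean(tr[wsel]), tolerance = 1e-12)
    }
  }
})

test_that("peak latency is shift-equivariant and ties break early", {
  times <- seq(-100, 450, by = 1)
  g <- function(lat) -exp(-(times - lat)^2 / (2 * 20^2))
  l1 <- peak_and_mean_amplitude(g(140), times, "mmn", acfg)$latency_ms
  l2 <- peak_and_mean_amplitude(g(150), times, "mmn", acfg)$latency_ms
  expect_equal(l2 - l1, 10)
  flat <- peak_and_mean_amplitude(rep(1, length(times)), times, "mmn", acfg)
  expect_equal(flat$latency_ms, 70)  # earliest sample of the window
  expect_true(flat$flat)
})

test_that("P2 window mean is exact on simple traces", {
  times <- seq(-100, 450, by = 1)
  expect_equal(p2_mean_amplitude(rep(2.5, length(times)), times, acfg), 2.5)
  lin <- 0.01 * times
  expect_equal(p2_mean_amplitude(lin, times, acfg), 0.01 * 141,
               tolerance = 1e-12)  # symmetric window around 141 ms
  set.seed(7)
  tr <- stats::rnorm(length(times))
  sel <- times >= 116 & times <= 166
  expect_equal(p2_mean_amplitude(tr, times, acfg), mean(tr[sel]),
               tolerance = 1e-12)
})
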