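test_that("channel CV matches the printed formula (population sd)", {
  expect_equal(channel_cv(c(100, 100, 100)), 0)
  expect_equal(channel_cv(c(190, 210)), 5)          # mean 200, pop sd 10
  expect_equal(channel_cv(rep(c(90, 110), 20)), 10) # mean 100, pop sd 10
  expect_error(channel_cv(c(1, -3)), "non-positive mean")
})

test_that("channel CV is scale invariant", {
  set.seed(1)
  for (i in 1:20) {
    x <- rlnorm(50)
    a <- runif(1, 0.1, 100)
    expect_equal(channel_cv(a * x), channel_cv(x))
  }
})

test_that("channel screening rejects exactly the high-CV channels at both wavelengths", {
  intensity <- array(100, c(16, 2, 40))
  raw <- raw_recording("s1", intensity)
  expect_true(all(screen_channels(raw)))

  intensity[5, 1, ] <- rep(c(90, 110), 20)   # CV 10% at one wavelength
  raw <- raw_recording("s1", intensity)
  mask <- screen_channels(raw, threshold_pct = 7.5)
  expect_identical(which(!mask), 5L)
  expect_equal(sum(mask), 15L)

  for (ch in 1:16) intensity[ch, 2, ] <- rep(c(80, 120), 20)
  raw <- raw_recording("s1", intensity)
  expect_error(screen_channels(raw), "cannot proceed")
})

test_that("optical density follows the log law against an elementwise oracle", {
  # constant at baseline level -> OD 0; tenth of baseline -> OD 1
  intensity <- array(NA_real_, c(1, 2, 6))
  intensity[1, , ] <- matrix(rep(c(5, 5, 5, 5, 0.5, 5), each = 2), 2)
  raw <- raw_recording("s1", intensity, sampling_rate_hz = 1,
                       baseline_duration_s = 4)
  od <- intensity_to_od(raw)
  expect_equal(od[1, 1, 1:4], rep(0, 4))
  expect_equal(od[1, 1, 5], 1)
  expect_equal(od[1, 2, 6], 0)

  set.seed(7)
  intensity <- array(rlnorm(16 * 2 * 100, meanlog = 3), c(16, 2, 100))
  raw <- raw_recording("s2", intensity, sampling_rate_hz = 1.77,
                       baseline_duration_s = 10)
  od <- intensity_to_od(raw)
  n_base <- floor(10 * 1.77)
  for (ch in c(1, 9, 16)) {
    for (w in 1:2) {
      oracle <- -log10(intensity[ch, w, ] / mean(intensity[ch, w, 1:n_base]))
      expect_equal(od[ch, w, ], oracle, tolerance = 1e-12)
    }
  }
})

test_that("Beer-Lambert inversion undoes the forward model", {
  params <- mbll_params()
  od <- array(0, c(3, 2, 10))
  res <- od_to_hemoglobin(od, params)
  expect_equal(res$hbo, matrix(0, 3, 10))
  expect_equal(res$hbr, matrix(0, 3, 10))

  # forward-generate OD from known concentrations, then invert
  hbo_true <- 1; hbr_true <- -0.3
  scale <- params$distance_cm * params$pathlength_factor
  od_vec <- params$extinction %*% c(hbo_true, hbr_true) * scale
  od <- array(rep(od_vec, each = 1), c(1, 2, 1))
  od[1, , 1] <- od_vec
  res <- od_to_hemoglobin(od, params)
  expect_equal(res$hbo[1, 1], hbo_true, tolerance = 1e-10)
  expect_equal(res$hbr[1, 1], hbr_true, tolerance = 1e-10)

  # linearity: doubling OD doubles both outputs
  res2 <- od_to_hemoglobin(od * 2, params)
  expect_equal(res2$hbo, res$hbo * 2, tolerance = 1e-12)
  expect_equal(res2$hbr, res$hbr * 2, tolerance = 1e-12)
})

test_that("Beer-Lambert round trip holds for arbitrary invertible extinction matrices", {
  set.seed(11)
  for (i in 1:25) {
    E <- matrix(rlnorm(4, meanlog = -7), 2, 2)
    if (abs(det(E)) < 1e-9 * prod(sqrt(rowSums(E^2)))) next
    params <- mbll_params(extinction = E)
    conc <- matrix(rnorm(2 * 20), 2)
    od <- array(NA_real_, c(1, 2, 20))
    od[1, , ] <- E %*% conc * params$distance_cm * params$pathlength_factor
    res <- od_to_hemoglobin(od, params)
    expect_equal(res$hbo[1, ], conc[1, ], tolerance = 1e-10)
    expect_equal(res$hbr[1, ], conc[2, ], tolerance = 1e-10)
  }
  expect_error(mbll_params(extinction = matrix(c(1, 2, 2, 4) * 1e-4, 2)),
               "singular")
})

test_that("high-pass filter removes DC and matches the analytic magnitude response", {
  fs <- 1.77
  t <- seq(0, 2000, by = 1 / fs)
  mid <- function(y) y[floor(0.4 * length(y)):ceiling(0.6 * length(y))]
  as_hemo <- function(x) hemo_recording("s", rbind(x), rbind(x), fs)

  const <- highpass(as_hemo(rep(5, length(t))))
  expect_lt(abs(mean(const$hbo)), 1e-6)

  pass <- highpass(as_hemo(sin(2 * pi * 0.1 * t)))
  expect_equal(max(abs(mid(pass$hbo[1, ]))), 1, tolerance = 0.01)

  stopb <- highpass(as_hemo(sin(2 * pi * 0.002 * t)))
  expect_lt(max(abs(mid(stopb$hbo[1, ]))), 1e-4)
})

test_that("high-pass filter is linear and rejects too-short input", {
  fs <- 1.77
  set.seed(5)
  x <- rnorm(600); y <- rnorm(600)
  as_hemo <- function(v) hemo_recording("s", rbind(v), rbind(v), fs)
  f <- function(v) highpass(as_hemo(v))$hbo[1, ]
  lhs <- f(2 * x - 3 * y)
  rhs <- 2 * f(x) - 3 * f(y)
  expect_equal(lhs, rhs, tolerance = 1e-9)
  expect_error(highpass(as_hemo(rnorm(10))), "at least 27")
})

test_that("artifact flagging finds planted spikes and passes manual flags through", {
  fs <- 1.77
  n <- 400
  set.seed(3)
  hbo <- matrix(rnorm(2 * n, sd = 0.5), 2, n)
  blocks <- data.frame(onset_s = c(30, 100), duration_s = 39,
                       condition = c("N", "C"))
  trials <- data.frame(block_index = c(1L, 1L, 2L, 2L),
                       onset_s = c(30, 49.5, 100, 119.5),
                       condition = c("N", "N", "C", "C"),
                       is_match = TRUE, response_correct = TRUE,
                       reaction_time_s = 1, artifact_flag = FALSE)
  ev <- event_table(blocks, trials)
  hemo <- hemo_recording("s", hbo, hbo, fs)

  clean <- flag_artifact_trials(hemo, ev, method = "amplitude_threshold")
  expect_false(any(clean$trials$artifact_flag))

  zero <- hemo_recording("s", matrix(0, 2, n), matrix(0, 2, n), fs)
  expect_false(any(flag_artifact_trials(zero, ev,
    method = "amplitude_threshold")$trials$artifact_flag))

  spike_at <- floor((119.5 + 1) * fs) + 1      # inside trial 4 only
  hbo2 <- hbo
  hbo2[1, spike_at] <- hbo2[1, spike_at] + 20 * sd(hbo[1, ])
  flagged <- flag_artifact_trials(hemo_recording("s", hbo2, hbo2, fs), ev,
                                  method = "amplitude_threshold")
  expect_identical(which(flagged$trials$artifact_flag), 4L)

  manual <- ev
  manual$trials$artifact_flag <- c(TRUE, FALSE, FALSE, TRUE)
  expect_identical(flag_artifact_trials(hemo, manual, method = "manual_flags"),
                   manual)
})
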