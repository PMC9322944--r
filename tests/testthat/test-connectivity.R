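test_that("global regressor is the retained-channel mean", {
  x <- sin(seq(0, 10, length.out = 200))
  h <- hemo_recording("s", rbind(x, -x), rbind(x, -x), 1.77)
  expect_equal(global_regressor(h), rep(0, 200))
  h2 <- hemo_recording("s", rbind(x, x, x), rbind(x, x, x), 1.77)
  expect_equal(global_regressor(h2), x)
  set.seed(2)
  m <- matrix(rnorm(16 * 100), 16)
  h3 <- hemo_recording("s", m, m, 1.77)
  expect_equal(global_regressor(h3), colMeans(m), tolerance = 1e-12)
  h4 <- hemo_recording("s", m, m, 1.77,
                       retained_channels = c(TRUE, rep(FALSE, 15)))
  expect_error(global_regressor(h4), "at least 2")
})

test_that("task-segment concatenation uses half-open floor-rounded block windows", {
  series <- seq_len(1000)
  # single block spanning the full recording is the identity
  ev <- one_block_events(duration_s = 500)
  expect_identical(concatenate_task_segments(series, ev, 2), series)
  fs <- 1.77

  blocks <- data.frame(onset_s = c(30, 100), duration_s = 39,
                       condition = c("N", "C"))
  ev2 <- event_table(blocks, one_block_events(1)$trials)
  out <- concatenate_task_segments(series, ev2, fs)
  expect_length(out, 138)   # floor-index arithmetic: 69 + 69 samples
  expect_identical(out[1:69], series[(floor(30 * fs) + 1):floor(69 * fs)])

  ev3 <- event_table(data.frame(onset_s = 900, duration_s = 39,
                                condition = "N"),
                     one_block_events(1)$trials)
  expect_error(concatenate_task_segments(series, ev3, fs), "outside")

  # artifact exclusion can empty the task series
  blocks4 <- data.frame(onset_s = 30, duration_s = 39, condition = "N")
  trials4 <- data.frame(block_index = 1L, onset_s = 31, condition = "N",
                        is_match = TRUE, response_correct = TRUE,
                        reaction_time_s = 1, artifact_flag = TRUE)
  ev4 <- event_table(blocks4, trials4)
  expect_error(concatenate_task_segments(series, ev4, fs,
                                         exclude_artifacts = TRUE),
               "empty task series")
  expect_length(concatenate_task_segments(series, ev4, fs), 69)
})

test_that("partial correlation matches formula reductions and the residual oracle", {
  set.seed(4)
  x <- rnorm(60); y <- rnorm(60)
  z <- residuals(lm(rnorm(60) ~ x + y))   # orthogonal to x and y
  expect_equal(partial_correlation(x, y, z), cor(x, y), tolerance = 1e-12)
  expect_error(partial_correlation(x, y, y), "collinear")
  expect_error(partial_correlation(x, y, rep(1, 60)), "constant")

  for (i in 1:200) {
    x <- rnorm(30); y <- rnorm(30); z <- rnorm(30)
    expect_equal(partial_correlation(x, y, z), pcor_oracle_residual(x, y, z),
                 tolerance = 1e-12)
  }
})

test_that("FC matrix is symmetric, unit-diagonal, and bounds independent noise", {
  fs <- 1.77
  n <- 600
  set.seed(8)
  m <- matrix(rnorm(6 * n), 6)
  h <- hemo_recording("s", m, m, fs)
  ev <- one_block_events(n / fs)
  fc <- fc_matrix(h, ev)
  v <- fc$values[1:6, 1:6]
  expect_equal(v, t(v), tolerance = 1e-12)
  expect_equal(diag(v), rep(1, 6), ignore_attr = TRUE)
  # partialling the channel mean of N independent channels induces an
  # exact -1/(N-1) background; around it, entries stay within sampling noise
  off <- v[upper.tri(v)]
  expect_true(all(abs(off + 1 / 5) < 3 / sqrt(n)))
})

test_that("global-signal partialling removes a strong shared component", {
  fs <- 1.77
  n <- 800
  n_ch <- 16
  set.seed(12)
  g <- as.numeric(arima.sim(list(ar = 0.9), n))
  m <- matrix(rnorm(n_ch * n, sd = 0.3), n_ch) + rep(1, n_ch) %o% g
  h <- hemo_recording("s", m, m, fs)
  ev <- one_block_events(n / fs)
  raw_cor <- cor(t(m))
  fc <- fc_matrix(h, ev)
  v <- fc$values
  expect_gt(mean(abs(raw_cor[upper.tri(raw_cor)])), 0.8)
  expect_lt(mean(abs(v[upper.tri(v)])), 0.2)
})

test_that("duplicated channels keep unit partial correlation", {
  fs <- 1.77
  set.seed(5)
  x <- rnorm(300)
  g <- rnorm(300)
  m <- rbind(x, x, g)
  h <- hemo_recording("s", m, m, fs)
  fc <- fc_matrix(h, one_block_events(300 / fs))
  expect_equal(fc$values[1, 2], 1, tolerance = 1e-10)
})

test_that("FC is invariant to a common affine map and to adding the global regressor", {
  fs <- 1.77
  n <- 500
  set.seed(21)
  m <- matrix(rnorm(5 * n), 5) + 0.5 * rep(1, 5) %o% rnorm(n)
  ev <- one_block_events(n / fs)
  base <- fc_matrix(hemo_recording("s", m, m, fs), ev)$values

  aff <- fc_matrix(hemo_recording("s", 2.7 * m + 3, 2.7 * m + 3, fs), ev)$values
  expect_equal(aff, base, tolerance = 1e-10)

  g <- colMeans(m)
  shifted <- m + 1.8 * rep(1, 5) %o% g
  withg <- fc_matrix(hemo_recording("s", shifted, shifted, fs), ev)$values
  expect_equal(withg, base, tolerance = 1e-10)
})

test_that("rejected channels appear as missing rows in the full container", {
  fs <- 1.77
  set.seed(6)
  m <- matrix(rnorm(4 * 300), 4)
  h <- hemo_recording("s", m, m, fs,
                      retained_channels = c(TRUE, TRUE, FALSE, TRUE))
  fc <- fc_matrix(h, one_block_events(300 / fs))
  expect_true(all(is.na(fc$values[3, ])))
  expect_true(all(is.na(fc$values[, 3])))
  expect_false(anyNA(fc$values[c(1, 2, 4), c(1, 2, 4)]))
})
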