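test_that("component-to-graph policies handle negatives and keep invariants", {
  m <- matrix(c(1, 0.5, 0.5, 1), 2)
  g <- component_to_graph(m)
  expect_equal(g$adjacency, matrix(c(0, 0.5, 0.5, 0), 2))

  m2 <- matrix(c(1, -0.4, -0.4, 1), 2)
  expect_equal(component_to_graph(m2, "absolute")$adjacency[1, 2], 0.4)
  expect_equal(component_to_graph(m2, "clamp_zero")$adjacency[1, 2], 0)

  for (seed in 1:10) {
    w <- component_to_graph(random_sym(8, seed))$adjacency
    expect_true(all(w >= 0))
    expect_equal(w, t(w))
    expect_equal(diag(w), rep(0, 8))
  }
})

test_that("global efficiency matches hand enumerations", {
  full <- matrix(1, 4, 4); diag(full) <- 0
  expect_equal(global_efficiency(full), 1)

  expect_equal(global_efficiency(matrix(0, 5, 5)), 0)

  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- 1
  path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(global_efficiency(path3), 5 / 6)   # d = {1, 1, 2}
})

test_that("global efficiency agrees with the igraph shortest-path oracle", {
  set.seed(14)
  for (i in 1:200) {
    n <- sample(3:10, 1)
    w <- matrix(runif(n * n), n)
    w[runif(n * n) < 0.35] <- 0     # sparsify, possibly disconnecting
    w <- (w + t(w)) / 2
    diag(w) <- 0
    expect_equal(global_efficiency(w), ge_oracle_igraph(w), tolerance = 1e-12)
  }
})

test_that("global efficiency never decreases when an edge is added", {
  set.seed(15)
  for (i in 1:30) {
    n <- 7
    w <- matrix(runif(n * n), n); w[runif(n * n) < 0.5] <- 0
    w <- (w + t(w)) / 2; diag(w) <- 0
    zero <- which(w == 0 & row(w) < col(w))
    if (length(zero) == 0) next
    e0 <- global_efficiency(w)
    pick <- zero[sample.int(length(zero), 1)]
    w[pick] <- 0.8; w[cbind(col(w)[pick], row(w)[pick])] <- 0.8
    w <- (w + t(w)) / 2
    expect_gte(global_efficiency(w), e0 - 1e-12)
  }
})

test_that("one_minus_w length mapping is available and guarded", {
  w <- matrix(c(0, 0.5, 0.5, 0), 2)
  expect_equal(global_efficiency(w, "one_minus_w"), 2)  # d = 0.5 both ways
  bad <- matrix(c(0, 1, 1, 0), 2)
  expect_error(global_efficiency(bad, "one_minus_w"), "strictly below 1")
})

test_that("cognitive quotient is accuracy percent over mean reaction time", {
  expect_equal(cognitive_quotient(make_trials(rep(TRUE, 10), rep(1, 10))), 100)
  expect_equal(cognitive_quotient(
    make_trials(rep(c(TRUE, FALSE), c(8, 2)), rep(2, 10))), 40)
  # 90 trials, 81 correct, reaction times totalling 108 s
  ev <- make_trials(rep(c(TRUE, FALSE), c(81, 9)), rep(1.2, 90))
  expect_equal(cognitive_quotient(ev), 75)
  empty <- make_trials(NA, NA)
  expect_error(cognitive_quotient(empty), "no trials")
})

test_that("artifact-flagged trials can be excluded from the cognitive quotient", {
  ev <- make_trials(c(TRUE, TRUE, FALSE, TRUE), rep(1, 4))
  ev$trials$artifact_flag <- c(FALSE, FALSE, TRUE, FALSE)
  expect_equal(cognitive_quotient(ev), 75)
  expect_equal(cognitive_quotient(ev, exclude_artifacts = TRUE), 100)
})

test_that("condition summaries report per-condition behaviour and mark missing levels", {
  blocks <- data.frame(onset_s = c(0, 100), duration_s = 39,
                       condition = c("N", "IC"))
  trials <- rbind(
    data.frame(block_index = 1L, onset_s = c(0, 6.5), condition = "N",
               is_match = TRUE, response_correct = TRUE,
               reaction_time_s = 0.9, artifact_flag = FALSE),
    data.frame(block_index = 2L, onset_s = c(100, 106.5), condition = "IC",
               is_match = TRUE, response_correct = c(TRUE, FALSE),
               reaction_time_s = 1.2, artifact_flag = FALSE))
  ev <- event_table(blocks, trials)
  s <- condition_behavior_summary(ev)
  expect_equal(s$mean_rt_s[s$condition == "IC"] - s$mean_rt_s[s$condition == "N"],
               0.3)
  expect_equal(s$error_rate[s$condition == "N"], 0)
  expect_equal(s$error_rate[s$condition == "IC"], 0.5)
  expect_true(is.na(s$mean_rt_s[s$condition == "C"]))
})

test_that("feature extraction is deterministic and reports the failing stage", {
  cfg <- cohort_config(n_per_class = c(HC = 1L, MIG = 1L, OCD = 0L, SCZ = 0L),
                       seed = 5)
  a <- simulate_subject(cfg, "HC", subject_seed = 77, subject_id = "sA")
  b <- simulate_subject(cfg, "HC", subject_seed = 77, subject_id = "sB")
  f <- extract_features(list(a, b))
  expect_equal(f$ge_cm[1], f$ge_cm[2], tolerance = 0)
  expect_equal(f$ge_dm[1], f$ge_dm[2], tolerance = 0)
  expect_equal(f$cq[1], f$cq[2], tolerance = 0)

  expect_error(extract_features(list()), "empty cohort")

  broken <- a
  broken$hemo$retained_channels <- c(TRUE, rep(FALSE, 15))
  broken$raw <- NULL
  expect_error(extract_features(list(broken)), "sA.*preprocess")
  expect_warning(res <- extract_features(list(broken, b), skip_failed = TRUE),
                 "sA")
  expect_equal(nrow(res), 1L)
})

test_that("extracted group means separate the designed extreme classes", {
  f <- small_features()
  means <- tapply(f$ge_cm, f$label, mean)
  expect_gt(means["HC"], means["SCZ"])
  cqm <- tapply(f$cq, f$label, mean)
  expect_gt(cqm["HC"], cqm["OCD"])
  expect_gt(cqm["OCD"], cqm["SCZ"])
})
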