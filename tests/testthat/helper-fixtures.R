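# Shared fixtures, built in code and memoised for the test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Tiny designed cohort: 3 subjects per class.
small_cohort <- function() {
  fixture("small_cohort", function() {
    simulate_cohort(cohort_config(
      n_per_class = c(HC = 3L, MIG = 3L, OCD = 3L, SCZ = 3L), seed = 42))
  })
}

small_features <- function() {
  fixture("small_features", function() extract_features(small_cohort()$subjects))
}

# Minimal single-block event table over a recording starting at t = 0.
one_block_events <- function(duration_s, condition = "N") {
  blocks <- data.frame(onset_s = 0, duration_s = duration_s,
                       condition = condition)
  trials <- data.frame(block_index = integer(0), onset_s = numeric(0),
                       condition = character(0), is_match = logical(0),
                       response_correct = logical(0),
                       reaction_time_s = numeric(0),
                       artifact_flag = logical(0))
  event_table(blocks, trials)
}

make_trials <- function(correct, rt, condition = "IC", block_onset = 0) {
  n <- length(correct)
  blocks <- data.frame(onset_s = block_onset, duration_s = n * 6.5,
                       condition = condition)
  trials <- data.frame(block_index = 1L,
                       onset_s = block_onset + (seq_len(n) - 1) * 6.5,
                       condition = condition, is_match = TRUE,
                       response_correct = correct, reaction_time_s = rt,
                       artifact_flag = FALSE)
  event_table(blocks, trials)
}

# Random symmetric matrix with unit diagonal (correlation-like).
random_sym <- function(n, seed) {
  set.seed(seed)
  a <- matrix(rnorm(n * n), n)
  m <- crossprod(a) / n
  d <- sqrt(diag(m))
  m <- m / outer(d, d)
  (m + t(m)) / 2
}

# Independent global-efficiency oracle via igraph shortest paths.
ge_oracle_igraph <- function(w) {
  n <- nrow(w)
  lengths <- ifelse(w > 0, 1 / w, 0)
  g <- igraph::graph_from_adjacency_matrix(lengths, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

# Independent partial-correlation oracle: correlation of least-squares
# residuals of x on z and y on z.
pcor_oracle_residual <- function(x, y, z) {
  rx <- stats::residuals(stats::lm(x ~ z))
  ry <- stats::residuals(stats::lm(y ~ z))
  stats::cor(rx, ry)
}

expect_error_message <- function(expr, pattern) {
  expect_error(expr, regexp = pattern)
}
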