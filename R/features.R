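# Subject-level features: global efficiency of the CM and DM network
# graphs, the behavioural cognitive quotient, and the cohort feature table.

#' Turn a component matrix into a weighted graph
#'
#' Zeroes the diagonal and maps negative entries per policy: `absolute`
#' (default) uses connection magnitude, `clamp_zero` removes
#' anti-correlated edges.
#'
#' @param component_matrix Symmetric numeric matrix.
#' @param negative_policy `"absolute"` or `"clamp_zero"`.
#' @return An object of class `weighted_graph` with a symmetric
#'   non-negative `adjacency` (zero diagonal) and `node_ids`.
#' @export
component_to_graph <- function(component_matrix,
                               negative_policy = c("absolute", "clamp_zero")) {
  negative_policy <- match.arg(negative_policy)
  m <- as.matrix(component_matrix)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8) {
    stop_stroopfc("component matrix must be symmetric")
  }
  m <- (m + t(m)) / 2
  w <- if (negative_policy == "absolute") abs(m) else pmax(m, 0)
  diag(w) <- 0
  structure(
    list(adjacency = w,
         node_ids = rownames(m) %||% channel_col_names(nrow(m))),
    class = "weighted_graph"
  )
}

# All-pairs shortest-path distances by Floyd-Warshall on the length
# matrix; vectorised over the intermediate node.
shortest_path_lengths <- function(lengths) {
  n <- nrow(lengths)
  d <- lengths
  diag(d) <- 0
  for (k in seq_len(n)) {
    via <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, via)
  }
  d
}

#' Weighted global efficiency
#'
#' The average inverse shortest-path length over all ordered node pairs:
#' `E = 1/(N(N-1)) * sum_{i != j} 1/d_ij`, with `d_ij` the weighted
#' shortest-path length. By default edge length is the reciprocal of edge
#' weight (strong connections are short); zero-weight edges are absent and
#' unreachable pairs contribute 0.
#'
#' @param g A [component_to_graph()] result, or a symmetric non-negative
#'   adjacency matrix with zero diagonal.
#' @param weight_to_length `"reciprocal"` (default) or `"one_minus_w"`
#'   (requires all weights strictly below 1).
#' @return Non-negative scalar.
#' @export
global_efficiency <- function(g, weight_to_length = c("reciprocal", "one_minus_w")) {
  weight_to_length <- match.arg(weight_to_length)
  w <- if (inherits(g, "weighted_graph")) g$adjacency else as.matrix(g)
  n <- nrow(w)
  if (n < 2) stop_stroopfc("global efficiency needs at least 2 nodes")
  if (any(w < 0) || max(abs(diag(w))) > 0) {
    stop_stroopfc("adjacency must be non-negative with zero diagonal")
  }
  lengths <- matrix(Inf, n, n)
  if (weight_to_length == "reciprocal") {
    pos <- w > 0
    lengths[pos] <- 1 / w[pos]
  } else {
    if (any(w >= 1 & row(w) != col(w))) {
      stop_stroopfc("one_minus_w mapping requires edge weights strictly below 1")
    }
    pos <- w > 0
    lengths[pos] <- 1 - w[pos]
  }
  d <- shortest_path_lengths(lengths)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Cognitive quotient
#'
#' Overall Stroop accuracy (percent correct over all trials) divided by the
#' mean reaction time over all trials:
#' `CQ = (100 * n_correct / n_trials) / mean(RT)`, in percent per second.
#'
#' @param events An [event_table()] with behavioural outcomes filled in.
#' @param exclude_artifacts Drop artifact-flagged trials first.
#' @return Non-negative scalar.
#' @export
cognitive_quotient <- function(events, exclude_artifacts = FALSE) {
  stopifnot(inherits(events, "event_table"))
  tr <- events$trials
  if (exclude_artifacts) tr <- tr[!(tr$artifact_flag %in% TRUE), , drop = FALSE]
  tr <- tr[!is.na(tr$response_correct) & !is.na(tr$reaction_time_s), , drop = FALSE]
  if (nrow(tr) == 0) stop_stroopfc("no trials with recorded responses")
  acc_pct <- 100 * mean(tr$response_correct)
  acc_pct / mean(tr$reaction_time_s)
}

#' Per-condition behavioural summary
#'
#' Mean reaction time and error rate for the neutral, congruent, and
#' incongruent conditions separately. Reported for descriptive use; not a
#' classifier feature.
#'
#' @param events An [event_table()].
#' @return data.frame with one row per condition (`N`, `C`, `IC`) and
#'   columns `condition`, `n_trials`, `mean_rt_s`, `error_rate`; conditions
#'   without trials carry `NA`.
#' @export
condition_behavior_summary <- function(events) {
  stopifnot(inherits(events, "event_table"))
  tr <- events$trials
  tr <- tr[!is.na(tr$response_correct) & !is.na(tr$reaction_time_s), , drop = FALSE]
  out <- data.frame(condition = CONDITION_LEVELS, n_trials = 0L,
                    mean_rt_s = NA_real_, error_rate = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(CONDITION_LEVELS)) {
    sub <- tr[tr$condition == CONDITION_LEVELS[i], , drop = FALSE]
    out$n_trials[i] <- nrow(sub)
    if (nrow(sub) > 0) {
      out$mean_rt_s[i] <- mean(sub$reaction_time_s)
      out$error_rate[i] <- mean(!sub$response_correct)
    }
  }
  out
}

#' Extract the per-subject feature table for a cohort
#'
#' Runs the full chain for every subject - channel screening, Beer-Lambert
#' conversion and filtering (when raw intensities are present), FC matrix,
#' CM/DM decomposition, global efficiency - and computes the cognitive
#' quotient. One row per subject.
#'
#' @param cohort List of [subject_record()]s.
#' @param config A [pipeline_config()] controlling thresholds and policies.
#' @param skip_failed If `TRUE`, subjects whose processing fails are
#'   dropped with a warning instead of aborting the cohort.
#' @return data.frame with columns `subject_id, ge_cm, ge_dm, cq, label`.
#' @export
extract_features <- function(cohort, config = pipeline_config(),
                             skip_failed = FALSE) {
  if (length(cohort) == 0) stop_stroopfc("empty cohort")
  rows <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    rec <- cohort[[i]]
    sid <- rec$hemo$subject_id
    rows[[i]] <- tryCatch(
      extract_subject_features(rec, config),
      error = function(e) {
        msg <- paste0("subject ", sid, ": ", conditionMessage(e))
        if (skip_failed) {
          warning(msg, call. = FALSE)
          NULL
        } else {
          stop_stroopfc(msg)
        }
      }
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop_stroopfc("no subject produced features")
  out <- do.call(rbind, rows)
  out$label <- factor(out$label, levels = CLASS_LEVELS)
  rownames(out) <- NULL
  out
}

extract_subject_features <- function(record, config) {
  stage <- "preprocess"
  res <- tryCatch({
    hemo <- preprocess_subject(
      record,
      cv_threshold_pct = config$cv_threshold_pct,
      mbll = mbll_params(config$extinction, config$dpf, config$distance_cm),
      spec = filter_spec(config$filter_order, config$filter_cutoff_hz)
    )
    events <- record$events
    if (config$artifact_method == "amplitude_threshold") {
      events <- flag_artifact_trials(
        hemo, events, method = "amplitude_threshold",
        scale_multiplier = config$artifact_scale_multiplier)
    }
    stage <- "connectivity"
    fc <- fc_matrix(hemo, events,
                    exclude_artifacts = config$exclude_artifact_blocks)
    stage <- "decomposition"
    dec <- decompose_fc(fc, strategy = config$threshold_strategy,
                        fixed_k = config$fixed_k,
                        cm_is_above = config$cm_is_above_threshold)
    stage <- "graph features"
    ge <- function(m) {
      global_efficiency(component_to_graph(m, config$negative_policy),
                        weight_to_length = config$weight_to_length)
    }
    stage <- "behaviour"
    data.frame(
      subject_id = record$hemo$subject_id,
      ge_cm = ge(dec$cm_matrix),
      ge_dm = ge(dec$dm_matrix),
      cq = cognitive_quotient(events,
                              exclude_artifacts = config$exclude_artifact_blocks),
      label = record$label,
      stringsAsFactors = FALSE
    )
  }, error = function(e) {
    stop_stroopfc("stage '", stage, "': ", conditionMessage(e))
  })
  res
}
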