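# Pipeline configuration and the end-to-end driver chaining feature
# extraction, repeated cross-validation for every algorithm x feature-set
# combination, and the pairwise statistical comparisons.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the processing chain with defaults
#' equal to the study constants (CV screen 7.5 percent, DPF 6, 0.009 Hz
#' 8th-order high-pass, C = 10, omega = sigma = 1, 10 runs of 10-fold CV).
#' Unknown keys are rejected and every value validated at construction.
#'
#' @param ... Key = value overrides of the defaults listed below.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    cv_threshold_pct = 7.5,
    dpf = 6,
    distance_cm = 2.5,
    extinction = DEFAULT_EXTINCTION,
    filter_order = 8L,
    filter_cutoff_hz = 0.009,
    artifact_method = "manual_flags",
    artifact_scale_multiplier = 10,
    exclude_artifact_blocks = FALSE,
    threshold_strategy = "mean_eigenvalue",
    fixed_k = NULL,
    cm_is_above_threshold = TRUE,
    negative_policy = "absolute",
    weight_to_length = "reciprocal",
    algorithms = c("nb", "lda", "svm"),
    C = 10,
    omega = 1,
    sigma = 1,
    standardize = TRUE,
    svm_tolerance = 1e-8,
    n_runs = 10L,
    k_folds = 10L,
    base_seed = 1L,
    average = "weighted"
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop_stroopfc("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, overrides, keep.null = TRUE)
  stopifnot(cfg$cv_threshold_pct > 0, cfg$dpf > 0, cfg$distance_cm > 0,
            cfg$filter_cutoff_hz > 0, cfg$filter_order >= 2,
            cfg$C > 0, cfg$omega > 0, cfg$sigma > 0,
            cfg$n_runs >= 1, cfg$k_folds >= 2)
  if (!all(cfg$algorithms %in% c("nb", "lda", "svm"))) {
    stop_stroopfc("algorithms must be among nb, lda, svm")
  }
  cfg$artifact_method <- match.arg(cfg$artifact_method,
                                   c("manual_flags", "amplitude_threshold"))
  cfg$threshold_strategy <- match.arg(
    cfg$threshold_strategy,
    c("mean_eigenvalue", "fixed_count_k", "elbow_max_gap"))
  cfg$negative_policy <- match.arg(cfg$negative_policy,
                                   c("absolute", "clamp_zero"))
  cfg$weight_to_length <- match.arg(cfg$weight_to_length,
                                    c("reciprocal", "one_minus_w"))
  cfg$average <- match.arg(cfg$average, c("weighted", "macro"))
  structure(cfg, class = "pipeline_config")
}

FEATURE_SETS <- list(
  fnirs_only = c("ge_cm", "ge_dm"),
  fnirs_behavioral = c("ge_cm", "ge_dm", "cq")
)

#' Run the full pipeline on a cohort
#'
#' Extracts features, cross-validates every requested algorithm with both
#' the fNIRS-only (GE_cm, GE_dm) and the fNIRS-plus-behavioural
#' (GE_cm, GE_dm, CQ) feature sets, performs pairwise comparisons of all
#' condition pairs per metric, and writes features, reports, comparisons,
#' and a provenance log to `out_dir`. Deterministic: identical
#' config + cohort give byte-identical outputs.
#'
#' @param cohort List of [subject_record()]s, or a directory path readable
#'   by [read_cohort()].
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `features`, `reports` (one
#'   `evaluation_report` per algorithm x feature set), and `comparisons`.
#' @export
run_pipeline <- function(cohort, out_dir, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  message("[features] extracting from ", length(cohort), " subjects")
  features <- extract_features(cohort, config)
  write_features(features, file.path(out_dir, "features.csv"))

  params <- puk_params(config$omega, config$sigma, config$C)
  reports <- list()
  for (alg in config$algorithms) {
    for (fs_name in names(FEATURE_SETS)) {
      key <- paste(alg, fs_name, sep = "_")
      message("[classify] ", key)
      rep <- cross_validate(features, alg,
                            feature_cols = FEATURE_SETS[[fs_name]],
                            n_runs = config$n_runs, k = config$k_folds,
                            base_seed = config$base_seed, params = params,
                            standardize = config$standardize,
                            average = config$average)
      reports[[key]] <- rep
      write_report(rep, file.path(out_dir, paste0("report_", key, ".json")))
    }
  }

  message("[compare] pairwise condition comparisons")
  keys <- names(reports)
  comparisons <- list()
  for (i in seq_along(keys)) {
    for (j in seq_along(keys)) {
      if (j <= i) next
      a <- reports[[keys[i]]]; b <- reports[[keys[j]]]
      same_alg <- a$algorithm == b$algorithm
      cmp <- compare_conditions(a, b,
                                test_kind = if (same_alg) "paired" else "two_sample")
      cmp$condition_a <- keys[i]
      cmp$condition_b <- keys[j]
      comparisons[[paste(keys[i], keys[j], sep = "_vs_")]] <- cmp
    }
  }
  comp_df <- do.call(rbind, comparisons)
  rownames(comp_df) <- NULL
  utils::write.csv(comp_df, file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE)

  provenance <- list(
    package_version = as.character(utils::packageVersion("stroopfc")),
    base_seed = config$base_seed,
    n_subjects = length(cohort),
    config = config[setdiff(names(config), "extinction")],
    extinction = config$extinction
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(list(features = features, reports = reports,
                 comparisons = comp_df))
}
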