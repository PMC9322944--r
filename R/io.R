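# Reading and writing the package's native interchange formats. The native
# subject format is a directory of delimited text tables plus a JSON
# metadata document; everything round-trips to full stored precision
# (17 significant digits), so features extracted from a re-read cohort are
# bit-identical to features extracted in memory.

fmt_num <- function(x) {
  out <- sprintf("%.17g", as.numeric(x))
  out[is.na(x)] <- "NA"
  out
}

write_numeric_table <- function(m, path, col_names, sep = ",") {
  stopifnot(is.matrix(m))
  lines <- c(
    paste(col_names, collapse = sep),
    vapply(seq_len(nrow(m)), function(i) paste(fmt_num(m[i, ]), collapse = sep), "")
  )
  writeLines(lines, path)
}

read_numeric_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "numeric", check.names = FALSE)
  as.matrix(df)
}

channel_col_names <- function(n) sprintf("ch%02d", seq_len(n))

#' Write a subject record as a native text bundle
#'
#' Creates a directory holding `meta.json`, `hbo.csv`/`hbr.csv`
#' (time-by-channel, micromolar), optional per-wavelength intensity tables,
#' and the event tables `blocks.tsv`/`trials.tsv`.
#'
#' @param record A [subject_record()].
#' @param path Directory to create (must not already contain a bundle
#'   unless `overwrite = TRUE`).
#' @param overwrite Replace an existing bundle.
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(record, path, overwrite = FALSE) {
  if (!inherits(record, "subject_record")) {
    stop_stroopfc("record must be a subject_record")
  }
  if (dir.exists(path) && file.exists(file.path(path, "meta.json")) && !overwrite) {
    stop_stroopfc("bundle already exists at ", path, "; use overwrite = TRUE")
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  hemo <- record$hemo
  n_ch <- nrow(hemo$hbo)
  meta <- list(
    format = "stroopfc_bundle",
    format_version = 1L,
    subject_id = hemo$subject_id,
    label = record$label,
    sampling_rate_hz = hemo$sampling_rate_hz,
    n_channels = n_ch,
    n_samples = ncol(hemo$hbo),
    retained_channels = hemo$retained_channels,
    has_raw = !is.null(record$raw)
  )
  if (!is.null(record$raw)) {
    meta$wavelengths_nm <- record$raw$wavelengths_nm
    meta$channel_distance_cm <- record$raw$channel_distance_cm
    meta$baseline_duration_s <- record$raw$baseline_duration_s
  }
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cols <- channel_col_names(n_ch)
  write_numeric_table(t(hemo$hbo), file.path(path, "hbo.csv"), cols)
  write_numeric_table(t(hemo$hbr), file.path(path, "hbr.csv"), cols)
  if (!is.null(record$raw)) {
    for (w in seq_along(record$raw$wavelengths_nm)) {
      write_numeric_table(
        t(record$raw$intensity[, w, ]),
        file.path(path, sprintf("intensity_%.0fnm.csv", record$raw$wavelengths_nm[w])),
        cols
      )
    }
  }
  ev <- record$events
  utils::write.table(
    data.frame(onset_s = fmt_num(ev$blocks$onset_s),
               duration_s = fmt_num(ev$blocks$duration_s),
               condition = ev$blocks$condition),
    file.path(path, "blocks.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(block_index = ev$trials$block_index,
               onset_s = fmt_num(ev$trials$onset_s),
               condition = ev$trials$condition,
               is_match = ev$trials$is_match,
               response_correct = ev$trials$response_correct,
               reaction_time_s = fmt_num(ev$trials$reaction_time_s),
               artifact_flag = ev$trials$artifact_flag),
    file.path(path, "trials.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a subject record
#'
#' @param path Bundle directory written by [write_recording()].
#' @param format `"csv_bundle"` (native) is the supported on-disk format.
#'   `"snirf"` is reserved for HDF5-based SNIRF containers and is not
#'   implemented in this build; requesting it raises an informative error.
#' @return A [subject_record()].
#' @export
read_recording <- function(path, format = c("csv_bundle", "snirf")) {
  format <- match.arg(format)
  if (format == "snirf") {
    stop_stroopfc("snirf input is not implemented; convert the recording ",
                  "to a csv bundle (see write_recording)")
  }
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop_stroopfc("no bundle found at ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)

  check_dims <- function(m, what) {
    if (ncol(m) != meta$n_channels) {
      stop_stroopfc(what, ": channel axis has ", ncol(m),
                    " columns but metadata declares ", meta$n_channels,
                    class = "stroopfc_format_error")
    }
    if (nrow(m) != meta$n_samples) {
      stop_stroopfc(what, ": time axis has ", nrow(m),
                    " rows but metadata declares ", meta$n_samples,
                    class = "stroopfc_format_error")
    }
    m
  }
  hbo <- unname(t(check_dims(read_numeric_table(file.path(path, "hbo.csv")), "hbo")))
  hbr <- unname(t(check_dims(read_numeric_table(file.path(path, "hbr.csv")), "hbr")))
  hemo <- hemo_recording(meta$subject_id, hbo, hbr,
                         sampling_rate_hz = meta$sampling_rate_hz,
                         retained_channels = as.logical(meta$retained_channels))
  raw <- NULL
  if (isTRUE(meta$has_raw)) {
    wl <- as.numeric(meta$wavelengths_nm)
    intensity <- array(NA_real_,
                       dim = c(meta$n_channels, length(wl), meta$n_samples))
    for (w in seq_along(wl)) {
      f <- file.path(path, sprintf("intensity_%.0fnm.csv", wl[w]))
      intensity[, w, ] <- unname(t(check_dims(
        read_numeric_table(f), sprintf("intensity %.0f nm", wl[w]))))
    }
    raw <- raw_recording(meta$subject_id, intensity,
                         sampling_rate_hz = meta$sampling_rate_hz,
                         wavelengths_nm = wl,
                         channel_distance_cm = meta$channel_distance_cm,
                         baseline_duration_s = meta$baseline_duration_s)
  }
  blocks <- utils::read.table(file.path(path, "blocks.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
  trials <- utils::read.table(file.path(path, "trials.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
  subject_record(hemo, event_table(blocks, trials), meta$label, raw = raw)
}

#' Write a cohort of subject records
#'
#' One bundle directory per subject plus an optional ground-truth document
#' (for synthetic cohorts).
#' @param cohort List of [subject_record()]s, or the list returned by
#'   [simulate_cohort()] (with `subjects` and `ground_truth` elements).
#' @param path Output directory.
#' @param overwrite Replace existing bundles.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, overwrite = FALSE) {
  ground_truth <- NULL
  if (!is.null(cohort$subjects)) {
    ground_truth <- cohort$ground_truth
    cohort <- cohort$subjects
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort) {
    write_recording(rec, file.path(path, rec$hemo$subject_id),
                    overwrite = overwrite)
  }
  if (!is.null(ground_truth)) {
    jsonlite::write_json(ground_truth, file.path(path, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a cohort directory
#' @param path Directory of subject bundles written by [write_cohort()].
#' @return List of [subject_record()]s, ordered by subject id.
#' @export
read_cohort <- function(path) {
  dirs <- list.dirs(path, recursive = FALSE)
  dirs <- dirs[file.exists(file.path(dirs, "meta.json"))]
  if (length(dirs) == 0) stop_stroopfc("no subject bundles found under ", path)
  lapply(sort(dirs), read_recording)
}

#' Write a feature table as CSV
#'
#' Columns `subject_id, GE_cm, GE_dm, CQ, label`, full precision.
#' @param table Feature data.frame from [extract_features()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_features <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0) {
    stop_stroopfc("feature table must be a non-empty data.frame")
  }
  lines <- c(
    "subject_id,GE_cm,GE_dm,CQ,label",
    sprintf("%s,%s,%s,%s,%s", table$subject_id, fmt_num(table$ge_cm),
            fmt_num(table$ge_dm), fmt_num(table$cq), table$label)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a feature table written by [write_features()]
#' @param path CSV file.
#' @return data.frame with columns `subject_id, ge_cm, ge_dm, cq, label`.
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(subject_id = df$subject_id,
             ge_cm = as.numeric(df$GE_cm),
             ge_dm = as.numeric(df$GE_dm),
             cq = as.numeric(df$CQ),
             label = factor(df$label, levels = CLASS_LEVELS),
             stringsAsFactors = FALSE)
}

#' Serialize an evaluation report to structured text (JSON)
#' @param report An `evaluation_report` from [cross_validate()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "evaluation_report")) {
    stop_stroopfc("report must be an evaluation_report")
  }
  payload <- list(
    algorithm = report$algorithm,
    feature_cols = report$feature_cols,
    n_runs = report$n_runs,
    k = report$k,
    base_seed = report$base_seed,
    average = report$average,
    per_run_metrics = report$per_run_metrics,
    aggregate = list(mean = as.list(report$aggregate["mean", ]),
                     sd = as.list(report$aggregate["sd", ])),
    confusion_counts = apply(report$confusion, 1, as.list),
    confusion_row_pct = apply(report$confusion_row_pct, 1, as.list),
    class_levels = rownames(report$confusion)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an evaluation report written by [write_report()]
#' @param path JSON file.
#' @return An `evaluation_report` object.
#' @export
read_report <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  lv <- p$class_levels
  conf <- t(vapply(p$confusion_counts, function(r) unlist(r)[lv], numeric(length(lv))))
  dimnames(conf) <- list(truth = lv, predicted = lv)
  conf_pct <- t(vapply(p$confusion_row_pct, function(r) unlist(r)[lv], numeric(length(lv))))
  dimnames(conf_pct) <- dimnames(conf)
  agg <- rbind(mean = unlist(p$aggregate$mean), sd = unlist(p$aggregate$sd))
  structure(
    list(algorithm = p$algorithm, feature_cols = p$feature_cols,
         n_runs = p$n_runs, k = p$k, base_seed = p$base_seed,
         average = p$average,
         per_run_metrics = as.data.frame(p$per_run_metrics),
         aggregate = agg, confusion = conf, confusion_row_pct = conf_pct),
    class = "evaluation_report"
  )
}
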