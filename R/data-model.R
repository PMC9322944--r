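# Core record types for the pipeline. All containers are plain lists with
# S3 classes and strict validators: every downstream module assumes the
# invariants enforced here.

#' Class labels recognised by the pipeline
#'
#' The closed four-class set: healthy controls (HC), migraine without aura
#' (MIG), obsessive compulsive disorder (OCD), and schizophrenia (SCZ).
#' @export
CLASS_LEVELS <- c("HC", "MIG", "OCD", "SCZ")

#' Stimulus conditions of the colour-word Stroop task
#' @export
CONDITION_LEVELS <- c("N", "C", "IC")

#' Construct a raw dual-wavelength intensity recording
#'
#' Holds detector intensities for a single subject: a 3-D array indexed
#' `[channel, wavelength, time]`. Intensities are strictly positive detector
#' counts in arbitrary units; the optical-density conversion only uses their
#' ratio to the baseline mean.
#'
#' @param subject_id Character scalar.
#' @param intensity Numeric array `[channel x wavelength x time]`, strictly
#'   positive.
#' @param sampling_rate_hz Sampling rate in Hz (device default 1.77).
#' @param wavelengths_nm Two source wavelengths in nm (default 750, 850).
#' @param channel_distance_cm Source-detector separation in cm (default 2.5).
#' @param baseline_duration_s Pre-task baseline length in seconds
#'   (default 30); the optical-density reference window.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(subject_id,
                          intensity,
                          sampling_rate_hz = 1.77,
                          wavelengths_nm = c(750, 850),
                          channel_distance_cm = 2.5,
                          baseline_duration_s = 30) {
  if (!is.character(subject_id) || length(subject_id) != 1L) {
    stop_stroopfc("subject_id must be a single character string")
  }
  if (!is.array(intensity) || length(dim(intensity)) != 3L) {
    stop_stroopfc("intensity must be a 3-D array [channel x wavelength x time]")
  }
  if (dim(intensity)[2] != length(wavelengths_nm)) {
    stop_stroopfc("wavelength axis: intensity has ", dim(intensity)[2],
                  " levels but ", length(wavelengths_nm), " wavelengths declared")
  }
  if (any(!is.finite(intensity)) || any(intensity <= 0)) {
    stop_stroopfc("all intensity values must be finite and strictly positive",
                  class = "stroopfc_validation_error")
  }
  if (!is_scalar_number(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop_stroopfc("sampling_rate_hz must be a positive scalar")
  }
  if (!is_scalar_number(baseline_duration_s) || baseline_duration_s < 0) {
    stop_stroopfc("baseline_duration_s must be a non-negative scalar")
  }
  structure(
    list(
      subject_id = subject_id,
      sampling_rate_hz = sampling_rate_hz,
      wavelengths_nm = as.numeric(wavelengths_nm),
      intensity = intensity,
      channel_distance_cm = channel_distance_cm,
      baseline_duration_s = baseline_duration_s
    ),
    class = "raw_recording"
  )
}

#' Construct a haemoglobin concentration recording
#'
#' Channel-by-time matrices of oxy- (HBO) and deoxy-haemoglobin (HBR)
#' concentration changes in micromolar, plus the channel retention mask
#' produced by quality screening.
#'
#' @param subject_id Character scalar.
#' @param hbo,hbr Numeric matrices `[channel x time]`, identical shape (uM).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param retained_channels Logical vector, one entry per channel; `TRUE`
#'   marks channels that passed quality screening.
#' @return An object of class `hemo_recording`.
#' @export
hemo_recording <- function(subject_id, hbo, hbr, sampling_rate_hz = 1.77,
                           retained_channels = rep(TRUE, nrow(hbo))) {
  if (!is.matrix(hbo) || !is.matrix(hbr)) {
    stop_stroopfc("hbo and hbr must be [channel x time] matrices")
  }
  if (!identical(dim(hbo), dim(hbr))) {
    stop_stroopfc("hbo and hbr must share the same shape; got ",
                  paste(dim(hbo), collapse = "x"), " vs ",
                  paste(dim(hbr), collapse = "x"))
  }
  if (length(retained_channels) != nrow(hbo) || !is.logical(retained_channels)) {
    stop_stroopfc("retained_channels must be a logical mask of length ",
                  nrow(hbo))
  }
  structure(
    list(
      subject_id = subject_id,
      sampling_rate_hz = sampling_rate_hz,
      hbo = hbo,
      hbr = hbr,
      retained_channels = retained_channels
    ),
    class = "hemo_recording"
  )
}

#' Construct a task event table
#'
#' `blocks` describes the 15 stimulus blocks (onset, duration, condition);
#' `trials` the individual Stroop trials with behavioural outcomes. Onsets
#' are in seconds from the first sample (t = 0); trial rows are matched to
#' blocks by `block_index` (1-based).
#'
#' @param blocks data.frame with columns `onset_s`, `duration_s`, `condition`.
#' @param trials data.frame with columns `block_index`, `onset_s`,
#'   `condition`, `is_match`, `response_correct`, `reaction_time_s`,
#'   `artifact_flag`. Behavioural columns may be `NA` for protocol
#'   scaffolds that have not been simulated or measured yet.
#' @param strict If `TRUE`, additionally require the full task protocol:
#'   15 blocks, 5 per condition, 6 trials per block.
#' @return An object of class `event_table`.
#' @export
event_table <- function(blocks, trials, strict = FALSE) {
  need_b <- c("onset_s", "duration_s", "condition")
  if (!is.data.frame(blocks) || !all(need_b %in% names(blocks))) {
    stop_stroopfc("blocks must contain columns ", paste(need_b, collapse = ", "))
  }
  need_t <- c("block_index", "onset_s", "condition", "is_match",
              "response_correct", "reaction_time_s", "artifact_flag")
  if (!is.data.frame(trials) || !all(need_t %in% names(trials))) {
    stop_stroopfc("trials must contain columns ", paste(need_t, collapse = ", "))
  }
  if (!all(blocks$condition %in% CONDITION_LEVELS)) {
    stop_stroopfc("block conditions must be one of ",
                  paste(CONDITION_LEVELS, collapse = ", "))
  }
  if (any(blocks$duration_s <= 0)) stop_stroopfc("block durations must be positive")
  if (nrow(trials) > 0) {
    bi <- trials$block_index
    if (any(bi < 1 | bi > nrow(blocks))) {
      stop_stroopfc("trial block_index out of range")
    }
    inside <- trials$onset_s >= blocks$onset_s[bi] &
      trials$onset_s < blocks$onset_s[bi] + blocks$duration_s[bi]
    if (!all(inside)) stop_stroopfc("trial onsets must fall inside their block")
    rt <- trials$reaction_time_s
    if (any(!is.na(rt) & rt <= 0)) stop_stroopfc("reaction times must be positive")
  }
  if (strict) {
    if (nrow(blocks) != 15L) stop_stroopfc("protocol requires 15 blocks")
    if (!all(table(blocks$condition)[CONDITION_LEVELS] == 5L)) {
      stop_stroopfc("protocol requires 5 blocks per condition")
    }
    if (nrow(trials) != 90L || !all(table(trials$block_index) == 6L)) {
      stop_stroopfc("protocol requires 6 trials in each of 15 blocks")
    }
  }
  structure(list(blocks = blocks, trials = trials), class = "event_table")
}

#' Bundle one subject's data
#'
#' @param hemo A [hemo_recording()].
#' @param events An [event_table()].
#' @param label Class label, one of `r paste(CLASS_LEVELS, collapse = ", ")`.
#' @param raw Optional [raw_recording()]; when present, feature extraction
#'   reruns the full screening and Beer-Lambert chain from intensities.
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(hemo, events, label, raw = NULL) {
  if (!inherits(hemo, "hemo_recording")) stop_stroopfc("hemo must be a hemo_recording")
  if (!inherits(events, "event_table")) stop_stroopfc("events must be an event_table")
  if (!is.null(raw) && !inherits(raw, "raw_recording")) {
    stop_stroopfc("raw must be a raw_recording or NULL")
  }
  label <- as.character(label)
  if (length(label) != 1L || !label %in% CLASS_LEVELS) {
    stop_stroopfc("label must be one of ", paste(CLASS_LEVELS, collapse = ", "))
  }
  structure(
    list(raw = raw, hemo = hemo, events = events, label = label),
    class = "subject_record"
  )
}

#' @export
print.subject_record <- function(x, ...) {
  cat("<subject_record>", x$hemo$subject_id, "label:", x$label, "\n")
  cat("  channels:", nrow(x$hemo$hbo),
      "(", sum(x$hemo$retained_channels), "retained )",
      " samples:", ncol(x$hemo$hbo),
      " raw:", if (is.null(x$raw)) "absent" else "present", "\n")
  invisible(x)
}

#' @export
print.event_table <- function(x, ...) {
  cat("<event_table>", nrow(x$blocks), "blocks,", nrow(x$trials), "trials\n")
  print(table(x$blocks$condition))
  invisible(x)
}
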