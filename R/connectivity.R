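# Partial-correlation functional connectivity: global systemic regressor,
# task-block truncation/concatenation, and the 16x16 FC matrix.

#' Global systemic regressor
#'
#' Unweighted mean of the (filtered) HBO series across retained channels at
#' every time point; used as the partial regressor that removes common
#' systemic interference from channel-pair correlations.
#'
#' @param hemo A filtered [hemo_recording()].
#' @return Numeric vector, one value per sample.
#' @export
global_regressor <- function(hemo) {
  stopifnot(inherits(hemo, "hemo_recording"))
  keep <- hemo$retained_channels
  if (sum(keep) < 2) {
    stop_stroopfc("global regressor needs at least 2 retained channels")
  }
  colMeans(hemo$hbo[keep, , drop = FALSE])
}

block_sample_indices <- function(blocks, sampling_rate_hz, n_samples) {
  lapply(seq_len(nrow(blocks)), function(b) {
    onset <- blocks$onset_s[b]
    end <- onset + blocks$duration_s[b]
    i0 <- floor(onset * sampling_rate_hz)        # 0-based half-open window
    i1 <- floor(end * sampling_rate_hz)
    if (i0 < 0 || i1 > n_samples) {
      stop_stroopfc("block ", b, " [", onset, ", ", end,
                    ") s lies outside the recording (", n_samples, " samples)")
    }
    if (i1 <= i0) stop_stroopfc("block ", b, " spans no samples")
    (i0 + 1L):i1                                 # 1-based for R
  })
}

#' Truncate a series to task blocks and concatenate
#'
#' For every stimulus block, samples with 0-based index in
#' `[floor(onset*fs), floor((onset+duration)*fs))` are kept; the blocks'
#' samples are concatenated in block order. When `exclude_artifacts` is
#' `TRUE`, blocks containing any artifact-flagged trial are dropped whole.
#'
#' @param series Numeric vector sampled at `sampling_rate_hz`.
#' @param events An [event_table()].
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param exclude_artifacts Drop blocks with artifact-flagged trials.
#' @return Numeric vector of concatenated task samples.
#' @export
concatenate_task_segments <- function(series, events, sampling_rate_hz,
                                      exclude_artifacts = FALSE) {
  stopifnot(inherits(events, "event_table"))
  blocks <- events$blocks
  keep <- rep(TRUE, nrow(blocks))
  if (exclude_artifacts && nrow(events$trials) > 0) {
    bad <- unique(events$trials$block_index[events$trials$artifact_flag %in% TRUE])
    keep[bad] <- FALSE
  }
  blocks <- blocks[keep, , drop = FALSE]
  if (nrow(blocks) == 0) {
    stop_stroopfc("no task blocks to concatenate (empty task series)")
  }
  idx <- block_sample_indices(blocks, sampling_rate_hz, length(series))
  series[unlist(idx)]
}

#' First-order partial correlation
#'
#' `r_xy|z = (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) (1 - r_yz^2))` with
#' `r` the Pearson correlation; the correlation between `x` and `y` after
#' removing the linear contribution of `z`.
#'
#' @param x,y,z Equal-length numeric vectors (length >= 3), each
#'   non-constant.
#' @param ids Optional labels for `x` and `y` used in error messages.
#' @return Partial correlation in `[-1, 1]`.
#' @export
partial_correlation <- function(x, y, z, ids = c("x", "y")) {
  n <- length(x)
  if (length(y) != n || length(z) != n) {
    stop_stroopfc("x, y, z must have equal length")
  }
  if (n < 3) stop_stroopfc("need at least 3 samples")
  for (s in list(x = x, y = y, z = z)) {
    if (stats::sd(s) == 0) stop_stroopfc("constant series: correlation undefined")
  }
  rxy <- stats::cor(x, y)
  rxz <- stats::cor(x, z)
  ryz <- stats::cor(y, z)
  den2 <- (1 - rxz^2) * (1 - ryz^2)
  if (den2 <= .Machine$double.eps) {
    stop_stroopfc("partial correlation undefined for channels ", ids[1], ", ",
                  ids[2], ": a channel is collinear with the global regressor")
  }
  r <- (rxy - rxz * ryz) / sqrt(den2)
  min(1, max(-1, r))
}

#' Partial-correlation functional connectivity matrix
#'
#' For every retained channel pair the Pearson correlation over the
#' concatenated task segments is partialled on the identically concatenated
#' global regressor. Rejected channels yield `NA` rows/columns in the
#' full-size container; the diagonal of retained channels is exactly 1.
#'
#' @param hemo A filtered [hemo_recording()].
#' @param events An [event_table()].
#' @param exclude_artifacts Drop blocks with artifact-flagged trials before
#'   concatenation.
#' @return An object of class `fc_matrix` with fields `values`
#'   (full-size symmetric matrix), `n_samples_used`, `channel_ids`, and
#'   `retained`.
#' @export
fc_matrix <- function(hemo, events, exclude_artifacts = FALSE) {
  stopifnot(inherits(hemo, "hemo_recording"))
  keep <- hemo$retained_channels
  n_ch <- length(keep)
  g <- global_regressor(hemo)
  fs <- hemo$sampling_rate_hz
  gz <- concatenate_task_segments(g, events, fs, exclude_artifacts)
  task <- lapply(which(keep), function(ch) {
    concatenate_task_segments(hemo$hbo[ch, ], events, fs, exclude_artifacts)
  })
  ids <- channel_col_names(n_ch)
  vals <- matrix(NA_real_, n_ch, n_ch, dimnames = list(ids, ids))
  ridx <- which(keep)
  for (a in seq_along(ridx)) {
    vals[ridx[a], ridx[a]] <- 1
    if (a < length(ridx)) {
      for (b in (a + 1):length(ridx)) {
        r <- partial_correlation(task[[a]], task[[b]], gz,
                                 ids = ids[c(ridx[a], ridx[b])])
        vals[ridx[a], ridx[b]] <- r
        vals[ridx[b], ridx[a]] <- r
      }
    }
  }
  structure(
    list(values = vals, n_samples_used = length(gz), channel_ids = ids,
         retained = keep),
    class = "fc_matrix"
  )
}

#' Export an FC matrix as square CSV
#' @param fc An `fc_matrix`.
#' @param path Output file; channel ids as header row and first column.
#' @return `path`, invisibly.
#' @export
write_fc_matrix <- function(fc, path) {
  stopifnot(inherits(fc, "fc_matrix"))
  utils::write.csv(fc$values, path, row.names = TRUE)
  invisible(path)
}
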