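# Synthetic cohort generator. Emulates the task protocol (30 s baseline;
# 15 blocks of 6 Stroop trials, 2.5 s stimulus + 4 s blank; 20 s rests),
# the signal model behind the connectivity analysis (latent cognitive-mode
# and default-mode factors with class-specific coupling, a task response,
# shared systemic physiology, white noise), and class-specific Stroop
# behaviour. Everything is reproducible: (config, seed) determines every
# output bit.

N_CHANNELS <- 16L

#' Synthetic cohort configuration
#'
#' Defaults encode the designed study conditions: cohort sizes 13/20/26/21
#' (HC/MIG/OCD/SCZ), the full task timing, and class effects chosen so
#' that cognitive-mode coupling is ordered HC > MIG > OCD > SCZ with HC
#' and MIG deliberately the closest pair (migraineurs tested interictally
#' behave nearly like controls), while default-mode coupling is common to
#' all classes.
#'
#' @param n_per_class Named integer vector of cohort sizes.
#' @param seed Master seed; all subject-level seeds derive from it.
#' @param class_effects `"designed"` (class-separated defaults) or
#'   `"null"` (all classes share one parameter set; no class signal).
#' @param class_network_coupling Per-class list of `cm` and `dm` latent
#'   factor loading scales.
#' @param class_hrf_amplitude Per-class task-response scaling.
#' @param class_behavior Per-class list: `p_correct` and `rt_mean_s`, each
#'   length 3 (conditions N, C, IC).
#' @param rt_sdlog Within-subject log-RT standard deviation.
#' @param rt_subject_sdlog,p_logit_jitter_sd,coupling_jitter_sd
#'   Between-subject variability of RT scale, accuracy (logit), and
#'   coupling scale.
#' @param systemic Shared physiology: Mayer-wave and respiratory sinusoid
#'   amplitudes (uM) and frequencies (Hz), plus a very slow drift
#'   amplitude (removed by the high-pass).
#' @param noise_sd Channel white-noise SD (uM).
#' @param hrf_base_amp Base task-response amplitude (uM).
#' @param hbr_scale,hbr_noise_sd HBR is `hbr_scale * HBO` plus noise.
#' @param planted_bad_channels Channels per subject given excess intensity
#'   variability (CV above the screening threshold).
#' @param planted_artifact_trials Trials per subject given a motion-spike.
#' @param emit_raw_intensity Also synthesise raw dual-wavelength
#'   intensities through the forward Beer-Lambert model.
#' @param sampling_rate_hz,baseline_s,stimulus_s,blank_s,rest_s,
#'   trials_per_block,blocks_per_condition Protocol timing constants.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_class = c(HC = 13L, MIG = 20L, OCD = 26L, SCZ = 21L),
                          seed = 1,
                          class_effects = c("designed", "null"),
                          class_network_coupling = NULL,
                          class_hrf_amplitude = NULL,
                          class_behavior = NULL,
                          rt_sdlog = 0.15,
                          rt_subject_sdlog = 0.05,
                          p_logit_jitter_sd = 0.2,
                          coupling_jitter_sd = 0.06,
                          systemic = list(mayer_amp = 0.3, mayer_freq_hz = 0.1,
                                          resp_amp = 0.2, resp_freq_hz = 0.3,
                                          drift_amp = 0.5),
                          noise_sd = 0.5,
                          hrf_base_amp = 0.2,
                          hbr_scale = -0.3,
                          hbr_noise_sd = 0.1,
                          planted_bad_channels = 0L,
                          planted_artifact_trials = 0L,
                          emit_raw_intensity = TRUE,
                          sampling_rate_hz = 1.77,
                          baseline_s = 30,
                          stimulus_s = 2.5,
                          blank_s = 4,
                          rest_s = 20,
                          trials_per_block = 6L,
                          blocks_per_condition = 5L) {
  class_effects <- match.arg(class_effects)
  if (!all(names(n_per_class) == CLASS_LEVELS)) {
    stop_stroopfc("n_per_class must be named ", paste(CLASS_LEVELS, collapse = ", "))
  }
  if (any(n_per_class < 0)) stop_stroopfc("cohort sizes must be non-negative")
  nyquist <- sampling_rate_hz / 2
  if (systemic$mayer_freq_hz >= nyquist || systemic$resp_freq_hz >= nyquist) {
    stop_stroopfc("systemic frequencies must be below Nyquist (", nyquist, " Hz)")
  }
  designed <- list(
    class_network_coupling = list(
      HC  = list(cm = 0.90, dm = 0.60),
      MIG = list(cm = 0.82, dm = 0.60),
      OCD = list(cm = 0.55, dm = 0.60),
      SCZ = list(cm = 0.35, dm = 0.60)
    ),
    class_hrf_amplitude = c(HC = 1.0, MIG = 0.9, OCD = 0.7, SCZ = 0.5),
    class_behavior = list(
      HC  = list(p_correct = c(0.97, 0.96, 0.900), rt_mean_s = c(0.85, 0.90, 1.15)),
      MIG = list(p_correct = c(0.94, 0.93, 0.850), rt_mean_s = c(1.00, 1.05, 1.35)),
      OCD = list(p_correct = c(0.88, 0.86, 0.760), rt_mean_s = c(1.50, 1.60, 2.00)),
      SCZ = list(p_correct = c(0.78, 0.75, 0.620), rt_mean_s = c(2.10, 2.20, 2.80))
    )
  )
  if (class_effects == "null") {
    shared_coupling <- list(cm = 0.60, dm = 0.60)
    shared_behavior <- list(p_correct = c(0.90, 0.89, 0.84),
                            rt_mean_s = c(1.20, 1.25, 1.50))
    designed$class_network_coupling <- stats::setNames(
      rep(list(shared_coupling), 4), CLASS_LEVELS)
    designed$class_hrf_amplitude <- stats::setNames(rep(0.75, 4), CLASS_LEVELS)
    designed$class_behavior <- stats::setNames(
      rep(list(shared_behavior), 4), CLASS_LEVELS)
  }
  cfg <- list(
    n_per_class = n_per_class,
    seed = seed,
    class_effects = class_effects,
    class_network_coupling = class_network_coupling %||% designed$class_network_coupling,
    class_hrf_amplitude = class_hrf_amplitude %||% designed$class_hrf_amplitude,
    class_behavior = class_behavior %||% designed$class_behavior,
    rt_sdlog = rt_sdlog,
    rt_subject_sdlog = rt_subject_sdlog,
    p_logit_jitter_sd = p_logit_jitter_sd,
    coupling_jitter_sd = coupling_jitter_sd,
    systemic = systemic,
    noise_sd = noise_sd,
    hrf_base_amp = hrf_base_amp,
    hbr_scale = hbr_scale,
    hbr_noise_sd = hbr_noise_sd,
    planted_bad_channels = as.integer(planted_bad_channels),
    planted_artifact_trials = as.integer(planted_artifact_trials),
    emit_raw_intensity = emit_raw_intensity,
    sampling_rate_hz = sampling_rate_hz,
    baseline_s = baseline_s,
    stimulus_s = stimulus_s,
    blank_s = blank_s,
    rest_s = rest_s,
    trials_per_block = trials_per_block,
    blocks_per_condition = blocks_per_condition
  )
  for (p in lapply(cfg$class_behavior, `[[`, "p_correct")) {
    if (any(p < 0 | p > 1)) stop_stroopfc("p_correct values must lie in [0, 1]")
  }
  structure(cfg, class = "cohort_config")
}

#' Canonical double-gamma haemodynamic response function
#'
#' Peak near 6 s, undershoot near 16 s; sampled at `fs` over
#' `duration_s` seconds and normalised to unit peak.
#'
#' @param fs Sampling rate in Hz.
#' @param duration_s Kernel length in seconds (default 30).
#' @return Numeric vector of kernel samples.
#' @export
canonical_hrf <- function(fs, duration_s = 30) {
  t <- seq(0, duration_s, by = 1 / fs)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Build a randomized task timeline
#'
#' 30 s baseline, then the 15 stimulus blocks (5 per condition) in seeded
#' random order. Each block holds 6 trials of
#' `stimulus_s + blank_s = 6.5` s, so a block spans 39 s; a 20 s rest
#' follows every block (including the last), for a total of 915 s.
#' Match/non-match cases are balanced within each block. Behavioural
#' outcome columns are left `NA`; [simulate_subject()] fills them.
#'
#' @param config A [cohort_config()].
#' @param seed Timeline seed.
#' @return An [event_table()] with attribute `total_duration_s`.
#' @export
build_timeline <- function(config = cohort_config(), seed = 1) {
  tpb <- config$trials_per_block
  trial_s <- config$stimulus_s + config$blank_s
  block_s <- tpb * trial_s
  n_blocks <- 3L * config$blocks_per_condition
  out <- with_seed(seed, {
    cond <- sample(rep(CONDITION_LEVELS, config$blocks_per_condition))
    onsets <- config$baseline_s + (seq_len(n_blocks) - 1) * (block_s + config$rest_s)
    blocks <- data.frame(onset_s = onsets, duration_s = block_s,
                         condition = cond, stringsAsFactors = FALSE)
    half <- tpb %/% 2
    trials <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
      data.frame(
        block_index = b,
        onset_s = onsets[b] + (seq_len(tpb) - 1) * trial_s,
        condition = cond[b],
        is_match = sample(rep(c(TRUE, FALSE), c(half, tpb - half))),
        response_correct = NA,
        reaction_time_s = NA_real_,
        artifact_flag = FALSE,
        stringsAsFactors = FALSE
      )
    }))
    event_table(blocks, trials)
  })
  attr(out, "total_duration_s") <-
    config$baseline_s + n_blocks * (block_s + config$rest_s)
  out
}

# AR(1) latent factor with unit marginal variance.
ar1_series <- function(n, phi = 0.9) {
  as.numeric(stats::filter(stats::rnorm(n, sd = sqrt(1 - phi^2)), phi,
                           method = "recursive",
                           init = stats::rnorm(1)))
}

# Fixed loading geometry: channels 1-8 carry the cognitive-mode factor,
# 9-16 the default-mode factor, with alternating signs so the factors
# cancel from the channel mean and survive global-signal correction.
cm_loading_pattern <- function() c(rep(c(1, -1), 4), rep(0, 8))
dm_loading_pattern <- function() c(rep(0, 8), rep(c(1, -1), 4))

#' Simulate one subject
#'
#' Generates the HBO signal model
#' `a_i f_cm(t) + b_i f_dm(t) + task response + shared systemic + noise`,
#' the negatively-coupled HBR copy, class-specific Stroop behaviour, and
#' (optionally) raw dual-wavelength intensities through the forward
#' Beer-Lambert model, with planted high-CV channels and artifact spikes
#' when requested.
#'
#' @param config A [cohort_config()].
#' @param label Class label.
#' @param subject_seed Integer seed; fully determines the subject.
#' @param subject_id Subject identifier.
#' @return A [subject_record()]. Planted defects are recorded in
#'   attributes `planted_bad_channels` and `planted_artifact_trials`.
#' @export
simulate_subject <- function(config, label, subject_seed,
                             subject_id = sprintf("sub_%s_%d", label, subject_seed)) {
  stopifnot(inherits(config, "cohort_config"))
  label <- match.arg(label, CLASS_LEVELS)
  fs <- config$sampling_rate_hz
  events <- build_timeline(config, seed = derive_seed(subject_seed, 1))
  total_s <- attr(events, "total_duration_s")
  n <- floor(total_s * fs)
  t <- (seq_len(n) - 1) / fs

  coup <- config$class_network_coupling[[label]]
  beh <- config$class_behavior[[label]]

  sig <- with_seed(derive_seed(subject_seed, 2), {
    s_cm <- coup$cm * exp(stats::rnorm(1, 0, config$coupling_jitter_sd))
    s_dm <- coup$dm * exp(stats::rnorm(1, 0, config$coupling_jitter_sd))
    f_cm <- ar1_series(n)
    f_dm <- ar1_series(n)
    # task regressor: condition boxcars convolved with the canonical HRF
    hrf <- canonical_hrf(fs)
    box <- numeric(n)
    for (b in seq_len(nrow(events$blocks))) {
      i0 <- floor(events$blocks$onset_s[b] * fs) + 1L
      i1 <- min(n, floor((events$blocks$onset_s[b] + events$blocks$duration_s[b]) * fs))
      box[i0:i1] <- 1
    }
    task <- stats::convolve(box, rev(hrf), type = "open")[seq_len(n)] / fs
    task <- task / max(max(abs(task)), .Machine$double.eps)
    amp <- config$class_hrf_amplitude[[label]] * config$hrf_base_amp
    sysd <- config$systemic
    phase <- stats::runif(3, 0, 2 * pi)
    systemic <- sysd$mayer_amp * sin(2 * pi * sysd$mayer_freq_hz * t + phase[1]) +
      sysd$resp_amp * sin(2 * pi * sysd$resp_freq_hz * t + phase[2]) +
      sysd$drift_amp * sin(2 * pi * t / (2 * total_s) + phase[3])
    sys_gain <- 1 + stats::runif(N_CHANNELS, -0.2, 0.2)
    task_gain <- rep(c(1, -1), N_CHANNELS / 2)
    lc <- cm_loading_pattern() * s_cm
    ld <- dm_loading_pattern() * s_dm
    hbo <- matrix(0, N_CHANNELS, n)
    for (ch in seq_len(N_CHANNELS)) {
      hbo[ch, ] <- lc[ch] * f_cm + ld[ch] * f_dm +
        task_gain[ch] * amp * task + sys_gain[ch] * systemic +
        stats::rnorm(n, sd = config$noise_sd)
    }
    hbr <- config$hbr_scale * hbo +
      matrix(stats::rnorm(N_CHANNELS * n, sd = config$hbr_noise_sd), N_CHANNELS, n)
    list(hbo = hbo, hbr = hbr, s_cm = s_cm, s_dm = s_dm)
  })

  trials <- events$trials
  trials <- with_seed(derive_seed(subject_seed, 3), {
    p_shift <- stats::rnorm(1, 0, config$p_logit_jitter_sd)
    rt_shift <- stats::rnorm(1, 0, config$rt_subject_sdlog)
    ci <- match(trials$condition, CONDITION_LEVELS)
    p <- stats::plogis(stats::qlogis(beh$p_correct[ci]) + p_shift)
    trials$response_correct <- stats::runif(nrow(trials)) < p
    rt <- stats::rlnorm(nrow(trials),
                        meanlog = log(beh$rt_mean_s[ci]) + rt_shift,
                        sdlog = config$rt_sdlog)
    trials$reaction_time_s <- pmin(rt, config$stimulus_s + config$blank_s)
    trials
  })

  planted <- with_seed(derive_seed(subject_seed, 4), {
    bad <- if (config$planted_bad_channels > 0) {
      sort(sample.int(N_CHANNELS, config$planted_bad_channels))
    } else integer(0)
    art <- if (config$planted_artifact_trials > 0) {
      sort(sample.int(nrow(trials), config$planted_artifact_trials))
    } else integer(0)
    list(bad_channels = bad, artifact_trials = art)
  })

  hbo <- sig$hbo
  hbr <- sig$hbr
  affected_trials <- integer(0)
  if (length(planted$artifact_trials) > 0) {
    spike_idx <- integer(0)
    for (tr in planted$artifact_trials) {
      i0 <- floor((trials$onset_s[tr] + 1.25) * fs) + 1L
      idx <- i0:min(n, i0 + 1L)
      hbo[, idx] <- hbo[, idx] + 25   # ~20x the robust signal scale
      spike_idx <- c(spike_idx, idx)
    }
    # the +/- 5 s screening windows of adjacent trials overlap, so one
    # spike can fall inside several trials' windows; record all of them
    win0 <- pmax(1L, floor((trials$onset_s - 5) * fs) + 1L)
    win1 <- pmin(n, floor((trials$onset_s + config$stimulus_s + 5) * fs) + 1L)
    affected_trials <- which(vapply(seq_len(nrow(trials)), function(j) {
      any(spike_idx >= win0[j] & spike_idx <= win1[j])
    }, logical(1)))
  }

  raw <- NULL
  if (config$emit_raw_intensity) {
    mb <- mbll_params()
    n_base <- floor(config$baseline_s * fs)
    ref <- function(m) m - rowMeans(m[, seq_len(n_base), drop = FALSE])
    dhbo <- ref(hbo); dhbr <- ref(hbr)
    scale <- mb$distance_cm * mb$pathlength_factor
    intensity <- array(NA_real_, dim = c(N_CHANNELS, 2L, n))
    i0_counts <- 800 + 25 * seq_len(N_CHANNELS)
    for (ch in seq_len(N_CHANNELS)) {
      od <- mb$extinction %*% rbind(dhbo[ch, ], dhbr[ch, ]) * scale
      for (w in 1:2) intensity[ch, w, ] <- i0_counts[ch] * 10^(-od[w, ])
    }
    for (ch in planted$bad_channels) {
      wobble <- 1 + 0.15 * sin(2 * pi * 0.005 * t)
      intensity[ch, 1, ] <- intensity[ch, 1, ] * wobble
      intensity[ch, 2, ] <- intensity[ch, 2, ] * wobble
    }
    raw <- raw_recording(subject_id, intensity, sampling_rate_hz = fs,
                         baseline_duration_s = config$baseline_s)
  }

  rec <- subject_record(
    hemo = hemo_recording(subject_id, hbo, hbr, sampling_rate_hz = fs),
    events = event_table(events$blocks, trials, strict = TRUE),
    label = label,
    raw = raw
  )
  attr(rec, "planted_bad_channels") <- planted$bad_channels
  attr(rec, "planted_artifact_trials") <- affected_trials
  attr(rec, "coupling") <- c(cm = sig$s_cm, dm = sig$s_dm)
  rec
}

#' Simulate a full cohort
#'
#' Subjects are generated class by class with seeds derived from the
#' master seed; the returned ground-truth document records the designed
#' class effects for recovery tests.
#'
#' @param config A [cohort_config()].
#' @return List with `subjects` (list of [subject_record()]s) and
#'   `ground_truth` (designed parameters, the expected descending GE_cm
#'   class ordering, and the designed closest class pair).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  labels <- rep(CLASS_LEVELS, config$n_per_class)
  subjects <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    subjects[[i]] <- simulate_subject(
      config, labels[i],
      subject_seed = derive_seed(config$seed, 100 + i),
      subject_id = sprintf("sub%03d", i)
    )
  }
  cm_scales <- vapply(config$class_network_coupling, `[[`, numeric(1), "cm")
  ordering <- names(sort(cm_scales, decreasing = TRUE))
  gaps <- abs(outer(cm_scales, cm_scales, `-`))
  diag(gaps) <- Inf
  closest <- sort(rownames(which(gaps == min(gaps), arr.ind = TRUE))[1:2])
  list(
    subjects = subjects,
    ground_truth = list(
      seed = config$seed,
      class_effects = config$class_effects,
      n_per_class = as.list(config$n_per_class),
      cm_coupling = as.list(cm_scales),
      dm_coupling = lapply(config$class_network_coupling, `[[`, "dm"),
      designed_ge_cm_ordering = ordering,
      designed_closest_pair = closest,
      class_behavior = config$class_behavior
    )
  )
}
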