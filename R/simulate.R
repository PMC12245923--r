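#' Simulation configuration for synthetic speech-production EEG
#'
#' Describes a synthetic cohort that mirrors the word-production protocol:
#' per subject, eight blocks of 50 trials (four blocks per condition) in
#' randomized block order, one of five words cued visually per trial,
#' recorded on the 32-channel 10/10 montage at 1200 Hz over a -1.5..1.5 s
#' window around the cue.  Each epoch is 1/f background noise plus
#' stimulus-locked evoked components (P100, N200, P300, N400, P450, with
#' posterior channels leading frontal ones by ~50 ms, and additional
#' overt-only activity at 600-800 ms), plus a word-specific low-rank
#' spatiotemporal signature of which a fraction `shared_fraction` is
#' common to the overt and imagined conditions.
#'
#' @param n_subjects number of subjects in the cohort.
#' @param n_blocks_per_condition blocks per condition (default 4).
#' @param trials_per_block trials per block (default 50); must be divisible
#'   by the number of words.
#' @param fs_native acquisition sampling rate, Hz (default 1200).
#' @param window epoch window in seconds relative to the cue.
#' @param words ordered vocabulary (default the five Spanish study words).
#' @param word_effect_size dimensionless scale of the word-specific evoked
#'   signature; 0 removes all class information.
#' @param shared_fraction fraction in `[0, 1]` of the word signature common
#'   to both conditions (1 = identical signatures, 0 = disjoint).
#' @param imagined_scale multiplier (0, 1] applied to the word signature in
#'   the imagined condition, modelling its lower signal-to-noise ratio.
#' @param noise_alpha exponent of the 1/f^alpha background noise.
#' @param noise_sd background noise standard deviation, microvolts.
#' @param component_amp amplitude scale of the evoked components, microvolts.
#' @param artifact_rates named per-trial probabilities for `blink`, `emg`,
#'   `ecg` artifact injection.
#' @param artifact_amps named artifact amplitudes in microvolts.
#' @param subject_gain_sd standard deviation of the per-channel log-normal
#'   subject gain.
#' @param latency_jitter_sd per-subject component latency jitter, seconds.
#' @param seed master seed; all randomness fans out from it through named
#'   substreams (schedule, noise, artifacts, signatures, subjects).
#' @param schedule_seed optional separate master seed for the trial
#'   schedule substream, so noise realizations can be varied while keeping
#'   the schedule fixed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 24,
                       n_blocks_per_condition = 4,
                       trials_per_block = 50,
                       fs_native = 1200,
                       window = c(-1.5, 1.5),
                       words = study_words(),
                       word_effect_size = 1,
                       shared_fraction = 0.8,
                       imagined_scale = 0.7,
                       noise_alpha = 1,
                       noise_sd = 10,
                       component_amp = 1,
                       artifact_rates = c(blink = 0.05, emg = 0.05, ecg = 0.02),
                       artifact_amps = c(blink = 120, emg = 30, ecg = 8),
                       subject_gain_sd = 0.1,
                       latency_jitter_sd = 0.01,
                       seed = 1,
                       schedule_seed = NULL) {
  stopifnot(n_subjects >= 1, n_blocks_per_condition >= 1,
            trials_per_block >= 1, fs_native > 0,
            shared_fraction >= 0, shared_fraction <= 1,
            imagined_scale > 0, imagined_scale <= 1,
            all(artifact_rates >= 0), all(artifact_rates <= 1),
            noise_sd > 0)
  cfg <- list(n_subjects = n_subjects,
              n_blocks_per_condition = n_blocks_per_condition,
              trials_per_block = trials_per_block,
              fs_native = fs_native, window = window, words = words,
              word_effect_size = word_effect_size,
              shared_fraction = shared_fraction,
              imagined_scale = imagined_scale,
              noise_alpha = noise_alpha, noise_sd = noise_sd,
              component_amp = component_amp,
              artifact_rates = artifact_rates,
              artifact_amps = artifact_amps,
              subject_gain_sd = subject_gain_sd,
              latency_jitter_sd = latency_jitter_sd,
              seed = seed, schedule_seed = schedule_seed)
  class(cfg) <- "sim_config"
  cfg
}

# evoked component inventory: latency (s), amplitude (uV, sign = polarity),
# width (s), scalp topography, and whether the component is overt-only
# (the late 600-800 ms production-related activity).
component_table <- function(cfg) {
  data.frame(
    name = c("P100", "N200", "P300", "N400", "P450", "late650", "late750"),
    lat = c(0.100, 0.200, 0.275, 0.370, 0.450, 0.650, 0.750),
    amp = cfg$component_amp * c(3, -3, 4, -3, 3, 3, -3),
    width = c(0.10, 0.10, 0.12, 0.12, 0.10, 0.10, 0.10),
    topo = c("posterior", "frontocentral", "centroparietal",
             "centroparietal", "frontal", "posterior", "centroparietal"),
    overt_only = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

topo_weights <- function(topo, montage = standard_montage()) {
  y <- montage$y
  switch(topo,
         posterior = exp(-(y + 0.8)^2 / (2 * 0.35^2)),
         frontal = exp(-(y - 0.8)^2 / (2 * 0.30^2)),
         frontocentral = exp(-(y - 0.45)^2 / (2 * 0.30^2)),
         centroparietal = exp(-(y + 0.30)^2 / (2 * 0.30^2)),
         uniform = rep(1, length(y)),
         stop("unknown topography: ", topo))
}

# smooth unimodal bump: half-cosine tapered by a Gaussian, supported on
# |t - lat| <= width
bump <- function(t, lat, width, amp) {
  u <- (t - lat) / width
  ifelse(abs(u) <= 1, amp * cos(pi * u / 2) * exp(-2 * u^2), 0)
}

#' Per-subject generative profile
#'
#' Draws the subject-level variability: a log-normal per-channel gain, a
#' latency jitter per evoked component, and a scalar mixing weight applied
#' to the cohort-level word signatures.
#'
#' @param cfg a [sim_config()].
#' @param subject 1-based subject index.
#' @return A `subject_profile` list.
#' @export
subject_profile <- function(cfg, subject) {
  montage <- standard_montage()
  comp <- component_table(cfg)
  with_seed(sub_seed(cfg$seed, "subject", subject), {
    gain <- exp(stats::rnorm(nrow(montage), 0, cfg$subject_gain_sd))
    jitter <- stats::rnorm(nrow(comp), 0, cfg$latency_jitter_sd)
    mix <- abs(stats::rnorm(1, 1, 0.2))
    structure(list(subject = subject,
                   id = sprintf("S%02d", subject),
                   gain = gain, latency_jitter = jitter,
                   signature_mix = mix),
              class = "subject_profile")
  })
}

#' Randomized block/trial schedule
#'
#' Builds the per-subject trial schedule: `n_blocks_per_condition` blocks
#' per condition, each block homogeneous in condition and balanced over
#' words (`trials_per_block / n_words` occurrences each, shuffled within
#' the block), with the block order randomized.
#'
#' @param cfg a [sim_config()].
#' @param seed schedule seed (defaults to the `schedule` substream of the
#'   master seed, or of `cfg$schedule_seed` when set).
#' @return A data.frame with columns `block`, `condition`, `word`; one row
#'   per trial in presentation order.
#' @export
generate_schedule <- function(cfg,
                              seed = sub_seed(
                                if (is.null(cfg$schedule_seed)) cfg$seed
                                else cfg$schedule_seed, "schedule")) {
  nw <- length(cfg$words)
  if (cfg$trials_per_block %% nw != 0)
    stop(sprintf("trials_per_block (%d) is not divisible by the number of words (%d)",
                 cfg$trials_per_block, nw))
  per_word <- cfg$trials_per_block / nw
  with_seed(seed, {
    blocks <- data.frame(
      condition = rep(study_conditions(), each = cfg$n_blocks_per_condition))
    blocks <- blocks[sample.int(nrow(blocks)), , drop = FALSE]
    out <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(b) {
      words <- sample(rep(cfg$words, per_word))
      data.frame(block = b, condition = blocks$condition[b], word = words,
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

# 1/f^alpha noise, one column per channel, scaled to sd `noise_sd`
one_over_f_noise <- function(n, n_chan, fs, alpha, noise_sd) {
  w <- matrix(stats::rnorm(n * n_chan), n, n_chan)
  if (alpha == 0) return(w * noise_sd)
  f <- c(1, seq_len(n - 1))           # DC bin treated as the first bin
  f <- pmin(f, n - f)                 # two-sided spectrum symmetry
  f <- f / n * fs
  f[f < fs / n] <- fs / n
  shape <- f^(-alpha / 2)
  x <- Re(stats::mvfft(stats::mvfft(w) * shape, inverse = TRUE)) / n
  sds <- apply(x, 2, stats::sd)
  sweep(x, 2, sds / noise_sd, "/")
}

# cohort-level word signatures: rank-2 spatiotemporal patterns per word,
# one shared across conditions and one condition-specific part, combined
# according to shared_fraction and scaled by word_effect_size (and by
# imagined_scale in the imagined condition).  Drawn once per cohort seed.
draw_signatures <- function(cfg) {
  montage <- standard_montage()
  t <- seq(cfg$window[1], cfg$window[2], by = 1 / cfg$fs_native)
  nc <- nrow(montage)
  one_pattern <- function() {
    m <- matrix(0, nc, length(t))
    for (k in 1:2) {
      u <- stats::rnorm(nc)
      u <- u / sqrt(mean(u^2))
      g <- bump(t, stats::runif(1, 0.08, 0.42), stats::runif(1, 0.08, 0.15),
                3 * sample(c(-1, 1), 1))
      m <- m + outer(u, g)
    }
    m
  }
  with_seed(sub_seed(cfg$seed, "signatures"), {
    sig <- list()
    for (w in cfg$words) {
      shared <- one_pattern()
      sig[[w]] <- list()
      for (cond in study_conditions()) {
        specific <- one_pattern()
        m <- sqrt(cfg$shared_fraction) * shared +
          sqrt(1 - cfg$shared_fraction) * specific
        m <- m * cfg$word_effect_size
        if (cond == "imagined") m <- m * cfg$imagined_scale
        sig[[w]][[cond]] <- m
      }
    }
    sig
  })
}

# deterministic (noise-free) part of an epoch for one subject/condition/word
evoked_epoch <- function(profile, condition, word, cfg,
                         signatures = draw_signatures(cfg)) {
  if (!condition %in% study_conditions())
    stop("unknown condition: ", condition)
  if (!word %in% cfg$words) stop("unknown word: ", word)
  montage <- standard_montage()
  t <- seq(cfg$window[1], cfg$window[2], by = 1 / cfg$fs_native)
  comp <- component_table(cfg)
  x <- matrix(0, nrow(montage), length(t))
  # posterior channels lead frontal ones by ~50 ms
  ap_delay <- 0.05 * (montage$y + 1) / 2
  for (i in seq_len(nrow(comp))) {
    if (comp$overt_only[i] && condition != "overt") next
    w <- topo_weights(comp$topo[i], montage)
    lat <- comp$lat[i] + profile$latency_jitter[i]
    for (ch in seq_len(nrow(montage)))
      x[ch, ] <- x[ch, ] +
        w[ch] * bump(t, lat + ap_delay[ch], comp$width[i], comp$amp[i])
  }
  x <- x + profile$signature_mix * signatures[[word]][[condition]]
  x * profile$gain
}

#' Generate a single synthetic EEG epoch
#'
#' One trial of multi-channel EEG at the native sampling rate over the
#' configured window: evoked components plus the word signature plus 1/f
#' noise.  Artifacts are injected separately by [inject_artifacts()].
#'
#' @param profile a [subject_profile()].
#' @param condition `"overt"` or `"imagined"`.
#' @param word one of `cfg$words`.
#' @param cfg a [sim_config()].
#' @param seed seed for the noise realization.
#' @param signatures cohort word signatures from the internal signature
#'   substream; pass the cached value when generating many epochs.
#' @return A numeric matrix (channels x samples), microvolts.
#' @export
generate_epoch <- function(profile, condition, word, cfg,
                           seed = sub_seed(cfg$seed, "noise"),
                           signatures = draw_signatures(cfg)) {
  ev <- evoked_epoch(profile, condition, word, cfg, signatures)
  noise <- with_seed(seed, t(one_over_f_noise(ncol(ev), nrow(ev),
                                              cfg$fs_native, cfg$noise_alpha,
                                              cfg$noise_sd)))
  ev + noise * profile$gain
}

#' Inject stereotyped artifacts into randomly chosen trials
#'
#' Adds ocular (frontal low-frequency transient), muscle (high-frequency
#' burst on temporal channels) and cardiac (periodic spikes, broad
#' topography) artifacts to a Bernoulli-selected subset of trials.
#'
#' @param es an [epoch_set()].
#' @param rates named per-trial probabilities for `blink`, `emg`, `ecg`.
#' @param seed RNG seed for the injection mask and artifact parameters.
#' @param amps named amplitudes in microvolts.
#' @return A list with `epochs` (the modified set) and `injected`, a named
#'   list of ground-truth trial indices per artifact type.
#' @export
inject_artifacts <- function(es, rates, seed,
                             amps = c(blink = 120, emg = 30, ecg = 8)) {
  stopifnot(all(rates >= 0), all(rates <= 1))
  montage <- standard_montage()
  if (!identical(es$channels$name, montage$name))
    stop("artifact injection requires the reference montage")
  t <- epoch_times(es)
  nt <- n_trials(es)
  blink_topo <- pmax(0, montage$y)^2
  emg_topo <- ifelse(montage$temporal, 1, 0.1)
  ecg_topo <- 0.8 + 0.2 * (montage$y + 1) / 2
  injected <- list(blink = integer(), emg = integer(), ecg = integer())
  with_seed(seed, {
    for (tr in seq_len(nt)) {
      if (stats::runif(1) < rates[["blink"]]) {
        injected$blink <- c(injected$blink, tr)
        c0 <- stats::runif(1, t[1] + 0.2, t[length(t)] - 0.2)
        wave <- bump(t, c0, 0.15, amps[["blink"]])
        es$data[, , tr] <- es$data[, , tr] + outer(blink_topo, wave)
      }
      if (stats::runif(1) < rates[["emg"]]) {
        injected$emg <- c(injected$emg, tr)
        c0 <- stats::runif(1, t[1] + 0.3, t[length(t)] - 0.3)
        env <- exp(-((t - c0) / 0.25)^2)
        hf <- stats::rnorm(length(t))
        hf <- hf - stats::filter(hf, rep(1 / 9, 9), sides = 2,
                                 circular = TRUE) # crude high-pass
        wave <- amps[["emg"]] * env * as.numeric(hf)
        es$data[, , tr] <- es$data[, , tr] + outer(emg_topo, wave)
      }
      if (stats::runif(1) < rates[["ecg"]]) {
        injected$ecg <- c(injected$ecg, tr)
        period <- stats::runif(1, 0.7, 1.1)
        phase <- stats::runif(1, 0, period)
        beats <- seq(t[1] + phase, t[length(t)], by = period)
        wave <- rowSums(vapply(beats, function(b)
          bump(t, b, 0.03, amps[["ecg"]]), numeric(length(t))))
        es$data[, , tr] <- es$data[, , tr] + outer(ecg_topo, wave)
      }
    }
    list(epochs = es, injected = injected)
  })
}

#' Generate a synthetic cohort
#'
#' Runs the full protocol for each subject: draws the subject profile,
#' builds the randomized block schedule, synthesizes every trial at the
#' native sampling rate and injects artifacts at the configured rates.
#'
#' @param cfg a [sim_config()].
#' @return A list of length `n_subjects`; each element has `subject` (id
#'   string), `profile`, `overt` and `imagined` ([epoch_set()]s at
#'   `fs_native`), and `artifacts` (ground-truth injected trial indices
#'   per condition).
#' @export
generate_cohort <- function(cfg) {
  montage <- standard_montage()
  chans <- channel_info(montage$name)
  t <- seq(cfg$window[1], cfg$window[2], by = 1 / cfg$fs_native)
  signatures <- draw_signatures(cfg)
  lapply(seq_len(cfg$n_subjects), function(s) {
    profile <- subject_profile(cfg, s)
    sched <- generate_schedule(
      cfg, seed = sub_seed(if (is.null(cfg$schedule_seed)) cfg$seed
                           else cfg$schedule_seed, "schedule", s))
    # evoked part is deterministic given (condition, word): cache it
    ev_cache <- list()
    out <- list(subject = profile$id, profile = profile,
                artifacts = list())
    for (cond in study_conditions()) {
      rows <- which(sched$condition == cond)
      data <- array(0, c(nrow(montage), length(t), length(rows)))
      for (k in seq_along(rows)) {
        word <- sched$word[rows[k]]
        key <- paste(cond, word)
        if (is.null(ev_cache[[key]]))
          ev_cache[[key]] <- evoked_epoch(profile, cond, word, cfg, signatures)
        noise <- with_seed(
          sub_seed(cfg$seed, paste0("noise_s", s, "_", cond), k),
          t(one_over_f_noise(length(t), nrow(montage), cfg$fs_native,
                             cfg$noise_alpha, cfg$noise_sd)))
        data[, , k] <- ev_cache[[key]] + noise * profile$gain
      }
      labels <- data.frame(subject = profile$id, condition = cond,
                           word = sched$word[rows],
                           stringsAsFactors = FALSE)
      es <- epoch_set(data, cfg$fs_native, cfg$window[1], labels, chans)
      if (any(cfg$artifact_rates > 0)) {
        inj <- inject_artifacts(es, cfg$artifact_rates,
                                seed = sub_seed(cfg$seed, "artifacts",
                                                s * 10L + match(cond, study_conditions())),
                                amps = cfg$artifact_amps)
        es <- inj$epochs
        out$artifacts[[cond]] <- inj$injected
      } else {
        out$artifacts[[cond]] <- list(blink = integer(), emg = integer(),
                                      ecg = integer())
      }
      out[[cond]] <- es
    }
    out
  })
}
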