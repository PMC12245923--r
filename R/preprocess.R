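#' Preprocessing configuration
#'
#' Parameters of the cleaning chain applied to raw epochs, in the fixed
#' order: trim/resample -> band-pass -> channel rejection -> ICA ->
#' trial rejection.
#'
#' @param window analysis window in seconds relative to onset.
#' @param fs_target target sampling rate after polyphase resampling, Hz.
#' @param bp_low,bp_high band-pass edges, Hz.
#' @param filter_order overall Butterworth order (even; the band-pass is
#'   designed from an order `filter_order / 2` low/high prototype).
#' @param p2p_threshold peak-to-peak trial-rejection threshold, microvolts.
#' @param std_threshold standard-deviation trial-rejection threshold,
#'   microvolts; a trial is rejected only when one and the same channel
#'   exceeds both thresholds.
#' @param channel_reject_z robust z-score cutoff on per-channel
#'   log-variance for noisy-channel detection.
#' @param channel_reject_cap maximum channels removed per subject.
#' @param ica_mode `"off"`, `"auto"` (score-based component selection) or
#'   `"manual"` (remove the indices in `ica_components`).
#' @param ica_components 0-based component indices for manual removal.
#' @param ica_max_remove cap on the number of removed components.
#' @param ica_seed seed for the ICA random initialisation.
#' @return A `preproc_config` list.
#' @export
preproc_config <- function(window = c(-1.5, 1.5),
                           fs_target = 256,
                           bp_low = 1, bp_high = 30,
                           filter_order = 8,
                           p2p_threshold = 150,
                           std_threshold = 20,
                           channel_reject_z = 4,
                           channel_reject_cap = 4,
                           ica_mode = c("off", "auto", "manual"),
                           ica_components = NULL,
                           ica_max_remove = 6,
                           ica_seed = 1) {
  ica_mode <- match.arg(ica_mode)
  stopifnot(bp_low < bp_high, bp_high < fs_target / 2,
            p2p_threshold > 0, std_threshold > 0,
            filter_order %% 2 == 0, channel_reject_z > 0)
  structure(list(window = window, fs_target = fs_target,
                 bp_low = bp_low, bp_high = bp_high,
                 filter_order = filter_order,
                 p2p_threshold = p2p_threshold,
                 std_threshold = std_threshold,
                 channel_reject_z = channel_reject_z,
                 channel_reject_cap = channel_reject_cap,
                 ica_mode = ica_mode, ica_components = ica_components,
                 ica_max_remove = ica_max_remove, ica_seed = ica_seed),
            class = "preproc_config")
}

# windowed-sinc resampling operator mapping n_in samples at fs_in starting
# at t0 onto the target grid t_out; rows are normalized to unit DC gain.
resample_matrix <- function(t_in, t_out, fs_in, fs_out, halfwidth = 30) {
  fc <- 0.45 * min(fs_in, fs_out)
  M <- matrix(0, length(t_out), length(t_in))
  for (m in seq_along(t_out)) {
    dt <- t_out[m] - t_in
    u <- dt * fs_in
    w <- which(abs(u) <= halfwidth)
    s <- ifelse(abs(dt[w]) < 1e-15, 1,
                sin(2 * pi * fc * dt[w]) / (2 * pi * fc * dt[w]))
    M[m, w] <- s * 0.5 * (1 + cos(pi * u[w] / halfwidth))
  }
  M / rowSums(M)
}

#' Trim an epoch set to the analysis window and resample
#'
#' Cuts each epoch to `cfg$window` (closed interval: both endpoint samples
#' included, so -1.5..1.5 s at 256 Hz yields 769 samples) and resamples to
#' `cfg$fs_target` with an anti-aliased windowed-sinc polyphase operator.
#' When the sampling rates already match, this is a pure trim and the data
#' on the window are returned unchanged.
#'
#' @param es an [epoch_set()] at the native sampling rate.
#' @param cfg a [preproc_config()].
#' @return An [epoch_set()] at `cfg$fs_target` on `cfg$window`.
#' @export
trim_and_resample <- function(es, cfg) {
  t_nat <- epoch_times(es)
  eps <- 1e-9
  if (cfg$window[1] < t_nat[1] - eps ||
      cfg$window[2] > t_nat[length(t_nat)] + eps)
    stop(sprintf("requested window [%g, %g] outside the recorded span [%g, %g]",
                 cfg$window[1], cfg$window[2], t_nat[1], t_nat[length(t_nat)]))
  if (es$fs < cfg$fs_target)
    stop("native sampling rate below the target rate")
  if (abs(es$fs - cfg$fs_target) < eps)
    return(crop_window(es, cfg$window))
  n_out <- round(diff(cfg$window) * cfg$fs_target) + 1L
  t_out <- cfg$window[1] + (seq_len(n_out) - 1) / cfg$fs_target
  M <- resample_matrix(t_nat, t_out, es$fs, cfg$fs_target)
  nc <- n_channels(es); nt <- n_trials(es)
  flat <- matrix(aperm(es$data, c(1, 3, 2)), nc * nt, n_samples(es))
  y <- flat %*% t(M)
  es$data <- aperm(array(y, c(nc, nt, n_out)), c(1, 3, 2))
  es$fs <- cfg$fs_target
  es$t0_offset <- cfg$window[1]
  es
}

#' Zero-phase Butterworth band-pass
#'
#' Applies the Butterworth band-pass forward and backward
#' (`signal::filtfilt`) so that peak latencies are not shifted.  Each
#' channel/trial is demeaned first (the pass band excludes DC) and
#' reflection-padded to suppress edge transients on the short epochs.
#'
#' @param es an [epoch_set()].
#' @param low,high band edges in Hz.
#' @param order overall filter order (even), default 8.
#' @return The filtered [epoch_set()].
#' @export
bandpass <- function(es, low, high, order = 8) {
  if (!(low < high && high < es$fs / 2))
    stop(sprintf("band [%g, %g] Hz infeasible at fs = %g Hz", low, high, es$fs))
  bf <- signal::butter(order / 2, c(low, high) / (es$fs / 2), type = "pass")
  ns <- n_samples(es)
  np <- min(ns - 1L, as.integer(es$fs)) # ~1 s reflection padding
  pre <- seq(np + 1L, 2L)
  post <- seq(ns - 1L, ns - np)
  for (tr in seq_len(n_trials(es))) {
    for (ch in seq_len(n_channels(es))) {
      x <- es$data[ch, , tr]
      x <- x - mean(x)
      xp <- c(2 * x[1] - x[pre], x, 2 * x[ns] - x[post])
      y <- signal::filtfilt(bf, xp)
      es$data[ch, , tr] <- y[np + seq_len(ns)]
    }
  }
  es
}

#' Detect noisy channels by robust log-variance
#'
#' Computes each channel's log-variance over all samples and trials and
#' flags channels whose robust z-score (median/MAD) exceeds the cutoff.
#' At most `channel_reject_cap` channels are flagged (the worst ones by
#' |z|), mirroring the 0-4 channels removed per participant in practice.
#'
#' @param es an [epoch_set()].
#' @param cfg a [preproc_config()].
#' @return Character vector of channel names to remove (possibly empty).
#' @export
detect_noisy_channels <- function(es, cfg) {
  good <- !es$channels$is_bad
  lv <- log(apply(es$data[good, , , drop = FALSE], 1,
                  function(v) stats::var(as.vector(v))))
  z <- (lv - stats::median(lv)) / max(stats::mad(lv), 1e-12)
  cand <- which(abs(z) > cfg$channel_reject_z)
  if (length(cand) > cfg$channel_reject_cap) {
    warning(sprintf("%d channels exceed the cutoff; keeping the worst %d",
                    length(cand), cfg$channel_reject_cap))
    cand <- cand[order(abs(z[cand]), decreasing = TRUE)][seq_len(cfg$channel_reject_cap)]
  }
  names_good <- es$channels$name[good]
  flagged <- names_good[cand]
  if (sum(good) - length(flagged) < 8L)
    stop("fewer than 8 good channels would remain after rejection")
  flagged
}

#' Drop bad channels from an epoch set
#' @param es an [epoch_set()].
#' @param names channel names to remove.
#' @return The reduced [epoch_set()].
#' @export
drop_channels <- function(es, names) {
  if (length(names) == 0L) return(es)
  keep <- !(es$channels$name %in% names)
  es$data <- es$data[keep, , , drop = FALSE]
  es$channels <- channel_info(es$channels$name[keep],
                              es$channels$is_bad[keep])
  es
}

#' Reject noisy trials by peak-to-peak and standard-deviation thresholds
#'
#' A trial is rejected if and only if at least one channel exceeds the
#' peak-to-peak threshold *and* the standard-deviation threshold on that
#' same channel.  Raising either threshold can only keep more trials.
#'
#' @param es an [epoch_set()].
#' @param cfg a [preproc_config()].
#' @return A list with `epochs` (surviving trials, labels re-aligned) and
#'   `rejected` (1-based indices of rejected trials).
#' @export
reject_noisy_trials <- function(es, cfg) {
  nt <- n_trials(es)
  bad <- logical(nt)
  for (tr in seq_len(nt)) {
    x <- es$data[, , tr, drop = FALSE][, , 1]
    p2p <- apply(x, 1, function(v) max(v) - min(v))
    sds <- apply(x, 1, stats::sd)
    bad[tr] <- any(p2p > cfg$p2p_threshold & sds > cfg$std_threshold)
  }
  if (all(bad)) stop("all trials rejected; thresholds too strict for these data")
  list(epochs = subset_trials(es, !bad), rejected = which(bad))
}

#' Baseline-correct each epoch
#'
#' Subtracts, per trial and channel, the mean over the pre-stimulus
#' baseline window.
#'
#' @param es an [epoch_set()].
#' @param window baseline window in seconds, default -0.4..-0.1 s.
#' @return The corrected [epoch_set()].
#' @export
baseline_correct <- function(es, window = c(-0.4, -0.1)) {
  idx <- window_indices(epoch_times(es), window)
  if (length(idx) == 0L) stop("baseline window outside the epoch")
  bl <- apply(es$data[, idx, , drop = FALSE], c(1, 3), mean)
  es$data <- es$data - aperm(array(bl, c(dim(bl), n_samples(es))), c(1, 3, 2))
  es
}

#' Preprocess both conditions of one subject with a shared montage
#'
#' Runs the cleaning chain on the subject's overt and imagined epoch
#' sets with noisy-channel detection performed **jointly** across the two
#' conditions, so that both conditions keep an identical channel set (a
#' requirement for mixed-condition training sets and cross-condition
#' evaluation).
#'
#' @param subject list with `subject` (id) and `overt`/`imagined`
#'   [epoch_set()]s at the native rate.
#' @param cfg a [preproc_config()].
#' @return The subject list with cleaned epoch sets and a `report` entry.
#' @export
preprocess_subject <- function(subject, cfg = preproc_config()) {
  conds <- intersect(study_conditions(), names(subject))
  filtered <- lapply(subject[conds], function(es)
    bandpass(trim_and_resample(es, cfg), cfg$bp_low, cfg$bp_high,
             cfg$filter_order))
  bad <- detect_noisy_channels(bind_trials(filtered), cfg)
  out <- list(subject = subject$subject)
  report <- list(channels_removed = bad)
  for (cond in conds) {
    es <- drop_channels(filtered[[cond]], bad)
    ica_removed <- integer()
    if (cfg$ica_mode != "off") {
      ica <- remove_artifact_components(es, cfg)
      es <- ica$epochs
      ica_removed <- ica$removed
    }
    rej <- reject_noisy_trials(es, cfg)
    out[[cond]] <- rej$epochs
    report[[cond]] <- list(ica_components_removed = ica_removed,
                           trials_rejected = rej$rejected)
  }
  out$report <- report
  out
}

#' Run the full preprocessing chain
#'
#' Applies, in this fixed order: trim/resample, band-pass, noisy-channel
#' rejection, ICA artifact removal (if enabled) and statistical trial
#' rejection.  The order is recorded in the returned report.
#'
#' @param es an [epoch_set()] at the native sampling rate.
#' @param cfg a [preproc_config()].
#' @return A list with `epochs` (the cleaned set) and `report` (channels
#'   removed, ICA components removed, trials rejected, stage order).
#' @export
preprocess_epochs <- function(es, cfg = preproc_config()) {
  es <- trim_and_resample(es, cfg)
  es <- bandpass(es, cfg$bp_low, cfg$bp_high, cfg$filter_order)
  bad <- detect_noisy_channels(es, cfg)
  es <- drop_channels(es, bad)
  ica_removed <- integer()
  if (cfg$ica_mode != "off") {
    ica <- remove_artifact_components(es, cfg)
    es <- ica$epochs
    ica_removed <- ica$removed
  }
  rej <- reject_noisy_trials(es, cfg)
  list(epochs = rej$epochs,
       report = list(order = c("trim_resample", "bandpass",
                               "channel_rejection", "ica", "trial_rejection"),
                     channels_removed = bad,
                     ica_components_removed = ica_removed,
                     trials_rejected = rej$rejected))
}
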