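# small programmatic fixtures shared across the test files

# minimal epoch set with arbitrary data and consistent labels
make_tiny_es <- function(n_chan = 2, n_samp = 10, n_trial = 4, fs = 256,
                         t0 = -0.5, words = NULL, condition = "imagined",
                         data = NULL, seed = 1) {
  if (is.null(words)) words <- rep_len(study_words(), n_trial)
  if (is.null(data))
    data <- with_seed(seed, array(rnorm(n_chan * n_samp * n_trial),
                                  c(n_chan, n_samp, n_trial)))
  labels <- data.frame(subject = "S01", condition = condition, word = words,
                       stringsAsFactors = FALSE)
  epoch_set(data, fs, t0, labels)
}

# epoch set on the full 32-channel montage
make_montage_es <- function(n_samp = 769, n_trial = 5, fs = 256, t0 = -1.5,
                            sd = 1, seed = 1) {
  m <- standard_montage()
  with_seed(seed, {
    data <- array(rnorm(32 * n_samp * n_trial, sd = sd),
                  c(32, n_samp, n_trial))
    labels <- data.frame(subject = "S01", condition = "imagined",
                         word = rep_len(study_words(), n_trial),
                         stringsAsFactors = FALSE)
    epoch_set(data, fs, t0, labels, channel_info(m$name))
  })
}

# fabricated task-filtered subject entry for assemble_training_set tests:
# tiny trials, n_per_word trials per word and condition
make_fake_subject <- function(id = "S01", n_per_word = 40,
                              words = study_words(), n_chan = 2, n_samp = 5) {
  out <- list(subject = id)
  for (cond in study_conditions()) {
    n <- n_per_word * length(words)
    data <- array(rnorm(n_chan * n_samp * n), c(n_chan, n_samp, n))
    labels <- data.frame(subject = id, condition = cond,
                         word = rep(words, each = n_per_word),
                         stringsAsFactors = FALSE)
    es <- epoch_set(data, 256, 0, labels)
    es$labels$uid <- sprintf("%s_%s_%04d", id, cond, seq_len(n))
    out[[cond]] <- es
    out[[paste0("labels_", cond)]] <- labels$word
  }
  out
}

# fast low-rate simulation config: epochs generated directly at the
# analysis rate over a short window so classification tests stay cheap
fast_sim_cfg <- function(window = c(-0.6, 0.6), trials_per_block = 25,
                         n_blocks_per_condition = 1, ...) {
  sim_config(fs_native = 256, window = window,
             n_blocks_per_condition = n_blocks_per_condition,
             trials_per_block = trials_per_block,
             artifact_rates = c(blink = 0, emg = 0, ecg = 0), ...)
}

# small model config used wherever a real fit is needed
fast_model_cfg <- function(epochs = 50, ...) {
  model_config(epochs = epochs, patience = epochs + 10, val_fraction = 0,
               batch_size = 16, ...)
}
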