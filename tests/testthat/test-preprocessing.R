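test_that("trim and resample hit the analysis grid exactly", {
  cfg <- preproc_config()
  # 3 s native epoch at 1200 Hz -> 769 samples at 256 Hz
  n_nat <- 3601
  t_nat <- -1.5 + (0:(n_nat - 1)) / 1200
  es <- make_tiny_es(n_chan = 2, n_samp = n_nat, n_trial = 3, fs = 1200,
                     t0 = -1.5, words = c("si", "no", "agua"))
  out <- trim_and_resample(es, cfg)
  expect_equal(n_samples(out), 769)
  expect_equal(out$fs, 256)
  expect_equal(out$t0_offset, -1.5)
  # identity when rates already match: pure trim
  es256 <- make_tiny_es(n_samp = 769, fs = 256, t0 = -1.5, n_trial = 2,
                        words = c("si", "no"))
  out2 <- trim_and_resample(es256, cfg)
  expect_identical(out2$data, es256$data)
  expect_error(trim_and_resample(es256, preproc_config(window = c(-2, 2))),
               "outside the recorded span")
})

test_that("resampling preserves in-band sinusoids to within 1%", {
  t_nat <- -1.5 + (0:3600) / 1200
  x <- sin(2 * pi * 10 * t_nat)
  es <- make_tiny_es(n_chan = 1, n_samp = 3601, n_trial = 1, fs = 1200,
                     t0 = -1.5, words = "si",
                     data = array(x, c(1, 3601, 1)))
  out <- trim_and_resample(es, preproc_config())
  t_out <- epoch_times(out)
  mid <- t_out > -1.3 & t_out < 1.3   # away from the epoch edges
  err <- max(abs(out$data[1, mid, 1] - sin(2 * pi * 10 * t_out[mid])))
  expect_lt(err, 0.01)
})

test_that("band-pass removes DC and attenuates out-of-band tones", {
  t <- (0:768) / 256
  dc <- array(5, c(1, 769, 1))
  es <- make_tiny_es(n_chan = 1, n_samp = 769, n_trial = 1, fs = 256,
                     t0 = 0, words = "si", data = dc)
  out <- bandpass(es, 1, 30, 8)
  expect_lt(max(abs(out$data)), 5e-6 * 5)
  # 50 Hz tone through 1-30 Hz: >= 20 dB down (frequency-response oracle)
  bf <- signal::butter(4, c(1, 30) / 128, type = "pass")
  H50 <- abs(signal::freqz(bf$b, bf$a, n = 2 * pi * 50 / 256,
                           Fs = 2 * pi)$h)^2 # |H|^2: filter applied twice
  expect_lt(20 * log10(H50), -20)
  es50 <- make_tiny_es(n_chan = 1, n_samp = 769, n_trial = 1, fs = 256,
                       t0 = 0, words = "si",
                       data = array(sin(2 * pi * 50 * t), c(1, 769, 1)))
  out50 <- bandpass(es50, 1, 30, 8)
  mid <- 200:569
  expect_lt(max(abs(out50$data[1, mid, 1])), 10^(-20 / 20))
  # 10 Hz through the 4-20 Hz ERP band: passband gain within 1 dB of unity
  es10 <- make_tiny_es(n_chan = 1, n_samp = 769, n_trial = 1, fs = 256,
                       t0 = 0, words = "si",
                       data = array(sin(2 * pi * 10 * t), c(1, 769, 1)))
  out10 <- bandpass(es10, 4, 20, 8)
  gain <- max(abs(out10$data[1, mid, 1]))
  expect_lt(abs(20 * log10(gain)), 1)
  expect_error(bandpass(es10, 4, 200), "infeasible")
})

test_that("noisy-channel detection follows the robust z-score rule", {
  es <- make_montage_es(n_samp = 200, n_trial = 4, sd = 1, seed = 2)
  # equal-variance channels: nothing flagged
  expect_length(detect_noisy_channels(es, preproc_config()), 0)
  # one channel at 100x variance: exactly that channel
  es2 <- es
  es2$data[7, , ] <- es2$data[7, , ] * 10
  expect_identical(detect_noisy_channels(es2, preproc_config()),
                   es$channels$name[7])
  # two gross + one borderline channel vs the median/MAD oracle
  es3 <- es
  es3$data[3, , ] <- es3$data[3, , ] * 12
  es3$data[20, , ] <- es3$data[20, , ] * 15
  es3$data[30, , ] <- es3$data[30, , ] * 1.05
  lv <- log(apply(es3$data, 1, function(v) var(as.vector(v))))
  z <- (lv - median(lv)) / mad(lv)
  oracle <- es3$channels$name[abs(z) > 4]
  got <- detect_noisy_channels(es3, preproc_config())
  expect_setequal(got, oracle)
  expect_setequal(got, es$channels$name[c(3, 20)])
})

test_that("channel rejection is capped and keeps at least 8 good channels", {
  es <- make_montage_es(n_samp = 100, n_trial = 3, sd = 1, seed = 3)
  es$data[1:6, , ] <- es$data[1:6, , ] * 100
  expect_warning(got <- detect_noisy_channels(es, preproc_config()),
                 "keeping the worst 4")
  expect_length(got, 4)
})

test_that("trial rejection requires both thresholds on the same channel", {
  cfg <- preproc_config()
  base <- array(0, c(2, 769, 3))
  t <- (0:768) / 256
  # trial 1: one channel p2p 160, sd ~ 56 -> rejected
  base[1, , 1] <- 80 * sin(2 * pi * 5 * t)
  # trial 2: p2p 160 via brief spike but tiny sd -> kept
  base[1, 100:102, 2] <- c(80, -80, 80)
  # trial 3: all zero -> kept
  es <- make_tiny_es(n_chan = 2, n_samp = 769, n_trial = 3, fs = 256,
                     t0 = -1.5, words = c("si", "no", "agua"), data = base)
  out <- reject_noisy_trials(es, cfg)
  expect_identical(out$rejected, 1L)
  expect_equal(n_trials(out$epochs), 2)
  expect_identical(out$epochs$labels$word, c("no", "agua"))
  # spike trial really is below the sd threshold
  expect_lt(sd(base[1, , 2]), 20)
  expect_gt(max(base[1, , 2]) - min(base[1, , 2]), 150)
})

test_that("trial rejection is monotone in both thresholds", {
  es <- make_montage_es(n_samp = 300, n_trial = 30, sd = 1, seed = 5)
  # graded per-trial amplitudes so some trials straddle the thresholds
  scales <- seq(5, 35, length.out = 30)
  for (tr in 1:30) es$data[, , tr] <- es$data[, , tr] * scales[tr]
  cfg1 <- preproc_config(p2p_threshold = 150, std_threshold = 20)
  r1 <- reject_noisy_trials(es, cfg1)$rejected
  for (cfg2 in list(preproc_config(p2p_threshold = 200, std_threshold = 20),
                    preproc_config(p2p_threshold = 150, std_threshold = 35))) {
    r2 <- reject_noisy_trials(es, cfg2)$rejected
    expect_true(all(r2 %in% r1))
  }
  expect_error(reject_noisy_trials(
    es, preproc_config(p2p_threshold = 1e-4, std_threshold = 1e-4)),
    "all trials rejected")
})

test_that("baseline correction zeroes the baseline mean and is idempotent", {
  es <- make_tiny_es(n_chan = 2, n_samp = 769, n_trial = 4, fs = 256,
                     t0 = -1.5, words = rep(c("si", "no"), 2))
  orig <- es
  es$data <- es$data + 5  # constant offset
  bc <- baseline_correct(es)
  idx <- imspeech:::window_indices(epoch_times(bc), c(-0.4, -0.1))
  bl_means <- apply(bc$data[, idx, , drop = FALSE], c(1, 3), mean)
  expect_lt(max(abs(bl_means)), 1e-9)
  # add-then-correct recovers the corrected original
  expect_equal(bc$data, baseline_correct(orig)$data, tolerance = 1e-9)
  # idempotence
  expect_equal(baseline_correct(bc)$data, bc$data, tolerance = 1e-12)
  expect_error(baseline_correct(es, c(-3, -2.5)), "outside")
})

test_that("ICA isolates one source of a noiseless two-source mixture", {
  n <- 4000
  t <- (0:(n - 1)) / 256
  s1 <- sin(2 * pi * 7 * t)
  s2 <- with_seed(2, sign(sin(2 * pi * 3 * t + 1)) * runif(n, 0.8, 1))
  A <- matrix(c(1.0, 0.4, -0.3, 0.9), 2, 2)
  X <- A %*% rbind(s1, s2)
  es <- make_tiny_es(n_chan = 2, n_samp = n, n_trial = 1, fs = 256,
                     t0 = 0, words = "si",
                     data = array(X, c(2, n, 1)))
  cfg <- preproc_config(ica_mode = "manual", ica_components = 0L)
  out <- remove_artifact_components(es, cfg)
  recon <- out$epochs$data[, , 1]
  # the reconstruction must equal one single source's contribution
  c1 <- A[, 1, drop = FALSE] %*% rbind(s1)
  c2 <- A[, 2, drop = FALSE] %*% rbind(s2)
  err <- min(max(abs(recon - c1)), max(abs(recon - c2)))
  # fastICA separation is exact only asymptotically; 3% of the signal
  # range at n = 4000 samples
  expect_lt(err, 0.03 * max(abs(X)))
  expect_error(remove_artifact_components(
    es, preproc_config(ica_mode = "manual", ica_components = 5L)),
    "out of range")
  ident <- remove_artifact_components(es, preproc_config(ica_mode = "off"))
  expect_identical(ident$epochs$data, es$data)
})

test_that("automatic ICA removes most of an injected blink", {
  es <- make_montage_es(n_samp = 769, n_trial = 12, sd = 2, seed = 11)
  blink_idx <- c(2, 5, 9, 11)
  montage <- standard_montage()
  topo <- pmax(0, montage$y)^2
  t <- epoch_times(es)
  blink_energy <- function(data) {
    e <- 0
    for (tr in blink_idx) {
      wave <- imspeech:::bump(t, 0.2, 0.15, 1)
      e <- e + sum((data[, , tr] %*% wave)^2)
    }
    e
  }
  dirty <- es
  for (tr in blink_idx)
    dirty$data[, , tr] <- dirty$data[, , tr] +
      outer(topo, imspeech:::bump(t, 0.2, 0.15, 80))
  cfg <- preproc_config(ica_mode = "auto")
  out <- remove_artifact_components(dirty, cfg)
  expect_gt(length(out$removed), 0)
  expect_lte(length(out$removed), cfg$ica_max_remove)
  before <- blink_energy(dirty$data)
  after <- blink_energy(out$epochs$data)
  expect_lt(after, 0.2 * before)
})

test_that("the full chain runs in the declared order and keeps alignment", {
  cfg <- sim_config(n_subjects = 1, n_blocks_per_condition = 1,
                    trials_per_block = 10, seed = 17,
                    artifact_rates = c(blink = 0.3, emg = 0.2, ecg = 0.1))
  coh <- generate_cohort(cfg)
  pp <- preprocess_epochs(coh[[1]]$overt, preproc_config())
  expect_identical(pp$report$order,
                   c("trim_resample", "bandpass", "channel_rejection",
                     "ica", "trial_rejection"))
  es <- pp$epochs
  expect_equal(n_samples(es), 769)
  expect_equal(n_trials(es) + length(pp$report$trials_rejected), 10)
  expect_equal(nrow(es$labels), n_trials(es))
})
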