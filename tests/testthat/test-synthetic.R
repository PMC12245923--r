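test_that("default schedule reproduces the protocol counts", {
  cfg <- sim_config()
  sched <- generate_schedule(cfg)
  expect_equal(nrow(sched), 400)
  tab <- table(sched$condition)
  expect_equal(unname(tab[study_conditions()]), c(200L, 200L),
               ignore_attr = TRUE)
  per_word <- table(sched$condition, sched$word)
  expect_true(all(per_word == 40))
  # blocks are homogeneous in condition
  expect_true(all(tapply(sched$condition, sched$block,
                         function(x) length(unique(x))) == 1))
})

test_that("schedule scales with block settings and rejects bad counts", {
  cfg <- sim_config(n_blocks_per_condition = 1, trials_per_block = 5)
  sched <- generate_schedule(cfg)
  expect_equal(sum(sched$condition == "overt"), 5)
  expect_equal(unname(table(sched$word[sched$condition == "imagined"])),
               rep(1L, 5), ignore_attr = TRUE)
  expect_error(generate_schedule(sim_config(trials_per_block = 7)),
               "not divisible")
})

test_that("schedule seed substream is independent of the noise stream", {
  cfg1 <- sim_config(seed = 1, schedule_seed = 99, n_subjects = 1,
                     n_blocks_per_condition = 1, trials_per_block = 10)
  cfg2 <- sim_config(seed = 2, schedule_seed = 99, n_subjects = 1,
                     n_blocks_per_condition = 1, trials_per_block = 10)
  expect_identical(generate_schedule(cfg1), generate_schedule(cfg2))
  coh1 <- generate_cohort(fast_sim_cfg(n_subjects = 1, seed = 1,
                                       schedule_seed = 99,
                                       trials_per_block = 5))
  coh2 <- generate_cohort(fast_sim_cfg(n_subjects = 1, seed = 2,
                                       schedule_seed = 99,
                                       trials_per_block = 5))
  expect_identical(coh1[[1]]$imagined$labels$word,
                   coh2[[1]]$imagined$labels$word)
  expect_false(identical(coh1[[1]]$imagined$data, coh2[[1]]$imagined$data))
})

test_that("zero word effect removes all class information from the evoked part", {
  cfg <- fast_sim_cfg(word_effect_size = 0, seed = 5)
  profile <- subject_profile(cfg, 1)
  sig <- imspeech:::draw_signatures(cfg)
  ev_si <- imspeech:::evoked_epoch(profile, "imagined", "si", cfg, sig)
  ev_no <- imspeech:::evoked_epoch(profile, "imagined", "no", cfg, sig)
  expect_equal(ev_si, ev_no)
})

test_that("with fully shared signatures at equal SNR the conditions differ only late", {
  cfg <- fast_sim_cfg(shared_fraction = 1, imagined_scale = 1,
                      window = c(-0.6, 1.0), seed = 7)
  profile <- subject_profile(cfg, 1)
  sig <- imspeech:::draw_signatures(cfg)
  t <- seq(cfg$window[1], cfg$window[2], by = 1 / cfg$fs_native)
  d <- abs(imspeech:::evoked_epoch(profile, "overt", "agua", cfg, sig) -
             imspeech:::evoked_epoch(profile, "imagined", "agua", cfg, sig))
  expect_equal(max(d[, t < 0.5]), 0)
  expect_gt(max(d[, t > 0.55 & t < 0.9]), 0.5)
})

test_that("posterior channels lead frontal channels by about 50 ms", {
  cfg <- sim_config(word_effect_size = 0, subject_gain_sd = 0,
                    latency_jitter_sd = 0)
  profile <- subject_profile(cfg, 1)
  sig <- imspeech:::draw_signatures(cfg)
  ev <- imspeech:::evoked_epoch(profile, "imagined", "si", cfg, sig)
  t <- seq(cfg$window[1], cfg$window[2], by = 1 / cfg$fs_native)
  m <- standard_montage()
  # first P100-window peak per channel
  win <- t > 0 & t < 0.25
  oz_peak <- t[win][which.max(ev[m$name == "Oz", win])]
  fp_peak <- t[win][which.max(ev[m$name == "Fp1", win])]
  expect_gt(fp_peak - oz_peak, 0.03)
  expect_lt(fp_peak - oz_peak, 0.07)
})

test_that("single epochs are reproducible under a fixed seed", {
  cfg <- fast_sim_cfg(seed = 3)
  profile <- subject_profile(cfg, 1)
  sig <- imspeech:::draw_signatures(cfg)
  e1 <- generate_epoch(profile, "overt", "agua", cfg, seed = 42,
                       signatures = sig)
  e2 <- generate_epoch(profile, "overt", "agua", cfg, seed = 42,
                       signatures = sig)
  expect_identical(e1, e2)
  e3 <- generate_epoch(profile, "overt", "agua", cfg, seed = 43,
                       signatures = sig)
  expect_false(identical(e1, e3))
  expect_error(generate_epoch(profile, "overt", "water", cfg,
                              signatures = sig), "unknown word")
})

test_that("cohort generation fills the protocol structure", {
  cfg <- fast_sim_cfg(n_subjects = 2, trials_per_block = 10, seed = 9)
  coh <- generate_cohort(cfg)
  expect_length(coh, 2)
  for (s in coh) {
    expect_equal(n_trials(s$overt), 10)
    expect_equal(n_trials(s$imagined), 10)
    expect_true(all(s$imagined$labels$condition == "imagined"))
    expect_equal(n_channels(s$overt), 32)
  }
  expect_false(identical(coh[[1]]$overt$data, coh[[2]]$overt$data))
})

test_that("artifact injection is seeded, bounded and optional", {
  es <- make_montage_es(n_samp = 400, n_trial = 20, sd = 5)
  none <- inject_artifacts(es, c(blink = 0, emg = 0, ecg = 0), seed = 1)
  expect_identical(none$epochs$data, es$data)
  expect_length(none$injected$blink, 0)
  a1 <- inject_artifacts(es, c(blink = 0.5, emg = 0.3, ecg = 0.2), seed = 4)
  a2 <- inject_artifacts(es, c(blink = 0.5, emg = 0.3, ecg = 0.2), seed = 4)
  expect_identical(a1$injected, a2$injected)
  expect_identical(a1$epochs$data, a2$epochs$data)
  expect_gt(length(a1$injected$blink), 0)
  # untouched trials stay bit-identical
  touched <- unique(unlist(a1$injected))
  keep <- setdiff(seq_len(20), touched)
  expect_identical(a1$epochs$data[, , keep], es$data[, , keep])
})

test_that("large injected blinks are caught by trial rejection downstream", {
  cfg <- sim_config(n_subjects = 1, n_blocks_per_condition = 1,
                    trials_per_block = 20, word_effect_size = 0,
                    artifact_rates = c(blink = 0, emg = 0, ecg = 0),
                    seed = 13)
  coh <- generate_cohort(cfg)
  inj <- inject_artifacts(coh[[1]]$imagined,
                          c(blink = 0.4, emg = 0, ecg = 0), seed = 8,
                          amps = c(blink = 300, emg = 30, ecg = 8))
  expect_gt(length(inj$injected$blink), 1)
  pcfg <- preproc_config()
  es <- bandpass(trim_and_resample(inj$epochs, pcfg), pcfg$bp_low,
                 pcfg$bp_high, pcfg$filter_order)
  rej <- reject_noisy_trials(es, pcfg)
  expect_true(all(inj$injected$blink %in% rej$rejected))
})

test_that("classification accuracy grows with the word effect size", {
  grid <- c(0, 1, 2)
  seeds <- 1:5
  task <- task_spec("word_pair", c("si", "comida"))
  mean_acc <- vapply(grid, function(effect) {
    accs <- vapply(seeds, function(sd) {
      coh <- generate_cohort(fast_sim_cfg(n_subjects = 1,
                                          word_effect_size = effect,
                                          seed = 1000 + sd))
      r <- run_scenario(scenario_spec("intra_imagined", task, seed = sd),
                        list(list(subject = coh[[1]]$subject,
                                  imagined = coh[[1]]$imagined)),
                        1, fast_model_cfg())
      r$accuracy_mean
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  # monotone trend up to fold noise; the null level must be clearly beaten
  expect_true(all(diff(mean_acc) > -5))
  expect_gt(mean_acc[3], mean_acc[1] + 15)
})
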