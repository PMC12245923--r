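test_that("stratified folds are mutually exclusive, exhaustive and balanced", {
  labels <- rep(study_words(), each = 40)   # 200 imagined trials
  folds <- make_folds(labels, 5, seed = 1)
  test_sizes <- lengths(folds$test)
  expect_equal(test_sizes, rep(40L, 5))     # 40 test / 160 train per fold
  all_idx <- sort(unlist(folds$test))
  expect_identical(all_idx, seq_along(labels))  # exhaustive, no overlap
  for (k in 1:5)
    expect_equal(unname(table(labels[folds$test[[k]]])), rep(8L, 5),
                 ignore_attr = TRUE)         # class-stratified
  # two-class case: 80 trials -> folds of 16 (8 + 8)
  lab2 <- rep(c("si", "no"), each = 40)
  f2 <- make_folds(lab2, 5, seed = 2)
  expect_equal(lengths(f2$test), rep(16L, 5))
  for (k in 1:5)
    expect_equal(unname(table(lab2[f2$test[[k]]])), c(8L, 8L),
                 ignore_attr = TRUE)
  # different seeds give different partitions of the same sizes
  f3 <- make_folds(lab2, 5, seed = 3)
  expect_false(identical(f2$test, f3$test))
  expect_equal(lengths(f3$test), lengths(f2$test))
  expect_error(make_folds(rep(c("a", "b"), c(4, 40)), 5), "at least 5")
})

test_that("scenario compositions reproduce the published trial arithmetic", {
  target <- make_fake_subject("S01", n_per_word = 40)
  others <- lapply(sprintf("S%02d", 2:24), make_fake_subject,
                   n_per_word = 40)
  folds <- make_folds(target$labels_imagined, 5, seed = 1)

  # imagined-only: 160 train / 40 test
  spec <- scenario_spec("intra_imagined", task_spec("all_words"))
  a <- assemble_training_set(spec, 1, folds, target)
  expect_equal(n_trials(a$train), 160)
  expect_equal(n_trials(a$test), 40)

  # mixed: 80% imagined + 100% overt = 360 train / 40 test
  spec <- scenario_spec("intra_mixed", task_spec("all_words"))
  a <- assemble_training_set(spec, 1, folds, target)
  expect_equal(n_trials(a$train), 360)
  expect_equal(n_trials(a$test), 40)

  # overt-only: 200 train / 200 test, single evaluation
  spec <- scenario_spec("intra_overt", task_spec("all_words"))
  a <- assemble_training_set(spec, 1, folds, target)
  expect_equal(n_trials(a$train), 200)
  expect_equal(n_trials(a$test), 200)

  # multi-subject augmentation with 24 subjects: 160 + 23*200 = 4760
  spec <- scenario_spec("multi_overt_augmented", task_spec("all_words"))
  a <- assemble_training_set(spec, 1, folds, target, others)
  expect_equal(n_trials(a$train), 160 + 23 * 200)
  expect_equal(n_trials(a$test), 40)

  # missing overt data is a hard error for scenarios that need it
  no_overt <- target; no_overt$overt <- NULL
  expect_error(assemble_training_set(
    scenario_spec("intra_mixed", task_spec("all_words")), 1, folds,
    no_overt), "requires overt")
})

test_that("train and test trials never overlap in any fold of any scenario", {
  target <- make_fake_subject("S01", n_per_word = 10)
  others <- list(make_fake_subject("S02", n_per_word = 10))
  folds <- make_folds(target$labels_imagined, 5, seed = 7)
  for (sid in c("intra_imagined", "intra_mixed", "intra_overt",
                "multi_overt_augmented")) {
    spec <- scenario_spec(sid, task_spec("all_words"))
    n_runs <- if (sid == "intra_overt") 1 else 5
    for (k in seq_len(n_runs)) {
      a <- assemble_training_set(spec, k, folds, target, others)
      expect_length(intersect(a$train$labels$uid, a$test$labels$uid), 0)
    }
  }
})

test_that("word-pair filtering keeps exactly the two requested words", {
  target <- make_fake_subject("S01", n_per_word = 40)
  es <- target$imagined
  ft <- imspeech:::apply_task(es, task_spec("word_pair", c("si", "no")))
  expect_equal(n_trials(ft$es), 80)
  expect_setequal(unique(ft$labels), c("si", "no"))
  # short vs long: {si,no} vs {agua,dormir}, comida excluded, 80 per class
  fl <- imspeech:::apply_task(es, task_spec("short_vs_long"))
  expect_equal(n_trials(fl$es), 160)
  expect_equal(unname(table(fl$labels)), c(80L, 80L), ignore_attr = TRUE)
  expect_false("comida" %in% fl$es$labels$word)
  expect_equal(sum(fl$labels == "short"), 80)
  expect_error(task_spec("word_pair", c("si", "si")), "distinct")
  expect_length(all_word_pairs(), 10)
})

test_that("z-score normalization follows the train-fit contract", {
  mk <- function(mean, sd, n = 30) {
    data <- with_seed(n, array(rnorm(3 * 20 * n, mean, sd), c(3, 20, n)))
    make_tiny_es(n_chan = 3, n_samp = 20, n_trial = n, fs = 256, t0 = 0,
                 data = data)
  }
  train_im <- mk(5, 2); train_ov <- mk(-3, 7); test <- mk(1, 2, 10)
  z <- zscore_normalize(train_im, train_ov, test)
  for (ch in 1:3) {
    expect_lt(abs(mean(z$train_im$data[ch, , ])), 1e-9)
    expect_lt(abs(sd(as.vector(z$train_im$data[ch, , ])) - 1), 1e-6)
    # overt standardized with its own parameters
    expect_lt(abs(mean(z$train_ov$data[ch, , ])), 1e-9)
  }
  # test transformed with the imagined-train parameters: not zero-mean
  expect_gt(abs(mean(z$test$data)), 0.5)
  # re-applying with refit is a no-op beyond numerical noise
  z2 <- zscore_normalize(z$train_im, z$train_ov, z$train_im)
  expect_lt(max(abs(z2$train_im$data - z$train_im$data)), 1e-9)
  # zero-variance channel: sd floored with a warning
  flat <- mk(0, 1, 5); flat$data[2, , ] <- 3
  expect_warning(zscore_normalize(flat, NULL, flat), "floored")
})

test_that("run_all tabulates subjects x scenarios x tasks with reproducible output", {
  cfg <- fast_sim_cfg(n_subjects = 2, word_effect_size = 1.5, seed = 33)
  coh <- lapply(generate_cohort(cfg), function(s)
    list(subject = s$subject, overt = s$overt, imagined = s$imagined))
  mcfg <- fast_model_cfg(epochs = 10)
  tasks <- list(task_spec("word_pair", c("si", "comida")))
  res <- run_all(coh, scenario_ids = c("intra_imagined", "intra_overt"),
                 tasks = tasks, model_cfg = mcfg, seed = 5)
  # 2 subjects x (5 folds + 1 single evaluation)
  expect_equal(nrow(res), 2 * 6)
  expect_setequal(unique(res$scenario), c("intra_imagined", "intra_overt"))
  expect_true(all(!is.na(res$accuracy)))
  expect_true(all(res$n_test[res$scenario == "intra_overt"] == 10))
  res2 <- run_all(coh, scenario_ids = c("intra_imagined", "intra_overt"),
                  tasks = tasks, model_cfg = mcfg, seed = 5)
  expect_identical(res, res2)
  # partial failure is recorded, not fatal: drop overt data
  coh_im <- lapply(coh, function(s) s[c("subject", "imagined")])
  res3 <- run_all(coh_im, scenario_ids = c("intra_imagined", "intra_mixed"),
                  tasks = tasks, model_cfg = mcfg, seed = 5)
  bad <- res3[res3$scenario == "intra_mixed", ]
  expect_true(all(is.na(bad$accuracy)))
  expect_match(bad$error[1], "requires overt")
  expect_true(all(!is.na(res3$accuracy[res3$scenario == "intra_imagined"])))
})

test_that("experimental multi-subject variants are gated", {
  expect_error(scenario_spec("multi_imagined_augmented"), "experimental")
  spec <- scenario_spec("multi_imagined_augmented", experimental = TRUE)
  expect_s3_class(spec, "scenario_spec")
})
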