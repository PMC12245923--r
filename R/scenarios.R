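#' Classification task definitions
#'
#' The three task types evaluated within every training scenario:
#' `word_pair` (one of the ten unordered pairs of the five words),
#' `short_vs_long` (one-syllable "si"/"no" versus two-syllable
#' "agua"/"dormir"; "comida" is excluded) and `all_words` (five-class).
#'
#' @param type task type.
#' @param words for `word_pair`, the two words to discriminate.
#' @return A `task_spec` list with a `name` suitable for result tables.
#' @export
task_spec <- function(type = c("word_pair", "short_vs_long", "all_words"),
                      words = NULL) {
  type <- match.arg(type)
  if (type == "word_pair") {
    if (is.null(words) || length(words) != 2L ||
        !all(words %in% study_words()) || words[1] == words[2])
      stop("word_pair requires two distinct study words")
    name <- paste0("word_pair:", words[1], "-", words[2])
  } else name <- type
  structure(list(type = type, words = words, name = name),
            class = "task_spec")
}

#' All ten unordered word pairs
#' @return A list of ten `word_pair` [task_spec()]s.
#' @export
all_word_pairs <- function() {
  w <- study_words()
  out <- list()
  for (i in 1:4) for (j in (i + 1):5)
    out[[length(out) + 1L]] <- task_spec("word_pair", c(w[i], w[j]))
  out
}

# filter an epoch set to the task's trials and return its class labels
apply_task <- function(es, task) {
  word <- es$labels$word
  if (task$type == "word_pair") {
    keep <- word %in% task$words
    es <- subset_trials(es, keep)
    labels <- es$labels$word
  } else if (task$type == "short_vs_long") {
    keep <- word %in% c("si", "no", "agua", "dormir")
    es <- subset_trials(es, keep)
    labels <- ifelse(es$labels$word %in% c("si", "no"), "short", "long")
  } else {
    labels <- word
  }
  list(es = es, labels = labels)
}

#' Training-scenario specification
#'
#' The four training-data compositions compared by the analysis, plus two
#' experimental multi-subject variants (reported as unstable in the study
#' design; runnable but carrying no calibration claims):
#' \describe{
#'   \item{intra_imagined}{train 80% target imagined, test 20% (5-fold CV).}
#'   \item{intra_mixed}{train 80% target imagined + 100% target overt,
#'     test 20% target imagined (5-fold CV).}
#'   \item{intra_overt}{train 100% target overt, test 100% target
#'     imagined (single evaluation, no folds).}
#'   \item{multi_overt_augmented}{train 80% target imagined + 100% overt
#'     of all *other* subjects, test 20% target imagined (5-fold CV).}
#'   \item{multi_imagined_augmented, multi_mixed_augmented}{experimental:
#'     add the other subjects' imagined (or both) streams to the
#'     intra_mixed composition.}
#' }
#'
#' @param id scenario identifier.
#' @param task a [task_spec()].
#' @param n_folds cross-validation folds (default 5).
#' @param zscore apply per-channel z-score normalization (train-fit
#'   parameters; see [zscore_normalize()]).
#' @param seed seed for fold assignment and per-fold model seeds.
#' @param experimental must be TRUE to run the two unstable variants.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(id = c("intra_imagined", "intra_mixed",
                                 "intra_overt", "multi_overt_augmented",
                                 "multi_imagined_augmented",
                                 "multi_mixed_augmented"),
                          task = task_spec("word_pair", c("si", "comida")),
                          n_folds = 5, zscore = TRUE, seed = 1,
                          experimental = FALSE) {
  id <- match.arg(id)
  if (id %in% c("multi_imagined_augmented", "multi_mixed_augmented") &&
      !experimental)
    stop(id, " is an experimental variant; set experimental = TRUE to run it")
  structure(list(id = id, task = task, n_folds = n_folds, zscore = zscore,
                 seed = seed, experimental = experimental),
            class = "scenario_spec")
}

#' Stratified cross-validation folds
#'
#' Partitions trials into `n_folds` mutually exclusive, exhaustive test
#' groups, stratified by class so every fold holds close to the same
#' class mix (an 80/20 train/test split per fold at `n_folds = 5`).
#'
#' @param labels per-trial class labels.
#' @param n_folds number of folds.
#' @param seed shuffle seed.
#' @return A `fold_plan`: list with `test` (list of test index vectors)
#'   and `n`.
#' @export
make_folds <- function(labels, n_folds = 5, seed = 1) {
  classes <- unique(labels)
  counts <- table(labels)
  if (any(counts < n_folds))
    stop(sprintf("class '%s' has %d trials; %d folds need at least %d per class",
                 names(counts)[which.min(counts)], min(counts),
                 n_folds, n_folds))
  fold_of <- integer(length(labels))
  with_seed(seed, {
    for (cl in classes) {
      i <- sample(which(labels == cl))
      fold_of[i] <- rep_len(seq_len(n_folds), length(i))
    }
  })
  list(test = lapply(seq_len(n_folds), function(k) which(fold_of == k)),
       n = length(labels))
}

#' Per-channel z-score normalization with train-fitted parameters
#'
#' Standardizes every channel to zero mean and unit variance.  The
#' parameters are estimated on the imagined-speech training portion of
#' the current fold and reused unchanged for the test set; the overt
#' portion (constant across folds) is standardized once with its own
#' parameters.  When the training set has no imagined portion
#' (overt-only training), the test set is transformed with the overt
#' parameters instead.
#'
#' @param train_im imagined-speech training [epoch_set()] or NULL.
#' @param train_ov overt-speech training [epoch_set()] or NULL.
#' @param test test [epoch_set()].
#' @return A list with standardized `train_im`, `train_ov`, `test`.
#' @export
zscore_normalize <- function(train_im, train_ov, test) {
  fit <- function(es) {
    m <- apply(es$data, 1, mean)
    s <- apply(es$data, 1, stats::sd)
    if (any(s < 1e-9)) {
      warning("zero-variance channel; sd floored at 1e-9")
      s <- pmax(s, 1e-9)
    }
    list(m = m, s = s)
  }
  apply_par <- function(es, p) {
    es$data <- (es$data - p$m) / p$s  # recycles over samples x trials
    es
  }
  ref <- NULL
  if (!is.null(train_im)) {
    p_im <- fit(train_im)
    train_im <- apply_par(train_im, p_im)
    ref <- p_im
  }
  if (!is.null(train_ov)) {
    p_ov <- fit(train_ov)
    train_ov <- apply_par(train_ov, p_ov)
    if (is.null(ref)) ref <- p_ov
  }
  list(train_im = train_im, train_ov = train_ov,
       test = apply_par(test, ref))
}

# attach stable trial identifiers used by the leakage guard
tag_uids <- function(es, subject, condition) {
  es$labels$uid <- sprintf("%s_%s_%04d", subject, condition,
                           seq_len(n_trials(es)))
  es
}

#' Assemble the training and test sets of one fold
#'
#' Implements the scenario compositions on task-filtered data.  Every
#' returned set carries trial identifiers; train/test disjointness is
#' asserted here and again in [run_scenario()].
#'
#' @param spec a [scenario_spec()].
#' @param fold fold number (1-based); ignored for `intra_overt`.
#' @param folds a `fold_plan` from [make_folds()] over the target
#'   subject's task-filtered imagined trials.
#' @param target list with `imagined`/`overt` task-filtered
#'   [epoch_set()]s and `labels_imagined`/`labels_overt` class labels for
#'   the target subject.
#' @param others same structure for all other subjects (list; may be
#'   empty for intra-subject scenarios).
#' @return A list with `train` (epoch_set), `train_labels`, `test`,
#'   `test_labels`; the imagined/overt split needed by the normalization
#'   contract is kept in `train_im`/`train_ov` (+ label vectors).
#' @export
assemble_training_set <- function(spec, fold, folds, target, others = list()) {
  needs_overt <- spec$id != "intra_imagined"
  if (needs_overt && is.null(target$overt))
    stop("scenario ", spec$id, " requires overt-speech data for the target subject")
  if (spec$id == "intra_overt") {
    train_im <- NULL; tl_im <- character()
    test_idx <- seq_len(n_trials(target$imagined))
  } else {
    test_idx <- folds$test[[fold]]
    tr_idx <- setdiff(seq_len(n_trials(target$imagined)), test_idx)
    train_im <- subset_trials(target$imagined, tr_idx)
    tl_im <- target$labels_imagined[tr_idx]
  }
  test <- subset_trials(target$imagined, test_idx)
  test_labels <- target$labels_imagined[test_idx]

  train_ov <- NULL; tl_ov <- character()
  if (spec$id %in% c("intra_mixed", "intra_overt")) {
    train_ov <- target$overt
    tl_ov <- target$labels_overt
  } else if (spec$id == "multi_overt_augmented") {
    if (length(others) == 0L)
      stop("multi_overt_augmented requires other subjects' overt data")
    train_ov <- bind_trials(lapply(others, `[[`, "overt"))
    tl_ov <- unlist(lapply(others, `[[`, "labels_overt"))
  } else if (spec$id == "multi_imagined_augmented") {
    train_ov <- bind_trials(lapply(others, `[[`, "imagined"))
    tl_ov <- unlist(lapply(others, `[[`, "labels_imagined"))
  } else if (spec$id == "multi_mixed_augmented") {
    train_ov <- bind_trials(c(lapply(others, `[[`, "overt"),
                              lapply(others, `[[`, "imagined"),
                              list(target$overt)))
    tl_ov <- c(unlist(lapply(others, `[[`, "labels_overt")),
               unlist(lapply(others, `[[`, "labels_imagined")),
               target$labels_overt)
  }

  train_sets <- Filter(Negate(is.null), list(train_im, train_ov))
  train <- if (length(train_sets) > 1L) bind_trials(train_sets) else train_sets[[1]]
  train_labels <- c(tl_im, tl_ov)
  if (length(intersect(train$labels$uid, test$labels$uid)) > 0L)
    stop("leakage: train and test share trials")
  list(train = train, train_labels = train_labels,
       train_im = train_im, train_labels_im = tl_im,
       train_ov = train_ov, train_labels_ov = tl_ov,
       test = test, test_labels = test_labels)
}

#' Run one scenario for one target subject
#'
#' Crops all epochs to the classification window (0-0.5 s), filters them
#' to the task, builds stratified folds over the target subject's
#' imagined trials, and for each fold assembles the scenario training
#' set, applies the z-score contract, trains a fresh network and
#' evaluates on the held-out imagined trials.  `intra_overt` performs a
#' single train/test evaluation instead of cross-validation.
#'
#' @param spec a [scenario_spec()].
#' @param cohort list of per-subject lists with `subject`, `overt`,
#'   `imagined` (preprocessed [epoch_set()]s on a window covering
#'   0-0.5 s at the analysis rate).
#' @param target_index 1-based index of the target subject.
#' @param model_cfg a [model_config()]; `n_channels`, `n_samples` and
#'   `n_classes` are adapted to the data/task automatically.
#' @param class_window classification window, seconds.
#' @return A `scenario_result`: list with `spec`, `subject`, `folds`
#'   (per-fold accuracy, per-class recall, confusion matrix, trial
#'   counts), `accuracy_mean`, `accuracy_sd`, `n_test_total`.
#' @export
run_scenario <- function(spec, cohort, target_index = 1L,
                         model_cfg = model_config(),
                         class_window = c(0, 0.5)) {
  prep <- function(subj) {
    out <- list(subject = subj$subject)
    for (cond in study_conditions()) {
      if (is.null(subj[[cond]])) next
      es <- tag_uids(crop_window(subj[[cond]], class_window),
                     subj$subject, cond)
      ft <- apply_task(es, spec$task)
      out[[cond]] <- ft$es
      out[[paste0("labels_", cond)]] <- ft$labels
    }
    out
  }
  target <- prep(cohort[[target_index]])
  others <- lapply(cohort[-target_index], prep)

  classes <- sort(unique(target$labels_imagined))
  n_fold_runs <- if (spec$id == "intra_overt") 1L else spec$n_folds
  folds <- if (spec$id == "intra_overt") NULL else
    make_folds(target$labels_imagined, spec$n_folds,
               seed = sub_seed(spec$seed, "folds", target_index))

  fold_results <- lapply(seq_len(n_fold_runs), function(k) {
    as_ <- assemble_training_set(spec, k, folds, target, others)
    if (spec$zscore) {
      z <- zscore_normalize(as_$train_im, as_$train_ov, as_$test)
      train_sets <- Filter(Negate(is.null), list(z$train_im, z$train_ov))
      train <- if (length(train_sets) > 1L) bind_trials(train_sets)
               else train_sets[[1]]
      train_labels <- c(as_$train_labels_im, as_$train_labels_ov)
      test <- z$test
    } else {
      train <- as_$train; train_labels <- as_$train_labels; test <- as_$test
    }
    stopifnot(length(intersect(train$labels$uid, test$labels$uid)) == 0L)
    cfg <- model_cfg
    cfg$n_channels <- n_channels(train)
    cfg$n_samples <- n_samples(train)
    cfg$n_classes <- length(classes)
    cfg$seed <- sub_seed(spec$seed, "model", target_index * 100L + k)
    fitted <- train_model(build_model(cfg), train, train_labels)
    pr <- predict_model(fitted, test, labels = as_$test_labels)
    recalls <- vapply(classes, function(cl)
      if (cl %in% as_$test_labels) recall_per_class(pr$predictions, cl)
      else NA_real_, numeric(1))
    list(fold = k,
         n_train = n_trials(train), n_test = n_trials(test),
         accuracy = accuracy(pr$predictions),
         recall = recalls,
         confusion = confusion_matrix(pr$predictions),
         epochs_run = fitted$epochs_run)
  })
  acc <- vapply(fold_results, `[[`, numeric(1), "accuracy")
  structure(list(spec = spec, subject = target$subject,
                 folds = fold_results,
                 accuracy_mean = mean(acc),
                 accuracy_sd = if (length(acc) > 1) stats::sd(acc) else NA_real_,
                 n_test_total = sum(vapply(fold_results, `[[`, numeric(1),
                                           "n_test"))),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s / %s / subject %s\n",
              x$spec$id, x$spec$task$name, x$subject))
  cat(sprintf("  accuracy %.2f%% +/- %s over %d evaluation(s), %d test trials\n",
              x$accuracy_mean,
              if (is.na(x$accuracy_sd)) "NA" else sprintf("%.2f", x$accuracy_sd),
              length(x$folds), x$n_test_total))
  invisible(x)
}

#' Run scenarios x tasks x subjects and tabulate per-fold results
#'
#' Iterates the requested combinations, recording one row per fold (or
#' per single evaluation for `intra_overt`).  Failures in one cell are
#' caught, recorded as `NA` rows with the error message, and do not stop
#' the remaining cells.
#'
#' @param cohort per-subject list as for [run_scenario()].
#' @param scenario_ids character vector of scenario identifiers.
#' @param tasks list of [task_spec()]s.
#' @param model_cfg a [model_config()].
#' @param subjects subject indices to evaluate (default all).
#' @param seed master seed for fold/model substreams.
#' @param csv optional path; when given the table is written as CSV.
#' @return A data.frame with columns `subject`, `scenario`, `task`,
#'   `fold`, `n_train`, `n_test`, `accuracy`, one `recall_*` column per
#'   class, and `error`.
#' @export
run_all <- function(cohort, scenario_ids = c("intra_imagined", "intra_mixed",
                                             "intra_overt",
                                             "multi_overt_augmented"),
                    tasks = list(task_spec("word_pair", c("si", "comida"))),
                    model_cfg = model_config(),
                    subjects = seq_along(cohort), seed = 1, csv = NULL) {
  rows <- list()
  for (s in subjects) for (sid in scenario_ids) for (task in tasks) {
    res <- tryCatch(
      run_scenario(scenario_spec(sid, task = task, seed = seed),
                   cohort, s, model_cfg),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = cohort[[s]]$subject, scenario = sid, task = task$name,
        fold = NA_integer_, n_train = NA_integer_, n_test = NA_integer_,
        accuracy = NA_real_, error = conditionMessage(res),
        stringsAsFactors = FALSE)
      next
    }
    for (fr in res$folds) {
      row <- data.frame(subject = res$subject, scenario = sid,
                        task = task$name, fold = fr$fold,
                        n_train = fr$n_train, n_test = fr$n_test,
                        accuracy = fr$accuracy, error = NA_character_,
                        stringsAsFactors = FALSE)
      for (cl in names(fr$recall))
        row[[paste0("recall_", cl)]] <- fr$recall[[cl]]
      rows[[length(rows) + 1L]] <- row
    }
  }
  # rows may have different recall columns across tasks; align them
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cn in setdiff(cols, names(r))) r[[cn]] <- NA_real_
    r[cols]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}
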