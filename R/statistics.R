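#' Overall classification accuracy
#'
#' Fraction of test instances whose predicted label equals the true
#' label, as a percentage.
#'
#' @param p a [labeled_predictions()].
#' @return Accuracy in percent.
#' @export
accuracy <- function(p) {
  stopifnot(inherits(p, "labeled_predictions"))
  if (length(p$y_true) == 0L) stop("empty prediction set")
  100 * mean(p$y_true == p$y_pred)
}

#' Per-class recall
#'
#' Correctly classified instances of class `class` divided by all true
#' instances of that class, as a percentage.  Undefined (an error, not 0)
#' when the class has no true instances.
#'
#' @param p a [labeled_predictions()].
#' @param class the class label.
#' @return Recall in percent.
#' @export
recall_per_class <- function(p, class) {
  stopifnot(inherits(p, "labeled_predictions"))
  pos <- p$y_true == class
  if (!any(pos)) stop("class '", class, "' absent from y_true; recall undefined")
  100 * sum(pos & p$y_pred == class) / sum(pos)
}

#' Confusion matrix
#'
#' @param p a [labeled_predictions()].
#' @return A c x c integer matrix, rows = true class, columns = predicted
#'   class, in the order of `p$class_set`.
#' @export
confusion_matrix <- function(p) {
  stopifnot(inherits(p, "labeled_predictions"))
  cls <- p$class_set
  m <- table(factor(p$y_true, levels = cls), factor(p$y_pred, levels = cls))
  m <- unclass(m)
  dimnames(m) <- list(true = cls, predicted = cls)
  m
}

# exact binomial CDF P(X <= x) for X ~ Bin(n, p) by log-space summation of
# the individual probability terms; the explicit summation pins down the
# "smallest integer whose CDF reaches the level" threshold convention.
binom_cdf <- function(x, n, p) {
  if (x < 0) return(0)
  x <- min(x, n)
  k <- 0:x
  terms <- lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)
  mx <- max(terms)
  min(1, exp(mx + log(sum(exp(terms - mx)))))
}

#' Analytic chance-level accuracy threshold
#'
#' Small-sample chance level for an `n`-trial test set with `c` equiprobable
#' classes: the smallest success count `X` whose binomial CDF (success
#' probability `1/c`) reaches `1 - alpha`, converted to a percentage of
#' `n`.  Always at least `100/c`, converging to `100/c` as `n` grows.
#'
#' @param n number of test samples.
#' @param c number of classes.
#' @param alpha significance level (default 0.05).
#' @return Threshold accuracy in percent.
#' @export
analytic_chance_threshold <- function(n, c, alpha = 0.05) {
  stopifnot(n >= 1, c >= 2, alpha > 0, alpha < 1)
  target <- 1 - alpha
  # monotone search from the mean upward; CDF at the mean is >= ~1/2
  x <- floor(n / c)
  while (x > 0 && binom_cdf(x - 1, n, 1 / c) >= target) x <- x - 1
  while (binom_cdf(x, n, 1 / c) < target) x <- x + 1
  100 * x / n
}

#' Two-sided analytic chance band
#'
#' Central `1 - alpha` interval of the accuracy of a random guesser on
#' `n` test samples with `c` classes, in percent.  Used to check that a
#' null classifier stays at chance.
#'
#' @inheritParams analytic_chance_threshold
#' @return Numeric `c(lower, upper)` in percent.
#' @export
chance_band <- function(n, c, alpha = 0.05) {
  stopifnot(n >= 1, c >= 2)
  lo <- stats::qbinom(alpha / 2, n, 1 / c)
  hi <- stats::qbinom(1 - alpha / 2, n, 1 / c)
  c(lower = 100 * lo / n, upper = 100 * hi / n)
}

#' Empirical chance threshold by training-label permutation
#'
#' Builds a null distribution of test accuracies by shuffling the
#' *training* labels (test labels stay intact), retraining and evaluating
#' `n_permutations` times, and returns the 95th percentile (or
#' `1 - alpha` quantile) of that distribution.
#'
#' @param runner function `(permuted_train_labels, permutation_index) ->
#'   accuracy percent`; it must retrain the model on the permuted labels
#'   and evaluate on the untouched test set.
#' @param train_labels the true training labels to permute.
#' @param n_permutations number of label permutations (500 in the full
#'   protocol; reducible for desk-scale runs).
#' @param alpha quantile level (default 0.05 -> 95th percentile).
#' @param seed RNG seed for the permutations.
#' @return A list with `threshold` (percent) and `null_accuracies`.
#' @export
permutation_chance_threshold <- function(runner, train_labels,
                                         n_permutations = 500,
                                         alpha = 0.05, seed = 1) {
  if (n_permutations < 20)
    warning("fewer than 20 permutations: the quantile estimate is unstable")
  accs <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      perm <- sample(train_labels)
      runner(perm, i)
    }, numeric(1))
  })
  list(threshold = unname(stats::quantile(accs, 1 - alpha, type = 7)),
       null_accuracies = accs)
}

#' Wilcoxon signed-rank test
#'
#' Paired signed-rank test of a sample against a second sample or a
#' constant reference (e.g. per-subject accuracies against a chance
#' threshold).  Zero differences are dropped; the null distribution is
#' exact for 25 or fewer non-zero differences without ties, with the
#' normal approximation (tie-corrected) otherwise.
#'
#' @param x numeric sample.
#' @param y second paired sample, or a single reference constant.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return A list with `statistic` (V, the sum of positive-difference
#'   ranks), `p_value` and `n` (non-zero differences used).
#' @export
wilcoxon_signed_rank <- function(x, y = 0,
                                 alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(y) == 1L) y <- rep(y, length(x))
  d <- x - y
  d <- d[d != 0]
  if (length(d) < 5L)
    stop("fewer than 5 non-zero differences; test not meaningful")
  wt <- suppressWarnings(stats::wilcox.test(d, alternative = alternative,
                                            exact = length(d) <= 25,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, n = length(d))
}

#' Summarize a results table across subjects
#'
#' Aggregates a per-fold results table (as produced by [run_all()]) per
#' scenario x task: mean and sd of accuracy across subjects, the number
#' of subjects whose mean accuracy exceeds the chance threshold, and the
#' number exceeding a headline level (70% by default).
#'
#' @param results data.frame with columns `subject`, `scenario`, `task`,
#'   `fold`, `accuracy` (and optionally per-class recalls).
#' @param threshold chance threshold(s) in percent: a single value or a
#'   named vector per task.
#' @param headline headline accuracy level in percent.
#' @return A data.frame with one row per scenario x task.
#' @export
summarize_results <- function(results, threshold, headline = 70) {
  cells <- unique(results[, c("scenario", "task")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- results[results$scenario == cells$scenario[i] &
                     results$task == cells$task[i], , drop = FALSE]
    thr <- if (length(threshold) > 1L) threshold[[cells$task[i]]] else threshold
    if (nrow(sub) == 0L || all(is.na(sub$accuracy)))
      return(data.frame(cells[i, ], n_subjects = 0L, mean_accuracy = NA_real_,
                        sd_accuracy = NA_real_, n_above_threshold = NA_integer_,
                        n_above_headline = NA_integer_, threshold = thr))
    per_subj <- tapply(sub$accuracy, sub$subject, mean, na.rm = TRUE)
    data.frame(cells[i, ],
               n_subjects = length(per_subj),
               mean_accuracy = mean(per_subj),
               sd_accuracy = stats::sd(per_subj),
               n_above_threshold = sum(per_subj > thr),
               n_above_headline = sum(per_subj > headline),
               threshold = thr)
  }))
  rownames(out) <- NULL
  out
}
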