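#' Compact CNN configuration
#'
#' Hyperparameters of the compact convolutional network used for
#' single-trial classification: `F1` temporal filters with a (1, 128)
#' kernel (half the 256 Hz sampling rate), a depthwise spatial
#' convolution of size (C, 1) with depth multiplier `D`, a separable
#' (1, 16) convolution with `F2 = F1 * D` pointwise filters, ELU
#' activations, batch normalization, dropout 0.65 and average pooling
#' (1, 4) then (1, 8), followed by a dense softmax classifier.  The
#' classification input is the 0-0.5 s window (129 samples at 256 Hz).
#'
#' @param n_channels number of EEG channels C.
#' @param n_samples input samples per trial (129 for 0-0.5 s at 256 Hz).
#' @param n_classes number of output classes (2 or 5).
#' @param F1 number of temporal filters.
#' @param D depth multiplier (spatial filters per temporal filter).
#' @param temporal_kernel temporal kernel length (same-padded).
#' @param sep_kernel separable depthwise kernel length (same-padded).
#' @param pool1,pool2 average-pooling widths of blocks 1 and 2.
#' @param dropout_p dropout probability in `[0, 1)`.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience on validation loss (only
#'   active when a validation set is available).
#' @param val_fraction fraction of the training trials held out
#'   (stratified) for early stopping; 0 disables the split.
#' @param seed seed for weight initialisation, shuffling and dropout.
#' @return A `model_config` list with `F2 = F1 * D` filled in.
#' @export
model_config <- function(n_channels = 32, n_samples = 129, n_classes = 2,
                         F1 = 8, D = 2,
                         temporal_kernel = 128, sep_kernel = 16,
                         pool1 = 4, pool2 = 8,
                         dropout_p = 0.65,
                         lr = 1e-3, batch_size = 16, epochs = 500,
                         patience = 50, val_fraction = 0.2, seed = 1) {
  stopifnot(dropout_p >= 0, dropout_p < 1, F1 >= 1, D >= 1,
            n_classes >= 2, val_fraction >= 0, val_fraction < 0.5)
  t_out <- (n_samples %/% pool1) %/% pool2
  if (t_out < 1)
    stop(sprintf("input of %d samples too short for pooling (1,%d) then (1,%d)",
                 n_samples, pool1, pool2))
  structure(list(n_channels = n_channels, n_samples = n_samples,
                 n_classes = n_classes, F1 = F1, D = D, F2 = F1 * D,
                 temporal_kernel = temporal_kernel, sep_kernel = sep_kernel,
                 pool1 = pool1, pool2 = pool2, dropout_p = dropout_p,
                 lr = lr, batch_size = batch_size, epochs = epochs,
                 patience = patience, val_fraction = val_fraction,
                 seed = seed),
            class = "model_config")
}

#' Analytic trainable-parameter count
#'
#' Closed-form layer-by-layer count for the architecture (batch-norm
#' running statistics excluded; they are not trained by gradient
#' descent): `F1*kt + F2*C + 2*F2 + F2*ks + F2^2 + 2*F2 +
#' n_classes*(F2*T2) + n_classes`, with `T2 = (T %/% p1) %/% p2`.
#'
#' @param cfg a [model_config()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(cfg) {
  t2 <- (cfg$n_samples %/% cfg$pool1) %/% cfg$pool2
  cfg$F1 * cfg$temporal_kernel +      # temporal kernels
    cfg$F2 * cfg$n_channels +         # depthwise spatial filters
    2L * cfg$F2 +                     # BN1 gamma/beta
    cfg$F2 * cfg$sep_kernel +         # separable depthwise kernels
    cfg$F2 * cfg$F2 +                 # pointwise filters
    2L * cfg$F2 +                     # BN2 gamma/beta
    cfg$n_classes * cfg$F2 * t2 +     # dense weights
    cfg$n_classes                     # dense bias
}

#' Build an untrained model
#'
#' Initialises the network weights (Glorot-uniform, seeded) for the
#' given configuration.
#'
#' @param cfg a [model_config()].
#' @return An `eegnet_model` list with `cfg`, `params`, and empty
#'   `classes`/`history` slots.
#' @export
build_model <- function(cfg) {
  params <- eegnet_init_cpp(cfg$n_channels, cfg$n_samples, cfg$F1, cfg$D,
                            cfg$temporal_kernel, cfg$sep_kernel,
                            cfg$pool1, cfg$pool2, cfg$n_classes, cfg$seed)
  structure(list(cfg = cfg, params = params, classes = NULL,
                 history = NULL, epochs_run = 0L),
            class = "eegnet_model")
}

#' @export
print.eegnet_model <- function(x, ...) {
  cat(sprintf("<eegnet_model> C=%d T=%d F1=%d D=%d F2=%d classes=%d (%s)\n",
              x$cfg$n_channels, x$cfg$n_samples, x$cfg$F1, x$cfg$D,
              x$cfg$F2, x$cfg$n_classes,
              if (is.null(x$classes)) "untrained"
              else paste(x$classes, collapse = "/")))
  cat(sprintf("  %d trainable parameters\n", count_parameters(x$cfg)))
  invisible(x)
}

# trial data of an epoch_set as a C x T x N numeric array for the C++ core
epochs_to_cube <- function(es, cfg) {
  d <- dim(es$data)
  if (d[1] != cfg$n_channels)
    stop(sprintf("model expects %d channels, data has %d",
                 cfg$n_channels, d[1]))
  if (d[2] != cfg$n_samples)
    stop(sprintf("model expects %d samples per trial, data has %d",
                 cfg$n_samples, d[2]))
  es$data
}

#' Train the model
#'
#' Minimises the cross-entropy by Adam over shuffled minibatches.  When
#' `cfg$val_fraction > 0`, a stratified validation split is carved from
#' the training trials and training stops early once the validation loss
#' has not improved for `cfg$patience` epochs (the best-validation
#' weights are restored).  A fixed seed makes the fitted weights
#' reproducible.
#'
#' @param model an `eegnet_model` from [build_model()].
#' @param es an [epoch_set()] cropped to the classification window.
#' @param labels per-trial class labels (character); at least 2 classes.
#' @return The fitted `eegnet_model` with `classes`, `history` (per-epoch
#'   train/validation loss and accuracy) and `epochs_run`.
#' @export
train_model <- function(model, es, labels) {
  cfg <- model$cfg
  labels <- as.character(labels)
  if (length(labels) != n_trials(es))
    stop("label count does not match trial count")
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("training set has a single class")
  if (length(classes) != cfg$n_classes)
    stop(sprintf("model expects %d classes, labels have %d",
                 cfg$n_classes, length(classes)))
  y <- match(labels, classes) - 1L
  X <- epochs_to_cube(es, cfg)
  nt <- n_trials(es)
  if (cfg$val_fraction > 0) {
    val_idx <- with_seed(sub_seed(cfg$seed, "valsplit"), {
      unlist(lapply(classes, function(cl) {
        i <- which(labels == cl)
        sample(i, max(1L, round(length(i) * cfg$val_fraction)))
      }))
    })
    tr_idx <- setdiff(seq_len(nt), val_idx)
    fit <- eegnet_train_cpp(model$params,
                            X[, , tr_idx, drop = FALSE], y[tr_idx],
                            X[, , val_idx, drop = FALSE], y[val_idx],
                            cfg$epochs, cfg$batch_size, cfg$lr,
                            cfg$dropout_p, cfg$patience, cfg$seed)
  } else {
    empty <- array(0, c(cfg$n_channels, cfg$n_samples, 0))
    fit <- eegnet_train_cpp(model$params, X, y, empty, integer(),
                            cfg$epochs, cfg$batch_size, cfg$lr,
                            cfg$dropout_p, cfg$epochs + 1L, cfg$seed)
  }
  model$params <- fit$params
  model$classes <- classes
  model$history <- fit$history[seq_len(fit$epochs_run), , drop = FALSE]
  model$epochs_run <- fit$epochs_run
  model
}

#' Predict class labels for new trials
#'
#' Eval-mode forward pass (batch-norm running statistics, dropout off);
#' the predicted class is the softmax argmax, with ties broken towards
#' the lowest class index.
#'
#' @param model a fitted `eegnet_model`.
#' @param es an [epoch_set()] on the classification window with the same
#'   channel count the model was built for.
#' @param labels optional true labels; when given, the result includes a
#'   [labeled_predictions()] object.
#' @return A list with `probs` (N x classes matrix, rows summing to 1),
#'   `y_pred` (character) and, when `labels` is supplied, `predictions`.
#' @export
predict_model <- function(model, es, labels = NULL) {
  if (is.null(model$classes)) stop("model has not been trained")
  X <- epochs_to_cube(es, model$cfg)
  probs <- eegnet_predict_cpp(model$params, X)
  colnames(probs) <- model$classes
  # ties broken deterministically towards the lowest class index
  y_pred <- model$classes[apply(probs, 1, which.max)]
  out <- list(probs = probs, y_pred = y_pred)
  if (!is.null(labels))
    out$predictions <- labeled_predictions(as.character(labels), y_pred,
                                           model$classes)
  out
}
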