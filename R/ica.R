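#' Symmetric FastICA decomposition of concatenated epochs
#'
#' Fits an ICA on the channels x (samples * trials) concatenation of all
#' epochs: the data are demeaned and whitened by eigendecomposition of the
#' channel covariance, then unmixed with the symmetric fixed-point
#' iteration under a tanh contrast, from a seeded random orthonormal
#' start.  As many components as channels are estimated.
#'
#' @param es an [epoch_set()].
#' @param seed seed for the random initial unmixing matrix.
#' @param max_iter,tol fixed-point iteration controls.
#' @return A list with `mixing` (channels x components), `unmixing`
#'   (components x channels), `sources` (components x (samples * trials))
#'   and `center` (channel means), such that
#'   `data ~ center + mixing %*% sources`.
#' @export
fastica_decompose <- function(es, seed = 1, max_iter = 200, tol = 1e-6) {
  nc <- n_channels(es)
  X <- matrix(es$data, nc, n_samples(es) * n_trials(es))
  center <- rowMeans(X)
  X <- X - center
  cv <- X %*% t(X) / ncol(X)
  eg <- eigen(cv, symmetric = TRUE)
  d <- pmax(eg$values, 1e-12)
  K <- diag(1 / sqrt(d)) %*% t(eg$vectors)   # whitening
  Z <- K %*% X
  W <- with_seed(seed, matrix(stats::rnorm(nc * nc), nc, nc))
  orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- orth(W)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    Gp <- 1 - G^2
    W1 <- G %*% t(Z) / ncol(Z) - diag(rowMeans(Gp)) %*% W
    W1 <- orth(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  unmixing <- W %*% K
  mixing <- eg$vectors %*% diag(sqrt(d)) %*% t(W)
  list(mixing = mixing, unmixing = unmixing,
       sources = unmixing %*% X, center = center)
}

# per-component artifact scores used by the automatic selection:
# blink  — frontal-concentrated topography with low-frequency dominance
# emg    — fraction of spectral power above 20 Hz
# ecg    — periodicity of the source autocorrelation at cardiac lags
ica_component_scores <- function(ica, es) {
  montage <- standard_montage()
  frontal <- es$channels$name %in% montage$name[montage$frontal]
  fs <- es$fs
  nc <- nrow(ica$sources)
  scores <- data.frame(component = seq_len(nc) - 1L,
                       blink = 0, emg = 0, ecg = 0)
  for (i in seq_len(nc)) {
    a <- ica$mixing[, i]
    frontal_frac <- sum(a[frontal]^2) / sum(a^2)
    s <- ica$sources[i, ]
    n <- length(s)
    pw <- Mod(stats::fft(s - mean(s)))^2
    half <- seq_len(floor(n / 2))
    f <- (half - 1) / n * fs
    pw <- pw[half]
    low_frac <- sum(pw[f <= 5]) / sum(pw)
    high_frac <- sum(pw[f >= 20]) / sum(pw)
    ac <- stats::acf(s, lag.max = min(n - 1, round(1.5 * fs)),
                     plot = FALSE, demean = TRUE)$acf[, 1, 1]
    lag_lo <- round(0.6 * fs); lag_hi <- min(length(ac) - 1, round(1.3 * fs))
    periodicity <- if (lag_hi > lag_lo) max(ac[(lag_lo:lag_hi) + 1]) else 0
    scores$blink[i] <- frontal_frac * low_frac
    scores$emg[i] <- high_frac
    scores$ecg[i] <- periodicity
  }
  scores
}

#' Remove artifact-carrying ICA components
#'
#' Decomposes the concatenated epochs into as many independent components
#' as channels and reconstructs the signal without the artifact
#' components.  In `"manual"` mode the caller supplies the component
#' indices (reproducing a human visual selection); in `"auto"` mode
#' components are selected by score: frontal low-frequency topography for
#' blinks (score > 0.3), spectral power fraction above 20 Hz > 0.6 for
#' muscle activity, and cardiac-lag autocorrelation > 0.4 for ECG.  At
#' most `ica_max_remove` components are removed.
#'
#' @param es an [epoch_set()] (after filtering and channel rejection).
#' @param cfg a [preproc_config()] with `ica_mode != "off"`.
#' @return A list with `epochs` (reconstructed set), `removed` (0-based
#'   component indices) and `scores` (per-component score table; `auto`
#'   mode only).
#' @export
remove_artifact_components <- function(es, cfg) {
  if (cfg$ica_mode == "off")
    return(list(epochs = es, removed = integer(), scores = NULL))
  ica <- fastica_decompose(es, seed = cfg$ica_seed)
  nc <- n_channels(es)
  scores <- NULL
  if (cfg$ica_mode == "manual") {
    removed <- as.integer(cfg$ica_components)
    if (length(removed) && (min(removed) < 0 || max(removed) >= nc))
      stop(sprintf("component index out of range 0..%d", nc - 1L))
  } else {
    scores <- ica_component_scores(ica, es)
    hit <- with(scores, blink > 0.3 | emg > 0.6 | ecg > 0.4)
    removed <- scores$component[hit]
    if (length(removed) > cfg$ica_max_remove) {
      worst <- with(scores, pmax(blink / 0.3, emg / 0.6, ecg / 0.4))
      removed <- removed[order(worst[hit], decreasing = TRUE)][seq_len(cfg$ica_max_remove)]
    }
  }
  if (length(removed)) {
    keep <- setdiff(seq_len(nc), removed + 1L)
    X <- ica$mixing[, keep, drop = FALSE] %*%
      ica$sources[keep, , drop = FALSE] + ica$center
    es$data <- array(X, dim(es$data))
  }
  list(epochs = es, removed = sort(removed), scores = scores)
}
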