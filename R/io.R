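#' Write an epoch set to the internal interchange format
#'
#' The internal serialization is a raw little-endian float32 array in
#' channel-fastest order (`<stem>.f32`) plus a JSON sidecar
#' (`<stem>.json`) holding the shape, sampling rate, time offset, channel
#' names/flags and per-trial labels.  Unlike EDF this round-trips at
#' float32 precision, which is what the pipeline uses internally.
#'
#' @param es an [epoch_set()].
#' @param stem file path without extension; `<stem>.f32` and
#'   `<stem>.json` are (over)written.
#' @return `stem`, invisibly.
#' @export
write_epochs <- function(es, stem) {
  stopifnot(inherits(es, "epoch_set"))
  if (n_trials(es) == 0L) stop("refusing to write an empty trial set")
  if (!all(is.finite(es$data))) stop("epoch data must be finite")
  con <- file(paste0(stem, ".f32"), "wb")
  on.exit(close(con))
  writeBin(as.vector(es$data), con, size = 4L, endian = "little")
  meta <- list(
    format = "imspeech-epochs-v1",
    shape = dim(es$data),
    fs = es$fs,
    t0_offset = es$t0_offset,
    channels = list(name = es$channels$name, is_bad = es$channels$is_bad),
    labels = list(subject = es$labels$subject,
                  condition = es$labels$condition,
                  word = es$labels$word)
  )
  jsonlite::write_json(meta, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Read an epoch set from the internal interchange format
#'
#' @param stem file path without extension, as used by [write_epochs()].
#' @return An [epoch_set()].
#' @export
read_epochs <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "imspeech-epochs-v1"))
    stop("not an imspeech epoch file: ", stem)
  shape <- as.integer(meta$shape)
  con <- file(paste0(stem, ".f32"), "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = prod(shape), size = 4L, endian = "little")
  if (length(x) != prod(shape))
    stop("truncated data file for ", stem)
  labels <- data.frame(subject = meta$labels$subject,
                       condition = meta$labels$condition,
                       word = meta$labels$word,
                       stringsAsFactors = FALSE)
  epoch_set(array(x, shape), meta$fs, meta$t0_offset, labels,
            channel_info(meta$channels$name, meta$channels$is_bad))
}

pad_ascii <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

# shortest decimal representation of x that fits in an 8-char EDF field
num8 <- function(x) {
  vapply(x, function(v) {
    for (d in 7:1) {
      s <- formatC(v, digits = d, format = "g")
      if (nchar(s) <= 8) return(s)
    }
    stop("cannot represent ", v, " in an 8-character field")
  }, "")
}

#' Export an epoch set to EDF plus a JSON label sidecar
#'
#' Writes a minimal EDF file with one data record per trial and 16-bit
#' samples scaled per channel to the data range, plus a JSON sidecar
#' mapping trial index to (subject, condition, word).  EDF quantization is
#' lossy (~range/65535 per channel); use [write_epochs()] for the lossless
#' internal format.
#'
#' @param es an [epoch_set()].
#' @param path EDF output path.
#' @param sidecar JSON sidecar path (default `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_edf_epochs <- function(es, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(es, "epoch_set"))
  if (n_trials(es) == 0L) stop("refusing to write an empty trial set")
  if (!all(is.finite(es$data))) stop("epoch data must be finite")
  nc <- n_channels(es); ns <- n_samples(es); nt <- n_trials(es)
  pmin <- apply(es$data, 1, min); pmax <- apply(es$data, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  # quantize the physical range to its 8-character ASCII form up front so
  # that the scaling used for the samples matches the header exactly
  pmin <- as.numeric(num8(pmin - abs(pmin) * 1e-6))
  pmax <- as.numeric(num8(pmax + abs(pmax) * 1e-6))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_ascii("0", 8), pad_ascii("X", 80), pad_ascii("imspeech export", 80),
    pad_ascii("01.01.26", 8), pad_ascii("00.00.00", 8),
    pad_ascii(256 * (nc + 1), 8), pad_ascii("", 44),
    pad_ascii(nt, 8), pad_ascii(format(ns / es$fs, digits = 7), 8),
    pad_ascii(nc, 4),
    paste0(vapply(es$channels$name, pad_ascii, "", width = 16), collapse = ""),
    paste0(rep(pad_ascii("AgAgCl", 80), nc), collapse = ""),
    paste0(rep(pad_ascii("uV", 8), nc), collapse = ""),
    paste0(vapply(num8(pmin), pad_ascii, "", width = 8), collapse = ""),
    paste0(vapply(num8(pmax), pad_ascii, "", width = 8), collapse = ""),
    paste0(rep(pad_ascii("-32768", 8), nc), collapse = ""),
    paste0(rep(pad_ascii("32767", 8), nc), collapse = ""),
    paste0(rep(pad_ascii("", 80), nc), collapse = ""),
    paste0(rep(pad_ascii(ns, 8), nc), collapse = ""),
    paste0(rep(pad_ascii("", 32), nc), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  scale <- 65535 / (pmax - pmin)
  for (tr in seq_len(nt)) {
    for (ch in seq_len(nc)) {
      dig <- round((es$data[ch, , tr] - pmin[ch]) * scale[ch]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
               size = 2L, endian = "little")
    }
  }
  jsonlite::write_json(
    list(format = "imspeech-edf-sidecar-v1", fs = es$fs,
         t0_offset = es$t0_offset,
         labels = list(subject = es$labels$subject,
                       condition = es$labels$condition,
                       word = es$labels$word)),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import epoch-structured EEG from an EDF file
#'
#' Reads an EDF file written with one fixed-length data record per trial
#' and a JSON sidecar of per-trial labels.  Channel labels are matched to
#' the 32-channel reference montage; montage channels absent from the file
#' are inserted as zero-filled placeholders flagged `is_bad`, and file
#' channels outside the montage are appended flagged `is_bad`.
#'
#' @param path EDF file path.
#' @param sidecar JSON sidecar path (default `<path>.json`).
#' @return An [epoch_set()] in microvolts.
#' @export
read_edf_epochs <- function(path, sidecar = paste0(path, ".json")) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8) # header bytes, implied by nc
  rd(44)
  nt <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nc <- as.integer(rd(4))
  labs <- trimws(vapply(seq_len(nc), function(i) rd(16), ""))
  rd(80 * nc); rd(8 * nc)
  pmin <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  rd(80 * nc)
  spr <- as.integer(vapply(seq_len(nc), function(i) rd(8), ""))
  rd(32 * nc)
  if (length(unique(spr)) != 1L)
    stop("sampling rate mismatch across channels: samples per record ",
         paste(unique(spr), collapse = " vs "))
  ns <- spr[1]
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  n_lab <- length(meta$labels$condition)
  if (n_lab != nt)
    stop(sprintf(
      "sidecar has %d labels but file has %d epochs; unlabelled trial indices: %s",
      n_lab, nt,
      if (nt > n_lab) paste(seq.int(n_lab + 1L, nt), collapse = ", ")
      else "none (surplus labels)"))
  fs <- if (!is.null(meta$fs)) meta$fs else ns / rec_dur
  data <- array(0, c(nc, ns, nt))
  gain <- (pmax - pmin) / (dmax - dmin)
  for (tr in seq_len(nt)) {
    for (ch in seq_len(nc)) {
      dig <- readBin(con, integer(), n = ns, size = 2L,
                     signed = TRUE, endian = "little")
      data[ch, , tr] <- (dig - dmin[ch]) * gain[ch] + pmin[ch]
    }
  }
  montage <- standard_montage()
  known <- labs %in% montage$name
  out_names <- c(montage$name, labs[!known])
  out <- array(0, c(length(out_names), ns, nt))
  is_bad <- rep(TRUE, length(out_names))
  for (i in seq_len(nc)) {
    j <- match(labs[i], out_names)
    out[j, , ] <- data[i, , ]
    is_bad[j] <- !known[i]
  }
  labels <- data.frame(subject = meta$labels$subject,
                       condition = meta$labels$condition,
                       word = meta$labels$word,
                       stringsAsFactors = FALSE)
  epoch_set(out, fs, meta$t0_offset, labels,
            channel_info(out_names, is_bad))
}
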