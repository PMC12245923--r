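#' Reference 32-channel 10/10 montage
#'
#' The recording montage assumed throughout the package: 32 active
#' electrodes placed according to the extended 10/10 system.  Each channel
#' carries an anterior-posterior coordinate `y` in (-1, 1) (+1 = frontal
#' pole, -1 = occipital pole) used by the synthetic generator to model the
#' posterior-to-frontal latency gradient of the visual evoked response, and
#' topography group tags used by the automatic ICA component scoring.
#'
#' @return A data.frame with columns `name`, `index` (0-based), `y`,
#'   `frontal` (logical), `temporal` (logical).
#' @export
standard_montage <- function() {
  name <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
            "FC5", "FC1", "FC2", "FC6",
            "T7", "C3", "Cz", "C4", "T8",
            "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
            "P7", "P3", "Pz", "P4", "P8",
            "PO9", "O1", "Oz", "O2", "PO10")
  y <- c(0.95, 0.95, 0.60, 0.60, 0.60, 0.60, 0.60,
         0.35, 0.35, 0.35, 0.35,
         0.00, 0.00, 0.00, 0.00, 0.00,
         -0.30, -0.30, -0.30, -0.30, -0.30, -0.30,
         -0.60, -0.60, -0.60, -0.60, -0.60,
         -0.80, -0.95, -0.95, -0.95, -0.80)
  data.frame(
    name = name,
    index = seq_along(name) - 1L,
    y = y,
    frontal = name %in% c("Fp1", "Fp2", "F7", "F8", "F3", "F4"),
    temporal = name %in% c("T7", "T8", "TP9", "TP10"),
    stringsAsFactors = FALSE
  )
}

#' Channel metadata constructor
#'
#' @param names character vector of channel labels; must be unique.
#' @param is_bad logical vector flagging channels excluded from all
#'   downstream computation (defaults to all good).
#' @return A data.frame with columns `name`, `index` (0-based), `is_bad`.
#' @export
channel_info <- function(names, is_bad = rep(FALSE, length(names))) {
  if (anyDuplicated(names)) stop("channel names must be unique")
  if (length(is_bad) != length(names))
    stop("is_bad must match the number of channels")
  data.frame(name = as.character(names),
             index = seq_along(names) - 1L,
             is_bad = as.logical(is_bad),
             stringsAsFactors = FALSE)
}

#' The five study words
#'
#' Ordered vocabulary of the word-production protocol: the Spanish words
#' "si", "no", "agua", "comida", "dormir".
#' @return Character vector of length 5.
#' @export
study_words <- function() c("si", "no", "agua", "comida", "dormir")

#' The two production conditions
#' @return Character vector `c("overt", "imagined")`.
#' @export
study_conditions <- function() c("overt", "imagined")
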