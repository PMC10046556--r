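#' Default 24-channel 10-20 montage
#'
#' Channel names of the 24-electrode scalp montage used throughout the
#' package: frontal (Fp1, Fp2, F3, F4, Fz), central (C3, C4, FC5, FC6, CP5,
#' CP6), parietal (P3, P4, Pz), occipital (O1, O2), left temporal (F7, T3,
#' TP7, P7) and right temporal (F8, T4, TP8, P8).
#'
#' @return Character vector of 24 channel labels.
#' @export
default_montage <- function() {
  c("Fp1", "Fp2", "F3", "F4", "Fz",
    "C3", "C4", "FC5", "FC6", "CP5", "CP6",
    "P3", "P4", "Pz",
    "O1", "O2",
    "F7", "T3", "TP7", "P7",
    "F8", "T4", "TP8", "P8")
}

#' Schematic 2-D electrode positions for the default montage
#'
#' Head-circle coordinates (unit disc, nose up) used for scalp scatter
#' plots. Positions are schematic 10-20 placements, not digitized locations.
#'
#' @return data.frame with columns `channel`, `x`, `y`.
#' @export
montage_layout <- function() {
  data.frame(
    channel = default_montage(),
    x = c(-0.31, 0.31, -0.36, 0.36, 0,
          -0.45, 0.45, -0.62, 0.62, -0.62, 0.62,
          -0.36, 0.36, 0,
          -0.31, 0.31,
          -0.72, -0.90, -0.85, -0.72,
          0.72, 0.90, 0.85, 0.72),
    y = c(0.85, 0.85, 0.45, 0.45, 0.48,
          0, 0, 0.25, 0.25, -0.25, -0.25,
          -0.45, -0.45, -0.48,
          -0.85, -0.85,
          0.52, 0, -0.28, -0.52,
          0.52, 0, -0.28, -0.52),
    stringsAsFactors = FALSE
  )
}

#' Construct a multichannel recording
#'
#' A `recording` bundles a channels-by-samples matrix with its sampling rate,
#' channel labels and event markers, the minimal container every pipeline
#' stage consumes and produces.
#'
#' @param data Numeric matrix, channels x samples.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param channel_labels Character vector of unique channel names, one per
#'   row of `data`. Defaults to the 24-channel montage when `data` has 24
#'   rows, otherwise `ch1..chN`.
#' @param events data.frame with columns `label`, `onset`, `offset` (sample
#'   indices, 1-based, inclusive). May be empty.
#' @return An object of class `recording`.
#' @export
recording <- function(data, sample_rate, channel_labels = NULL, events = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric channels x samples matrix")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("`sample_rate` must be a single positive number")
  }
  n_ch <- nrow(data)
  if (is.null(channel_labels)) {
    channel_labels <- if (n_ch == 24L) default_montage() else paste0("ch", seq_len(n_ch))
  }
  if (length(channel_labels) != n_ch) {
    stop("`channel_labels` length must equal nrow(data)")
  }
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  if (is.null(events)) {
    events <- data.frame(label = character(), onset = integer(), offset = integer(),
                         stringsAsFactors = FALSE)
  }
  stopifnot(all(c("label", "onset", "offset") %in% names(events)))
  rownames(data) <- channel_labels
  structure(
    list(data = data, sample_rate = sample_rate,
         channel_labels = channel_labels, events = events),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s), %d event(s)\n",
              nrow(x$data), ncol(x$data), x$sample_rate,
              ncol(x$data) / x$sample_rate, nrow(x$events)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A `recording`.
#' @return Numeric scalar, seconds.
#' @export
rec_duration <- function(rec) ncol(rec$data) / rec$sample_rate
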