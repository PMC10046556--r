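#' Zero-phase bandpass and integer decimation
#'
#' Applies an anti-alias low-pass at the native rate, decimates by an integer
#' factor, then applies a zero-phase 4th-order Butterworth bandpass at the
#' target rate (forward-backward filtering, so phase relations downstream
#' are untouched). Event indices are re-mapped to the new rate.
#'
#' @param rec A [recording()].
#' @param band Numeric length-2 (low, high) Hz passband.
#' @param target_rate Target sampling rate in Hz; the native rate must be an
#'   integer multiple of it.
#' @return A filtered, decimated [recording()].
#' @export
bandpass_and_decimate <- function(rec, band = c(0.5, 48), target_rate = 250) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$sample_rate
  factor <- fs / target_rate
  if (abs(factor - round(factor)) > 1e-9) {
    stop(sprintf("native rate %g Hz is not an integer multiple of target %g Hz",
                 fs, target_rate))
  }
  factor <- as.integer(round(factor))
  if (band[2] >= target_rate / 2) {
    stop("band upper edge must be below the Nyquist frequency of target_rate")
  }
  X <- rec$data
  if (factor > 1L) {
    # anti-alias low-pass before subsampling
    lp <- signal::butter(4, min(band[2], 0.4 * target_rate) / (fs / 2), type = "low")
    X <- t(apply(X, 1, function(x) signal::filtfilt(lp, x)))
    idx <- seq(1L, ncol(X), by = factor)
    X <- X[, idx, drop = FALSE]
  }
  bp <- signal::butter(4, band / (target_rate / 2), type = "pass")
  X <- t(apply(X, 1, function(x) signal::filtfilt(bp, x)))
  ev <- rec$events
  if (nrow(ev)) {
    ev$onset <- pmax(1L, as.integer(ceiling(ev$onset / factor)))
    ev$offset <- pmin(ncol(X), as.integer(floor(ev$offset / factor)))
  }
  recording(X, target_rate, rec$channel_labels, ev)
}

#' Cut a recording into event-delimited segments
#'
#' Returns one sub-recording per event with duration at or above
#' `min_duration_s`; shorter segments (e.g. aborted trials) are dropped and
#' the count reported via a message.
#'
#' @param rec A [recording()].
#' @param min_duration_s Minimum segment length in seconds (default 30 s).
#' @return List of [recording()] objects (possibly empty), each carrying its
#'   originating event as attribute `event_label`.
#' @export
segment_by_events <- function(rec, min_duration_s = 30) {
  stopifnot(inherits(rec, "recording"))
  ev <- rec$events
  if (!nrow(ev)) {
    warning("recording has no events; returning an empty segment list")
    return(list())
  }
  dur <- (ev$offset - ev$onset + 1L) / rec$sample_rate
  keep <- dur >= min_duration_s
  if (any(!keep)) {
    message(sprintf("segment_by_events: discarded %d segment(s) shorter than %g s",
                    sum(!keep), min_duration_s))
  }
  out <- lapply(which(keep), function(i) {
    seg <- recording(rec$data[, ev$onset[i]:ev$offset[i], drop = FALSE],
                     rec$sample_rate, rec$channel_labels)
    attr(seg, "event_label") <- ev$label[i]
    seg
  })
  out
}

#' Welch power spectral density
#'
#' Mean periodogram over Hann-tapered, overlapping segments, one spectrum
#' per channel. Segment means are removed before tapering.
#'
#' @param rec A [recording()] (or a numeric matrix with `sample_rate` given).
#' @param window_s Segment length in seconds (default 2 s, i.e. 0.5 Hz
#'   resolution).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @param sample_rate Required when `rec` is a bare matrix.
#' @return list with `freqs` (Hz) and `psd` (channels x frequencies).
#' @export
welch_psd <- function(rec, window_s = 2, overlap = 0.5, sample_rate = NULL) {
  if (inherits(rec, "recording")) {
    X <- rec$data
    fs <- rec$sample_rate
  } else {
    X <- rec
    fs <- sample_rate
    if (is.null(fs)) stop("sample_rate required for matrix input")
  }
  nwin <- round(window_s * fs)
  if (ncol(X) < nwin) stop("recording shorter than one Welch window")
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, ncol(X) - nwin + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / (nwin + 1))  # Hann
  scale <- sum(w^2) * fs
  n_half <- floor(nwin / 2)
  freqs <- seq_len(n_half) * fs / nwin
  psd <- matrix(0, nrow(X), n_half)
  for (s in starts) {
    seg <- X[, s:(s + nwin - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    seg <- sweep(seg, 2, w, `*`)
    ft <- t(apply(seg, 1, stats::fft))
    if (nrow(X) == 1L) ft <- matrix(ft, nrow = 1L)
    psd <- psd + 2 * abs(ft[, 2:(n_half + 1), drop = FALSE])^2 / scale
  }
  list(freqs = freqs, psd = psd / length(starts))
}

#' Estimate the individual alpha peak frequency by center of gravity
#'
#' Welch PSD averaged over channels; the iAPF is the power-weighted mean
#' frequency over the alpha search window,
#' \eqn{\sum_f P(f) f / \sum_f P(f)}. The COG estimator is robust to split
#' or flat alpha peaks where an argmax is not.
#'
#' @param rest A [recording()] of eyes-closed rest, at least 10 s long.
#' @param alpha_window Numeric length-2 search window in Hz (default
#'   7.5-12.5 Hz).
#' @param channels Optional subset of channel labels to average (default:
#'   all channels).
#' @return An object of class `spectral_profile`: list with `freqs`, `psd`,
#'   `alpha_window`, `iapf`, and `theta_band` (NA if the iAPF does not
#'   support one).
#' @export
estimate_iapf_cog <- function(rest, alpha_window = c(7.5, 12.5), channels = NULL) {
  stopifnot(inherits(rest, "recording"))
  if (rec_duration(rest) < 10) stop("rest recording must be at least 10 s long")
  if (!is.null(channels)) {
    rest <- recording(rest$data[channels, , drop = FALSE], rest$sample_rate, channels)
  }
  pw <- welch_psd(rest)
  mean_psd <- colMeans(pw$psd)
  in_win <- pw$freqs >= alpha_window[1] & pw$freqs <= alpha_window[2]
  if (!any(in_win)) stop("alpha_window contains no PSD bins")
  p <- mean_psd[in_win]
  f <- pw$freqs[in_win]
  if (sum(p) <= 0) stop("zero power in the alpha window")
  iapf <- sum(p * f) / sum(p)
  tb <- if (iapf > 5) theta_band(iapf) else c(NA_real_, NA_real_)
  structure(
    list(freqs = pw$freqs, psd = pw$psd, alpha_window = alpha_window,
         iapf = iapf, theta_band = tb),
    class = "spectral_profile"
  )
}

#' @export
print.spectral_profile <- function(x, ...) {
  cat(sprintf("<spectral_profile> iAPF = %.2f Hz (window %g-%g Hz), theta band %.2f-%.2f Hz\n",
              x$iapf, x$alpha_window[1], x$alpha_window[2],
              x$theta_band[1], x$theta_band[2]))
  invisible(x)
}

#' Session-level iAPF from pre- and post-session rest
#'
#' The session iAPF is the arithmetic mean of the pre- and post-session
#' eyes-closed estimates.
#'
#' @param pre_rest,post_rest `spectral_profile` objects sharing the same
#'   alpha window.
#' @return Numeric scalar, Hz.
#' @export
session_iapf <- function(pre_rest, post_rest) {
  stopifnot(inherits(pre_rest, "spectral_profile"),
            inherits(post_rest, "spectral_profile"))
  if (!isTRUE(all.equal(pre_rest$alpha_window, post_rest$alpha_window))) {
    stop("pre and post profiles must share the same alpha window")
  }
  (pre_rest$iapf + post_rest$iapf) / 2
}

#' Individualized theta band
#'
#' The subject-specific theta band runs from 4 Hz to 0.8 x iAPF, tying its
#' upper edge to the individual alpha peak.
#'
#' @param iapf Individual alpha peak frequency in Hz; must exceed 5 Hz for
#'   the band to be non-degenerate.
#' @return Numeric length-2 (low, high) Hz.
#' @export
theta_band <- function(iapf) {
  if (!is.numeric(iapf) || length(iapf) != 1L || is.na(iapf)) {
    stop("`iapf` must be a single number")
  }
  if (iapf <= 5) {
    stop(sprintf("iAPF of %.2f Hz gives a degenerate theta band (upper edge 0.8*iAPF <= 4 Hz)",
                 iapf))
  }
  c(4, 0.8 * iapf)
}
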