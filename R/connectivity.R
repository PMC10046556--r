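#' Band-limited analytic signals
#'
#' Zero-phase 4th-order Butterworth bandpass to `band`, then the analytic
#' signal via the FFT Hilbert transform, per channel. One second is trimmed
#' from each end to suppress filter and Hilbert edge transients.
#'
#' @param segment A [recording()], already broadband-filtered and decimated.
#' @param band Numeric length-2 (low, high) Hz, e.g. an individualized theta
#'   band from [theta_band()].
#' @param trim_s Seconds trimmed from each end (default 1).
#' @return Complex matrix, channels x samples, with attributes `sample_rate`
#'   and `band`.
#' @export
analytic_signals <- function(segment, band, trim_s = 1) {
  stopifnot(inherits(segment, "recording"))
  fs <- segment$sample_rate
  trim <- round(trim_s * fs)
  n <- ncol(segment$data)
  if (n - 2 * trim < 2 * fs) {
    stop("segment shorter than 2 s after edge trimming")
  }
  if (band[2] >= fs / 2) stop("band upper edge must be below Nyquist")
  bp <- signal::butter(4, band / (fs / 2), type = "pass")
  Z <- matrix(0i, nrow(segment$data), n)
  for (ch in seq_len(nrow(segment$data))) {
    x <- signal::filtfilt(bp, segment$data[ch, ])
    Z[ch, ] <- hilbert_analytic(x)
  }
  Z <- Z[, (trim + 1):(n - trim), drop = FALSE]
  rownames(Z) <- segment$channel_labels
  attr(Z, "sample_rate") <- fs
  attr(Z, "band") <- band
  Z
}

# analytic signal x + i*H(x) via the one-sided FFT spectrum
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Weighted Phase Lag Index of two analytic signals
#'
#' From the per-sample cross-spectrum \eqn{S_{xy,t} = z_x(t)\,\overline{z_y(t)}}:
#' \deqn{wPLI = \left|\frac{\sum_t |Im(S_{xy,t})|\,sgn(Im(S_{xy,t}))}{\sum_t |Im(S_{xy,t})|}\right|}
#' Phase-lead/lag consistency is weighted by the magnitude of the imaginary
#' cross-spectrum, which makes the index insensitive to zero-lag
#' (volume-conducted) coupling. When the imaginary cross-spectrum carries no
#' mass at all (purely zero-lag relation) the index is defined as 0.
#'
#' @param zx,zy Complex vectors of equal length (>= 2), e.g. rows of
#'   [analytic_signals()].
#' @return Scalar in \[0, 1\].
#' @export
wpli <- function(zx, zy) {
  if (length(zx) != length(zy)) stop("zx and zy must have equal length")
  if (length(zx) < 2L) stop("need at least 2 samples")
  im <- Im(zx * Conj(zy))
  den <- sum(abs(im))
  if (den == 0) return(0)
  abs(sum(im)) / den   # sum(|im|*sign(im)) == sum(im)
}

# signed and absolute imaginary cross-spectral sums for pooled aggregation
wpli_terms <- function(zx, zy) {
  im <- Im(zx * Conj(zy))
  c(num = sum(im), den = sum(abs(im)))
}

#' Condition-level wPLI connectivity matrix
#'
#' Computes the wPLI for every channel pair of a condition. With
#' `method = "pool"` (default) the per-sample imaginary cross-spectral terms
#' are pooled across all segments before the ratio is taken — equivalent to
#' concatenating the segments and robust to unequal segment lengths. With
#' `method = "average"` per-segment wPLI values are averaged instead.
#'
#' @param segments List of complex analytic arrays (channels x samples), all
#'   with identical channel order, e.g. several trials of one scenario.
#' @param labels Character channel labels; defaults to the rownames of the
#'   first segment.
#' @param band Numeric length-2 band in Hz (metadata).
#' @param condition Named list or character vector identifying
#'   (subject, test, scenario); metadata carried through to outputs.
#' @param method "pool" or "average".
#' @return Object of class `connectivity_matrix`: list with `values`
#'   (symmetric N x N in \[0,1\], zero diagonal), `channel_labels`, `band`,
#'   `n_samples_used`, `condition`.
#' @export
connectivity_matrix <- function(segments, labels = NULL, band = c(NA, NA),
                                condition = NULL,
                                method = c("pool", "average")) {
  method <- match.arg(method)
  if (!length(segments)) {
    stop(sprintf("no segments for condition %s",
                 paste(unlist(condition), collapse = "/")))
  }
  n_ch <- nrow(segments[[1]])
  if (is.null(labels)) labels <- rownames(segments[[1]])
  if (is.null(labels)) labels <- paste0("ch", seq_len(n_ch))
  V <- matrix(0, n_ch, n_ch, dimnames = list(labels, labels))
  for (i in seq_len(n_ch - 1L)) {
    for (j in (i + 1L):n_ch) {
      if (method == "pool") {
        num <- 0
        den <- 0
        for (seg in segments) {
          tm <- wpli_terms(seg[i, ], seg[j, ])
          num <- num + tm["num"]
          den <- den + tm["den"]
        }
        V[i, j] <- if (den == 0) 0 else abs(num) / den
      } else {
        V[i, j] <- mean(vapply(segments, function(seg) wpli(seg[i, ], seg[j, ]),
                               numeric(1)))
      }
      V[j, i] <- V[i, j]
    }
  }
  structure(
    list(values = V, channel_labels = labels, band = band,
         n_samples_used = sum(vapply(segments, ncol, integer(1))),
         condition = condition),
    class = "connectivity_matrix"
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  ut <- x$values[upper.tri(x$values)]
  cat(sprintf("<connectivity_matrix> %d channels, band %.2g-%.2g Hz, %d samples; wPLI median %.3f [%.3f, %.3f]\n",
              length(x$channel_labels), x$band[1], x$band[2],
              x$n_samples_used, stats::median(ut), min(ut), max(ut)))
  invisible(x)
}
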