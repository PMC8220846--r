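# Filtering and windowing of raw recordings before feature extraction.

#' One Euro filter parameters
#'
#' @param min_cutoff Minimum cutoff frequency in Hz (> 0). Governs
#'   smoothing of slow signals.
#' @param beta Cutoff-per-speed coefficient (>= 0). The instantaneous
#'   cutoff grows linearly with the filtered derivative magnitude, trading
#'   lag for jitter on fast signals.
#' @param d_cutoff Cutoff (Hz) of the low-pass applied to the derivative
#'   estimate.
#' @return A `one_euro_params` object.
#' @export
one_euro_params <- function(min_cutoff = 1, beta = 0.05, d_cutoff = 1) {
  stopifnot(min_cutoff > 0, beta >= 0, d_cutoff > 0)
  structure(list(min_cutoff = min_cutoff, beta = beta, d_cutoff = d_cutoff),
            class = "one_euro_params")
}

# single-pole smoothing coefficient at cutoff fc for sample rate fs:
# alpha = 1 / (1 + fs / (2 pi fc))
euro_alpha <- function(fc, fs) 1 / (1 + fs / (2 * pi * fc))

#' One Euro adaptive low-pass filter
#'
#' First-order causal smoother whose cutoff adapts to signal speed: per
#' sample the derivative estimate is low-passed at `d_cutoff`, then the
#' signal is low-passed at `min_cutoff + beta * |filtered derivative|`.
#' The first sample passes through unchanged. With `beta = 0` this reduces
#' to a fixed-cutoff exponential smoother.
#'
#' @param x Numeric vector, or a matrix filtered column-wise.
#' @param fs Sampling rate in Hz.
#' @param params A [one_euro_params()].
#' @return Filtered signal, same shape as `x`.
#' @export
one_euro_filter <- function(x, fs, params = one_euro_params()) {
  stopifnot(fs > 0)
  if (is.matrix(x))
    return(apply(x, 2, one_euro_filter, fs = fs, params = params))
  if (length(x) < 1L) stop("series must have length >= 1")
  if (any(!is.finite(x))) stop("non-finite samples in input")
  out <- numeric(length(x))
  out[1] <- x[1]
  dx_hat <- 0
  a_d <- euro_alpha(params$d_cutoff, fs)
  for (i in seq_along(x)[-1]) {
    dx <- (x[i] - out[i - 1]) * fs
    dx_hat <- a_d * dx + (1 - a_d) * dx_hat
    fc <- params$min_cutoff + params$beta * abs(dx_hat)
    a <- euro_alpha(fc, fs)
    out[i] <- a * x[i] + (1 - a) * out[i - 1]
  }
  out
}

#' Sliding-window specification
#'
#' @param width Window width in frames; the default 512 frames at 50 Hz
#'   spans roughly ten gait cycles.
#' @param stride Hop between consecutive window starts, in frames.
#' @param window_fn Taper name; only `"hanning"` is defined.
#' @return A `window_spec` object.
#' @export
window_spec <- function(width = 512L, stride = 25L, window_fn = "hanning") {
  stopifnot(width >= 2, stride >= 1)
  structure(list(width = as.integer(width), stride = as.integer(stride),
                 window_fn = match.arg(window_fn, "hanning")),
            class = "window_spec")
}

#' Extract aligned sliding windows from a multichannel series
#'
#' Yields `floor((L - width) / stride) + 1` windows, aligned across all
#' sensor channels; each carries its 1-based start frame.
#'
#' @param x Numeric matrix (frames x sensors) or vector.
#' @param spec A [window_spec()].
#' @return List of `list(start =, data =)` entries, where `data` is a
#'   `width` x sensors matrix.
#' @export
sliding_windows <- function(x, spec = window_spec()) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  L <- nrow(x)
  if (L < spec$width)
    stop("series too short: ", L, " frames < window width ", spec$width)
  starts <- seq.int(1L, L - spec$width + 1L, by = spec$stride)
  lapply(starts, function(s)
    list(start = s, data = x[s:(s + spec$width - 1L), , drop = FALSE]))
}

#' Partition a static recording into fixed-length segments
#'
#' Non-overlapping segments of `segment_length` frames; a trailing
#' remainder shorter than one segment is dropped. A recording shorter than
#' one segment yields an empty list without error.
#'
#' @param x A `pressure_recording` with `section = "static"`, or a numeric
#'   frames x sensors matrix.
#' @param segment_length Segment length in frames (>= 1).
#' @return List of `list(start =, data =)` entries.
#' @export
static_segments <- function(x, segment_length = 100L) {
  if (segment_length < 1) stop("segment_length must be >= 1")
  segment_length <- as.integer(segment_length)
  if (inherits(x, "pressure_recording")) {
    if (x$section != "static") stop("recording is not a static-section recording")
    x <- x$frames
  }
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  n_seg <- nrow(x) %/% segment_length
  if (n_seg == 0L) return(list())
  lapply(seq_len(n_seg), function(k) {
    s <- (k - 1L) * segment_length + 1L
    list(start = s, data = x[s:(s + segment_length - 1L), , drop = FALSE])
  })
}
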