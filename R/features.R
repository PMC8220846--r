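# Gait feature extraction. Dynamic walking windows are tapered, Fourier
# transformed per sensor, and summarised as band magnitude sums over
# (0,2], (2,4], (4,6], (6,8], (8,10] Hz -- the DC bin is excluded and the
# concatenated vector is normalised to unit length so that bodyweight
# cancels. Static standing segments keep only the DC (time-mean) pressure
# per sensor, again unit-normalised.

#' Default 30-cell sensor mask
#'
#' The thirty on-foot cells of [foot_region_map()] in fixed row-major
#' order: a 3x2 heel block, the four medial and four lateral in-mask
#' midfoot cells, and sixteen forefoot cells. Rows and columns are
#' 1-based.
#'
#' @return Integer matrix with columns `row`, `col`, 30 rows.
#' @export
default_sensor_mask <- function() {
  rm <- foot_region_map()
  keep <- rm != "off_foot" & !(rm %in% c("medial_midfoot", "lateral_midfoot") &
                                 col(rm) %in% c(2L, 7L))
  idx <- which(t(keep))                     # row-major order
  m <- cbind(row = (idx - 1L) %/% 8L + 1L, col = (idx - 1L) %% 8L + 1L)
  storage.mode(m) <- "integer"
  m
}

validate_mask <- function(mask) {
  if (!is.matrix(mask) || ncol(mask) != 2L) stop("mask must be an n x 2 matrix")
  if (any(mask < 1L) || any(mask > 8L)) stop("mask indices must lie in 1..8")
  if (anyDuplicated(paste(mask[, 1], mask[, 2]))) stop("mask indices must be unique")
  mask
}

#' Frequency-band specification
#'
#' Ordered half-open intervals (lo, hi] in Hz. The default five bands
#' cover 0--10 Hz in 2 Hz steps; the 0 Hz bin itself never contributes.
#'
#' @param bands Numeric matrix with columns `lo`, `hi`.
#' @return Validated band matrix.
#' @export
band_spec <- function(bands = cbind(lo = c(0, 2, 4, 6, 8),
                                    hi = c(2, 4, 6, 8, 10))) {
  if (!is.matrix(bands) || ncol(bands) != 2L) stop("bands must be an n x 2 matrix")
  if (any(bands[, 2] <= bands[, 1])) stop("each band needs hi > lo")
  if (nrow(bands) > 1L && any(bands[-1L, 1] < bands[-nrow(bands), 2]))
    stop("bands must be non-overlapping and ascending")
  if (bands[1L, 1] != 0) stop("first band must start at 0 (DC excluded)")
  colnames(bands) <- c("lo", "hi")
  bands
}

#' Hann taper
#'
#' @param n Length.
#' @return Numeric vector `0.5 * (1 - cos(2 pi k / (n - 1)))`, k = 0..n-1.
#' @export
hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

#' Magnitude spectrum of one sensor window
#'
#' Applies the Hann taper when flagged and returns the DFT magnitudes
#' `|S(k)|`, k = 0..L-1, for the fixed analysis length L = 512.
#'
#' @param window Numeric vector of length `expected_length`.
#' @param apply_hann Apply the Hann taper before transforming.
#' @param expected_length Required window length.
#' @return Numeric magnitude vector of the same length.
#' @export
dft_magnitude <- function(window, apply_hann = TRUE, expected_length = 512L) {
  if (length(window) != expected_length)
    stop("window length ", length(window), " != required ", expected_length)
  if (any(!is.finite(window))) stop("non-finite samples in window")
  if (apply_hann) window <- window * hann_window(length(window))
  Mod(stats::fft(window))
}

#' Band magnitude sums of a spectrum
#'
#' For each band (lo, hi], sums the one-sided bin magnitudes with
#' frequency `f = k * fs / L` satisfying `lo < f <= hi`, over
#' k = 1..L/2 only; the DC bin k = 0 never contributes.
#'
#' @param spectrum Magnitude spectrum from [dft_magnitude()].
#' @param bands A [band_spec()].
#' @param fs Sampling rate in Hz.
#' @return Numeric vector with one entry per band.
#' @export
band_energies <- function(spectrum, bands = band_spec(), fs = 50) {
  stopifnot(fs > 0)
  if (any(bands[, "hi"] > fs / 2 + 1e-9))
    stop("band extends above the Nyquist frequency ", fs / 2, " Hz")
  L <- length(spectrum)
  k <- seq_len(L %/% 2)            # one-sided, DC excluded
  f <- k * fs / L
  vapply(seq_len(nrow(bands)), function(b) {
    sum(spectrum[k[f > bands[b, "lo"] & f <= bands[b, "hi"]] + 1L])
  }, numeric(1))
}

finalize_feature <- function(v, label = NULL, subject_id = NULL,
                             section = NULL) {
  nrm <- sqrt(sum(v^2))
  all_zero <- nrm == 0
  if (all_zero) warning("all-zero raw feature vector; returning zeros")
  else v <- v / nrm
  attr(v, "all_zero") <- all_zero
  attr(v, "label") <- label
  attr(v, "subject_id") <- subject_id
  attr(v, "section") <- section
  v
}

#' Dynamic-section feature vector of one window
#'
#' Concatenates the per-sensor band magnitude sums of the masked sensors
#' in mask order (|mask| x |bands| elements; 150 with defaults) and
#' normalises to unit L2 norm. An all-zero raw vector is returned as
#' zeros with attribute `all_zero = TRUE` and a warning.
#'
#' @param window Numeric matrix, 512 frames x 64 sensors (row-major cell
#'   columns, as in recording frames).
#' @param mask Sensor mask, see [default_sensor_mask()].
#' @param bands A [band_spec()].
#' @param fs Sampling rate in Hz.
#' @param apply_hann Apply the Hann taper per sensor.
#' @return Unit-norm numeric feature vector.
#' @export
extract_dynamic <- function(window, mask = default_sensor_mask(),
                            bands = band_spec(), fs = 50, apply_hann = TRUE) {
  mask <- validate_mask(mask)
  if (!is.matrix(window)) stop("window must be a frames x sensors matrix")
  cols <- cell_index(mask[, 1], mask[, 2])
  if (max(cols) > ncol(window)) stop("window is missing masked sensor columns")
  v <- as.vector(vapply(cols, function(cc) {
    band_energies(dft_magnitude(window[, cc], apply_hann = apply_hann,
                                expected_length = nrow(window)),
                  bands, fs)
  }, numeric(nrow(bands))))
  finalize_feature(v)
}

#' Static-section feature vector of one segment
#'
#' Per masked sensor, the time-mean pressure of the segment (its DC
#' component), concatenated in mask order and L2-normalised; 30 elements
#' with the default mask.
#'
#' @param segment Numeric matrix, frames x 64 sensors, non-empty.
#' @param mask Sensor mask.
#' @return Unit-norm numeric feature vector.
#' @export
extract_static <- function(segment, mask = default_sensor_mask()) {
  mask <- validate_mask(mask)
  if (!is.matrix(segment) || nrow(segment) < 1L)
    stop("segment must be a non-empty frames x sensors matrix")
  cols <- cell_index(mask[, 1], mask[, 2])
  if (max(cols) > ncol(segment)) stop("segment is missing masked sensor columns")
  finalize_feature(colMeans(segment[, cols, drop = FALSE]))
}

#' Feature table of a dataset of recordings
#'
#' Applies the section-appropriate extractor to every window (dynamic) or
#' segment (static) of every recording and assembles the samples into one
#' data frame with feature columns `f1..fD`, `label`, `subject_id`,
#' `section` and `window_start`.
#'
#' @param dataset A `gait_dataset` from [make_dataset()], or a plain list
#'   of `pressure_recording` objects.
#' @param mask,bands Feature configuration.
#' @param stride Dynamic window stride; defaults to the dataset's.
#' @param segment_length Static segment length; defaults to the dataset's.
#' @param filter_params Optional [one_euro_params()]; when supplied each
#'   sensor channel is One-Euro filtered before extraction (off by
#'   default: the filter serves display smoothing, not classification).
#' @return Data frame of labelled feature vectors.
#' @export
extract_features <- function(dataset, mask = default_sensor_mask(),
                             bands = band_spec(), stride = NULL,
                             segment_length = NULL, filter_params = NULL) {
  recs <- if (inherits(dataset, "gait_dataset")) dataset$recordings else dataset
  if (is.null(stride))
    stride <- if (inherits(dataset, "gait_dataset")) dataset$stride else 25L
  if (is.null(segment_length))
    segment_length <- if (inherits(dataset, "gait_dataset"))
      dataset$segment_length else 100L
  rows <- list()
  for (rec in recs) {
    frames <- rec$frames
    if (!is.null(filter_params))
      frames <- one_euro_filter(frames, rec$fs, filter_params)
    if (rec$section == "dynamic") {
      wins <- sliding_windows(frames, window_spec(width = 512L, stride = stride))
      feats <- lapply(wins, function(w)
        extract_dynamic(w$data, mask, bands, fs = rec$fs))
    } else {
      wins <- static_segments(frames, segment_length)
      feats <- lapply(wins, function(w) extract_static(w$data, mask))
    }
    if (length(feats) == 0L) next
    fm <- do.call(rbind, feats)
    df <- as.data.frame(fm)
    names(df) <- paste0("f", seq_len(ncol(fm)))
    df$label <- rec$label
    df$subject_id <- rec$subject$subject_id
    df$section <- rec$section
    df$window_start <- vapply(wins, `[[`, integer(1), "start")
    rows[[length(rows) + 1L]] <- df
  }
  if (length(rows) == 0L) {
    warning("no extractable samples in input")
    return(data.frame())
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$label <- as_gait_factor(out$label)
  out
}

# split a feature data frame into x matrix / y factor
feature_xy <- function(features) {
  fcols <- grep("^f[0-9]+$", names(features), value = TRUE)
  fcols <- fcols[order(as.integer(sub("^f", "", fcols)))]
  list(x = as.matrix(features[, fcols, drop = FALSE]),
       y = as_gait_factor(features$label))
}
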