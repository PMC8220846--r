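# Plain-text serialisation: recordings as CSV frames (t, r0c0..r7c7)
# with a JSON sidecar for metadata, feature tables as CSV, fitted models
# and calibration tables as JSON.

#' Write a recording to CSV + JSON sidecar
#'
#' The CSV has one row per frame with columns `t, r0c0..r7c7` (row-major
#' integer-count or kPa values); the sidecar `<path>.json` carries the
#' subject parameters, label, section and sampling rate.
#'
#' @param rec A `pressure_recording`.
#' @param path CSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  df <- data.frame(t = rec$t, rec$frames, check.names = FALSE)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(subject = unclass(rec$subject), label = rec$label,
               section = rec$section, fs = rec$fs)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' Validates monotone timestamps and that the sidecar sampling rate
#' agrees with the timestamps within 1%.
#'
#' @param path CSV path; sidecar expected at `<path>.json`.
#' @return A `pressure_recording`.
#' @export
read_recording <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  t <- as.numeric(df$t)
  if (any(diff(t) <= 0)) stop("timestamps are not strictly increasing")
  fs_obs <- 1 / stats::median(diff(t))
  if (abs(fs_obs - meta$fs) / meta$fs > 0.01)
    stop(sprintf("sampling rate %.3f Hz inconsistent with sidecar fs = %g Hz",
                 fs_obs, meta$fs))
  frames <- as.matrix(df[, -1, drop = FALSE])
  sub <- meta$subject
  subject <- subject_params(sub$subject_id, sub$mass, sub$cadence,
                            sub$fpa, sub$diagnosis)
  new_recording(t, unname(frames), meta$fs, subject, meta$label, meta$section)
}

#' Write a feature table to CSV
#'
#' @param features Feature data frame from [extract_features()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  out <- features
  fcols <- grep("^f[0-9]+$", names(out))
  for (j in fcols) out[[j]] <- format(out[[j]], digits = 17, trim = TRUE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_features()]
#'
#' @param path CSV path.
#' @return Feature data frame with canonical label factor.
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("label" %in% names(df)) df$label <- as_gait_factor(df$label)
  df
}

mat_to_list <- function(m) list(dim = dim(m), data = as.vector(m))
list_to_mat <- function(l) {
  d <- unlist(l$data)
  if (is.null(d)) d <- numeric(0)
  matrix(d, l$dim[[1]], l$dim[[2]])
}

#' Serialise a fitted model to JSON
#'
#' Supports `gait_pca`, `gait_lda`, `gait_svm` and `gait_nn` fits;
#' matrices are stored column-major with explicit shape metadata and full
#' floating precision, so a write/read round trip is lossless to within
#' 1e-12.
#'
#' @param model A supported fit.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  cls <- class(model)[1]
  payload <- switch(cls,
    gait_pca = list(mean = model$mean, rotation = mat_to_list(model$rotation),
                    ratios = model$ratios, n_components = model$n_components,
                    variance_target = model$variance_target),
    gait_lda = list(W = mat_to_list(model$W), mean = model$mean,
                    class_means = mat_to_list(model$class_means),
                    classes = model$classes, d = model$d),
    gait_svm = list(classes = model$classes,
                    kernel = unclass(model$kernel), gamma = model$gamma,
                    C = model$C, tol = model$tol,
                    n_features = model$n_features,
                    binaries = lapply(model$binaries, function(b)
                      list(pair = b$pair, sv = mat_to_list(b$sv),
                           coef = b$coef, alpha = b$alpha, y_sv = b$y_sv,
                           b = b$b))),
    gait_nn = list(W1 = mat_to_list(model$W1), b1 = model$b1,
                   W2 = mat_to_list(model$W2), b2 = model$b2,
                   classes = model$classes, hidden = model$hidden),
    stop("unsupported model class: ", cls))
  jsonlite::write_json(list(class = cls, model = payload), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path JSON path.
#' @return The reconstructed fit.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  m <- obj$model
  switch(obj$class,
    gait_pca = structure(list(mean = m$mean,
                              rotation = list_to_mat(m$rotation),
                              ratios = m$ratios,
                              n_components = m$n_components,
                              variance_target = m$variance_target),
                         class = "gait_pca"),
    gait_lda = structure(list(W = list_to_mat(m$W), mean = m$mean,
                              class_means = list_to_mat(m$class_means),
                              classes = m$classes, d = m$d),
                         class = "gait_lda"),
    gait_svm = {
      binaries <- lapply(m$binaries, function(b)
        list(pair = unlist(b$pair), sv = list_to_mat(b$sv),
             coef = unlist(b$coef), alpha = unlist(b$alpha),
             y_sv = unlist(b$y_sv), b = b$b))
      structure(list(binaries = binaries, classes = m$classes,
                     kernel = structure(list(kind = m$kernel$kind,
                                             gamma = m$kernel$gamma),
                                        class = "kernel_spec"),
                     gamma = m$gamma, C = m$C, tol = m$tol,
                     n_features = m$n_features),
                class = "gait_svm")
    },
    gait_nn = structure(list(W1 = list_to_mat(m$W1), b1 = m$b1,
                             W2 = list_to_mat(m$W2), b2 = m$b2,
                             classes = m$classes, hidden = m$hidden),
                        class = "gait_nn"),
    stop("unsupported model class in file: ", obj$class))
}

#' Write calibration lines for all cells as a JSON table
#'
#' @param calibrations Named list of `calibration_line` objects keyed by
#'   cell index (e.g. `"r0c0"`).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(calibrations, path) {
  jsonlite::write_json(lapply(calibrations, unclass), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
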