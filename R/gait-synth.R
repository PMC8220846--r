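# Labelled synthetic plantar-pressure generator. Spatial load templates on
# the 8x8 grid are derived from published regional load-shift percentages
# (in-toeing amplifies lateral midfoot/forefoot loading by up to 61%/49%,
# out-toeing the medial aspects by up to 72%/52%; flat foot enlarges the
# midfoot contact area); temporal structure is a heel-to-toe sequence of
# raised-cosine activation bumps over a 60% stance phase.

FOOT_REGIONS <- c("medial_forefoot", "lateral_forefoot", "medial_midfoot",
                  "lateral_midfoot", "heel", "off_foot")

#' Anatomical region map of the 8x8 sensor grid
#'
#' Assigns every cell to one of heel, medial/lateral midfoot,
#' medial/lateral forefoot, or off-foot. Rows run heel (row 1) to toes
#' (row 8); columns run medial (col 1) to lateral (col 8). Off-foot cells
#' carry zero pressure in every template.
#'
#' @return 8x8 character matrix of region names.
#' @export
foot_region_map <- function() {
  m <- matrix("off_foot", 8, 8)
  m[1:3, 4:5] <- "heel"
  m[4:5, 2:4] <- "medial_midfoot"
  m[4:5, 5:7] <- "lateral_midfoot"
  m[6:7, 2:4] <- "medial_forefoot"
  m[8, 3:4] <- "medial_forefoot"
  m[6:7, 5:7] <- "lateral_forefoot"
  m[8, 5:6] <- "lateral_forefoot"
  m
}

# normal-foot spatial load shares: heel-dominant, arched medial midfoot
# (outer midfoot columns 2 and 7 unloaded -- the flat template fills them)
normal_template_weights <- function(region_map = foot_region_map()) {
  w <- matrix(0, 8, 8)
  w[1:3, 4:5] <- 0.45 / 6
  w[4:5, 3:4] <- 0.04 / 4          # medial midfoot (arch barely touching)
  w[4:5, 5:6] <- 0.11 / 4          # lateral midfoot
  w[region_map == "medial_forefoot"] <- 0.22 / 8
  w[region_map == "lateral_forefoot"] <- 0.18 / 8
  w
}

#' Build the spatial load template for a gait class
#'
#' Starting from the normal template, toe-in multiplies the lateral midfoot
#' weights by 1.61 and the lateral forefoot by 1.49 before renormalisation;
#' toe-out multiplies the medial midfoot by 1.72 and the medial forefoot by
#' 1.52; the flat template activates every midfoot cell of the region map
#' (more nonzero midfoot cells than normal) and raises the midfoot share to
#' 0.30 of body load. Weights always renormalise to sum 1.
#'
#' @param label One of [gait_classes()].
#' @param region_map Region assignment, see [foot_region_map()].
#' @param base Normal template weights (8x8, summing to 1).
#' @return A `foot_template`: list with `label` and 8x8 `weights`.
#' @export
make_template <- function(label, region_map = foot_region_map(),
                          base = normal_template_weights(region_map)) {
  if (!label %in% gait_classes()) stop("unknown gait label: ", label)
  w <- base
  if (label == "toe_in") {
    w[region_map == "lateral_midfoot"] <- w[region_map == "lateral_midfoot"] * 1.61
    w[region_map == "lateral_forefoot"] <- w[region_map == "lateral_forefoot"] * 1.49
  } else if (label == "toe_out") {
    w[region_map == "medial_midfoot"] <- w[region_map == "medial_midfoot"] * 1.72
    w[region_map == "medial_forefoot"] <- w[region_map == "medial_forefoot"] * 1.52
  } else if (label == "flat") {
    mid <- region_map %in% c("medial_midfoot", "lateral_midfoot")
    rest <- !mid & region_map != "off_foot"
    w[mid] <- 0.30 / sum(mid)
    w[rest] <- w[rest] * 0.70 / sum(w[rest])
  }
  w <- w / sum(w)
  structure(list(label = label, weights = w), class = "foot_template")
}

#' Subject parameters
#'
#' @param subject_id Identifier string.
#' @param mass Body mass in kg (> 0).
#' @param cadence Step rate in steps/s (two steps per gait cycle); typical
#'   children walk at about 1.5--2.5 steps/s.
#' @param fpa Foot progression angle in degrees; if `NULL`, a typical value
#'   for the diagnosis is filled in (+10 normal/flat, -10 toe-in, +30
#'   toe-out). Must be consistent with the label: normal within
#'   \[-3, +20\] degrees, toe-in below -3, toe-out above +20.
#' @param diagnosis Gait class label.
#' @return A `subject_params` object.
#' @export
subject_params <- function(subject_id, mass, cadence = 2.0, fpa = NULL,
                           diagnosis = "normal") {
  if (!diagnosis %in% gait_classes()) stop("unknown gait label: ", diagnosis)
  stopifnot(is.numeric(mass), mass > 0, is.numeric(cadence), cadence > 0)
  if (is.null(fpa))
    fpa <- switch(diagnosis, normal = 10, flat = 10, toe_in = -10, toe_out = 30)
  ok <- switch(diagnosis,
               normal = fpa >= -3 && fpa <= 20,
               flat = TRUE,
               toe_in = fpa < -3,
               toe_out = fpa > 20)
  if (!ok) stop("foot progression angle ", fpa,
                " inconsistent with diagnosis '", diagnosis, "'")
  structure(list(subject_id = as.character(subject_id), mass = mass,
                 cadence = cadence, fpa = fpa, diagnosis = diagnosis),
            class = "subject_params")
}

#' Simulation configuration
#'
#' @param fs Sampling rate in Hz.
#' @param duration Recording length in seconds.
#' @param noise_sd Per-cell, per-frame sensor noise standard deviation (kPa).
#' @param seed Integer RNG seed; `NULL` leaves the RNG state alone.
#' @param section `"dynamic"` (walking) or `"static"` (standing).
#' @return A `sim_config` object. Dynamic recordings meant for feature
#'   extraction need `duration * fs >= 512`.
#' @export
sim_config <- function(fs = 50, duration = 12, noise_sd = 2, seed = NULL,
                       section = c("dynamic", "static")) {
  section <- match.arg(section)
  stopifnot(fs > 0, duration > 0, noise_sd >= 0)
  structure(list(fs = fs, duration = duration, noise_sd = noise_sd,
                 seed = seed, section = section),
            class = "sim_config")
}

# raised-cosine activation bump, centred at cc with half-width w, on [0,1]
rc_bump <- function(u, cc, w) {
  out <- numeric(length(u))
  inside <- abs(u - cc) < w
  out[inside] <- cos(pi / 2 * (u[inside] - cc) / w)^2
  out
}

# per-region stance-phase envelope timing (fractions of stance)
REGION_TIMING <- list(
  heel             = c(centre = 0.15, width = 0.30),
  medial_midfoot   = c(centre = 0.45, width = 0.35),
  lateral_midfoot  = c(centre = 0.45, width = 0.35),
  medial_forefoot  = c(centre = 0.80, width = 0.30),
  lateral_forefoot = c(centre = 0.80, width = 0.30)
)

STANCE_FRACTION <- 0.6   # stance occupies 60% of the gait cycle
CELL_AREA_M2 <- 2.5e-4   # sensing area per cell
DYNAMIC_LOAD_FACTOR <- 1.8  # peak regional load in bodyweight multiples

new_recording <- function(t, frames, fs, subject, label, section) {
  colnames(frames) <- as.vector(t(outer(0:7, 0:7,
                                        function(r, c) sprintf("r%dc%d", r, c))))
  structure(list(t = t, frames = frames, fs = fs, subject = subject,
                 label = label, section = section),
            class = "pressure_recording")
}

#' @export
print.pressure_recording <- function(x, ...) {
  cat(sprintf("Plantar-pressure recording: %s section, %d frames @ %g Hz\n",
              x$section, nrow(x$frames), x$fs))
  cat(sprintf("  subject %s (%s), peak pressure %.1f kPa\n",
              x$subject$subject_id, x$label, max(x$frames)))
  invisible(x)
}

# frames matrix column index of grid cell (i, j), 1-based, row-major
cell_index <- function(i, j) (i - 1L) * 8L + j

#' Synthesise a dynamic (walking) recording
#'
#' Produces a gait-cycle-periodic 8x8 pressure sequence: stance occupies
#' 60% of each cycle, within which heel, midfoot and forefoot regions are
#' activated in order by raised-cosine envelopes; swing carries no load.
#' The instantaneous grid is the mass-scaled spatial template modulated by
#' the regional envelope, plus truncated Gaussian sensor noise; pressures
#' are clipped to \[0, 700\] kPa. The gait-cycle rate is `cadence / 2`
#' (two steps per cycle), so the default 2 steps/s gives roughly ten
#' cycles per 512-sample window at 50 Hz.
#'
#' @param subject A [subject_params()].
#' @param template A `foot_template`; defaults to the subject's diagnosis.
#' @param cfg A [sim_config()] with `section = "dynamic"`.
#' @return A `pressure_recording`.
#' @export
synth_dynamic <- function(subject, template = NULL,
                          cfg = sim_config(section = "dynamic")) {
  if (cfg$section != "dynamic") stop("cfg$section must be 'dynamic'")
  if (is.null(template)) template <- make_template(subject$diagnosis)
  cycle_hz <- subject$cadence / 2
  n <- round(cfg$duration * cfg$fs)
  if (n < cfg$fs / cycle_hz)
    stop("duration too short for one full gait cycle")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  t <- (seq_len(n) - 1) / cfg$fs
  period <- cfg$fs / cycle_hz
  # integer frame periods are made exactly periodic (no edge jitter from
  # accumulated floating-point phase)
  phase <- if (abs(period - round(period)) < 1e-9)
    ((seq_len(n) - 1) %% round(period)) / round(period)
  else (t * cycle_hz) %% 1
  u <- phase / STANCE_FRACTION          # position within stance
  in_stance <- phase < STANCE_FRACTION
  region_map <- foot_region_map()
  # per-frame envelope for each region
  env <- sapply(names(REGION_TIMING), function(rg) {
    e <- rc_bump(u, REGION_TIMING[[rg]]["centre"], REGION_TIMING[[rg]]["width"])
    e * in_stance
  })
  base_kpa <- subject$mass * 9.80665 * DYNAMIC_LOAD_FACTOR / CELL_AREA_M2 / 1000
  frames <- matrix(0, n, 64)
  for (i in 1:8) for (j in 1:8) {
    rg <- region_map[i, j]
    if (rg == "off_foot") next
    frames[, cell_index(i, j)] <- base_kpa * template$weights[i, j] * env[, rg]
  }
  if (cfg$noise_sd > 0)
    frames <- frames + matrix(stats::rnorm(n * 64, 0, cfg$noise_sd), n, 64)
  frames[] <- pmin(pmax(frames, 0), 700)
  frames[, region_map[cbind(rep(1:8, each = 8), rep(1:8, 8))] == "off_foot"] <- 0
  new_recording(t, frames, cfg$fs, subject, template$label, "dynamic")
}

#' Synthesise a static (standing) recording
#'
#' Quasi-constant grid: the mass-scaled spatial template, optionally
#' perturbed once per trial by log-normal per-region posture jitter (a
#' child standing unnaturally), modulated by a slow anterior-posterior sway
#' oscillation, plus truncated Gaussian sensor noise.
#'
#' @inheritParams synth_dynamic
#' @param cfg A [sim_config()] with `section = "static"`.
#' @param sway_hz,sway_amp Sway frequency (Hz) and relative amplitude; the
#'   sway shifts load between heel (-) and forefoot (+).
#' @param posture_sd Standard deviation of the per-region log-normal
#'   posture jitter applied once for the whole trial; 0 disables it.
#' @return A `pressure_recording`.
#' @export
synth_static <- function(subject, template = NULL,
                         cfg = sim_config(duration = 10, section = "static"),
                         sway_hz = 0.25, sway_amp = 0.03, posture_sd = 0) {
  if (cfg$section != "static") stop("cfg$section must be 'static'")
  if (is.null(template)) template <- make_template(subject$diagnosis)
  n <- round(cfg$duration * cfg$fs)
  if (n < 1L) stop("duration too short")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  region_map <- foot_region_map()
  w <- template$weights
  if (posture_sd > 0) {
    regions <- setdiff(FOOT_REGIONS, "off_foot")
    fac <- stats::setNames(exp(stats::rnorm(length(regions), 0, posture_sd)),
                           regions)
    for (rg in regions) w[region_map == rg] <- w[region_map == rg] * fac[[rg]]
    w <- w / sum(w)
  }
  t <- (seq_len(n) - 1) / cfg$fs
  sway <- sway_amp * sin(2 * pi * sway_hz * t)
  # heel rows rock opposite to forefoot rows
  sway_sign <- matrix(0, 8, 8)
  sway_sign[region_map == "heel"] <- -1
  sway_sign[region_map %in% c("medial_forefoot", "lateral_forefoot")] <- 1
  base_kpa <- subject$mass * 9.80665 / CELL_AREA_M2 / 1000
  frames <- matrix(0, n, 64)
  for (i in 1:8) for (j in 1:8) {
    if (region_map[i, j] == "off_foot") next
    frames[, cell_index(i, j)] <-
      base_kpa * w[i, j] * (1 + sway * sway_sign[i, j])
  }
  if (cfg$noise_sd > 0)
    frames <- frames + matrix(stats::rnorm(n * 64, 0, cfg$noise_sd), n, 64)
  frames[] <- pmin(pmax(frames, 0), 1000)
  frames[, as.vector(region_map[cbind(rep(1:8, each = 8), rep(1:8, 8))]) == "off_foot"] <- 0
  new_recording(t, frames, cfg$fs, subject, template$label, "static")
}

#' Default study cohort
#'
#' Seventeen child subjects with the diagnosis mix of the motivating study
#' (nine flat, four normal, two toe-in, two toe-out), masses from the
#' paediatric estimate 2 x age + 8 kg, and slightly varied cadences.
#'
#' @return List of [subject_params()] objects.
#' @export
default_cohort <- function() {
  ages <- c(6, 10, 8, 9, 10, 7, 9, 9, 10, 8, 5, 6, 6, 8, 9, 8, 9)
  diagnoses <- c(rep("flat", 9), rep("normal", 4),
                 rep("toe_in", 2), rep("toe_out", 2))
  cadences <- 1.8 + 0.1 * (seq_along(ages) %% 5)
  mapply(function(i, age, dx, cad) {
    subject_params(sprintf("s%02d", i), mass = 2 * age + 8,
                   cadence = cad, diagnosis = dx)
  }, seq_along(ages), ages, diagnoses, cadences, SIMPLIFY = FALSE)
}

#' Generate a balanced labelled dataset of recordings
#'
#' Plans recording durations so that downstream windowing (dynamic:
#' 512-frame sliding windows at the given stride; static: non-overlapping
#' segments) yields exactly `n_per_class` samples per gait class, splits
#' them as evenly as possible across the subjects of each class, and
#' synthesises one recording per subject per class with subject-specific
#' template individuality. Fully deterministic under `seed`.
#'
#' @param n_per_class Samples (windows/segments) required per class.
#' @param subjects List of [subject_params()]; every class needs at least
#'   one subject. Defaults to [default_cohort()].
#' @param cfg A [sim_config()] setting section, rate and noise; its
#'   `duration` is ignored (computed per recording) and its `seed` is
#'   superseded by `seed`.
#' @param seed Master RNG seed.
#' @param stride Dynamic window stride in frames.
#' @param segment_length Static segment length in frames.
#' @param subject_sd Between-subject log-normal template jitter (sd of the
#'   per-region log factor); models individual walking patterns.
#' @param posture_sd Static-trial posture jitter, see [synth_static()].
#' @return A `gait_dataset`: list of recordings plus a manifest data frame
#'   and the windowing parameters used to plan it.
#' @export
make_dataset <- function(n_per_class, subjects = default_cohort(),
                         cfg = sim_config(section = "dynamic"), seed = 1,
                         stride = 25, segment_length = 100,
                         subject_sd = 0.05, posture_sd = 0.1) {
  stopifnot(n_per_class >= 1)
  diagnoses <- vapply(subjects, function(s) s$diagnosis, character(1))
  missing <- setdiff(gait_classes(), diagnoses)
  if (length(missing) > 0L)
    stop("no subject for class(es): ", paste(missing, collapse = ", "))
  set.seed(seed)
  region_map <- foot_region_map()
  regions <- setdiff(FOOT_REGIONS, "off_foot")
  recordings <- list()
  manifest <- list()
  for (cl in gait_classes()) {
    subs <- subjects[diagnoses == cl]
    ns <- length(subs)
    # spread n_per_class samples across subjects, difference at most 1
    per_sub <- rep(n_per_class %/% ns, ns)
    extra <- n_per_class %% ns
    if (extra > 0L) per_sub[seq_len(extra)] <- per_sub[seq_len(extra)] + 1L
    for (si in seq_along(subs)) {
      if (per_sub[si] == 0L) next
      sub <- subs[[si]]
      base <- make_template(cl)
      w <- base$weights
      if (subject_sd > 0) {
        fac <- exp(stats::rnorm(length(regions), 0, subject_sd))
        for (k in seq_along(regions))
          w[region_map == regions[k]] <- w[region_map == regions[k]] * fac[k]
        w <- w / sum(w)
      }
      tpl <- structure(list(label = cl, weights = w), class = "foot_template")
      rec_seed <- sample.int(.Machine$integer.max, 1)
      if (cfg$section == "dynamic") {
        frames_needed <- 512L + (per_sub[si] - 1L) * stride
        rcfg <- sim_config(fs = cfg$fs, duration = frames_needed / cfg$fs,
                           noise_sd = cfg$noise_sd, seed = rec_seed,
                           section = "dynamic")
        rec <- synth_dynamic(sub, tpl, rcfg)
      } else {
        frames_needed <- per_sub[si] * segment_length
        rcfg <- sim_config(fs = cfg$fs, duration = frames_needed / cfg$fs,
                           noise_sd = cfg$noise_sd, seed = rec_seed,
                           section = "static")
        rec <- synth_static(sub, tpl, rcfg, posture_sd = posture_sd)
      }
      recordings[[length(recordings) + 1L]] <- rec
      manifest[[length(manifest) + 1L]] <- data.frame(
        subject_id = sub$subject_id, label = cl, section = cfg$section,
        n_samples = per_sub[si], frames = frames_needed, seed = rec_seed,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(recordings = recordings,
                 manifest = do.call(rbind, manifest),
                 section = cfg$section, fs = cfg$fs,
                 stride = stride, segment_length = segment_length),
            class = "gait_dataset")
}

#' @export
print.gait_dataset <- function(x, ...) {
  cat(sprintf("Synthetic gait dataset: %s section, %d recordings, %d planned samples\n",
              x$section, length(x$recordings), sum(x$manifest$n_samples)))
  print(stats::aggregate(n_samples ~ label, x$manifest, sum))
  invisible(x)
}
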