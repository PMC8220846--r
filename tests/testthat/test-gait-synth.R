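test_that("class templates encode the published regional load shifts", {
  rm <- foot_region_map()
  base <- gaitpress:::normal_template_weights(rm)
  tin <- make_template("toe_in")
  tout <- make_template("toe_out")
  tfl <- make_template("flat")
  tnorm <- make_template("normal")
  # normal label is the identity on the base template
  expect_equal(tnorm$weights, base)
  # pre-normalisation regional shares: recover by undoing the renorm
  pre_in <- tin$weights * sum(base +
    0.61 * base * (rm == "lateral_midfoot") +
    0.49 * base * (rm == "lateral_forefoot"))
  expect_equal(sum(pre_in[rm == "lateral_midfoot"]),
               1.61 * sum(base[rm == "lateral_midfoot"]), tolerance = 1e-9)
  expect_equal(sum(pre_in[rm == "lateral_forefoot"]),
               1.49 * sum(base[rm == "lateral_forefoot"]), tolerance = 1e-9)
  pre_out <- tout$weights * sum(base +
    0.72 * base * (rm == "medial_midfoot") +
    0.52 * base * (rm == "medial_forefoot"))
  expect_equal(sum(pre_out[rm == "medial_midfoot"]),
               1.72 * sum(base[rm == "medial_midfoot"]), tolerance = 1e-9)
  # every template sums to 1 with zero off-foot weight
  for (t in list(tnorm, tin, tout, tfl)) {
    expect_equal(sum(t$weights), 1, tolerance = 1e-9)
    expect_true(all(t$weights[rm == "off_foot"] == 0))
  }
  # flat activates strictly more midfoot cells than normal
  mid <- rm %in% c("medial_midfoot", "lateral_midfoot")
  expect_gt(sum(tfl$weights[mid] > 0), sum(base[mid] > 0))
  # class templates pairwise distinct
  tpls <- list(tnorm, tin, tout, tfl)
  for (i in 1:3) for (j in (i + 1):4)
    expect_gt(sqrt(sum((tpls[[i]]$weights - tpls[[j]]$weights)^2)), 0)
  expect_error(make_template("limp"), "unknown")
})

test_that("dynamic synthesis is periodic, bounded and band-limited", {
  s <- subject_params("p1", mass = 40, cadence = 2, diagnosis = "normal")
  rec <- synth_dynamic(s, cfg = sim_config(duration = 12, noise_sd = 0))
  period <- 50 / (s$cadence / 2)  # frames per gait cycle
  expect_equal(rec$frames[1:(nrow(rec$frames) - period), ],
               rec$frames[(period + 1):nrow(rec$frames), ])
  expect_true(all(rec$frames >= 0 & rec$frames <= 700))
  # heaviest subject in the default cohort still stays below 700 kPa
  heavy <- subject_params("p2", mass = 60, diagnosis = "toe_out")
  expect_lte(max(synth_dynamic(heavy,
    cfg = sim_config(duration = 11, noise_sd = 0))$frames), 700)
  # > 99% of non-DC spectral energy within 0-10 Hz for every active cell
  spec_cols <- which(colSums(rec$frames[1:512, ]) > 0)
  for (cc in spec_cols[c(1, length(spec_cols) %/% 2, length(spec_cols))]) {
    mag <- Mod(stats::fft(rec$frames[1:512, cc]))[2:256]
    f <- (1:255) * 50 / 512
    expect_gt(sum(mag[f <= 10]^2) / sum(mag^2), 0.99)
  }
  expect_error(synth_dynamic(s, cfg = sim_config(duration = 0.5, noise_sd = 0)),
               "full gait cycle")
})

test_that("static synthesis is constant without noise/sway and mass cancels in features", {
  s <- subject_params("p1", mass = 35, diagnosis = "flat")
  cfg <- sim_config(duration = 4, noise_sd = 0, section = "static")
  rec <- synth_static(s, cfg = cfg, sway_amp = 0)
  expect_true(all(apply(rec$frames, 2, function(x) diff(range(x))) == 0))
  # time-mean grid proportional to template x mass
  tpl <- make_template("flat")
  mean_grid <- matrix(colMeans(rec$frames)[
    gaitpress:::cell_index(rep(1:8, each = 8), rep(1:8, 8))], 8, 8, byrow = TRUE)
  expect_equal(mean_grid / sum(mean_grid), tpl$weights, tolerance = 1e-12)
  # two subjects differing only in mass give the same static feature vector
  s2 <- subject_params("p2", mass = 70, diagnosis = "flat")
  rec2 <- synth_static(s2, cfg = cfg, sway_amp = 0)
  f1 <- extract_static(rec$frames)
  f2 <- extract_static(rec2$frames)
  expect_equal(as.numeric(f1), as.numeric(f2), tolerance = 1e-9)
})

test_that("dataset generation is balanced, planned for windowing, and seed-deterministic", {
  ds <- make_dataset(10, cfg = sim_config(section = "dynamic"), seed = 9)
  expect_equal(sum(ds$manifest$n_samples), 40)
  ft <- extract_features(ds)
  expect_equal(unname(table(ft$label)), rep(10L, 4), ignore_attr = TRUE)
  # same seed -> bit-identical; different seed -> different
  ds_b <- make_dataset(10, cfg = sim_config(section = "dynamic"), seed = 9)
  expect_identical(ds, ds_b)
  ds_c <- make_dataset(10, cfg = sim_config(section = "dynamic"), seed = 10)
  expect_false(identical(ds$recordings[[1]]$frames, ds_c$recordings[[1]]$frames))
  # all generated pressures finite, non-negative, within the sensor range
  allp <- unlist(lapply(ds$recordings, function(r) range(r$frames)))
  expect_true(all(is.finite(allp)) && min(allp) >= 0 && max(allp) <= 1000)
  # a class without subjects errors
  subs <- Filter(function(s) s$diagnosis != "toe_in", default_cohort())
  expect_error(make_dataset(5, subjects = subs), "toe_in")
})

test_that("subject parameter validation ties FPA ranges to the diagnosis", {
  expect_error(subject_params("x", 30, fpa = -10, diagnosis = "normal"),
               "inconsistent")
  expect_error(subject_params("x", 30, fpa = 5, diagnosis = "toe_in"),
               "inconsistent")
  expect_error(subject_params("x", 30, fpa = 10, diagnosis = "toe_out"),
               "inconsistent")
  expect_silent(subject_params("x", 30, fpa = -8, diagnosis = "toe_in"))
  expect_equal(subject_params("x", 30, diagnosis = "toe_out")$fpa, 30)
})
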