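test_that("noiseless forward model inverts: programmed amplitude recovered at blob center", {
  sc <- plateau_scene()
  tr <- simulate_trial(sc, amplitudes = c(1, 0.5, 0.25, 0))
  map <- build_response_map(tr$volume)
  gl <- tr$truth$glomeruli
  for (i in seq_len(nrow(gl))) {
    got <- map[gl$y[i], gl$x[i]]
    expect_lt(abs(got - gl$amplitude[i]), 0.05 * max(gl$amplitude[i], 0.02))
  }
})

test_that("null trial (all amplitudes zero) yields near-zero fold change at centers", {
  sc <- scene_config(noise_sd = 2, motion_sd_px = 0, seed = 4)
  tr <- simulate_trial(sc, amplitudes = rep(0, 4))
  map <- build_response_map(tr$volume)
  gl <- tr$truth$glomeruli
  vals <- map[cbind(gl$y, gl$x)]
  expect_lt(max(abs(vals)), 0.02)
})

test_that("simulation is bit-identical under a fixed seed and leaves the global RNG alone", {
  sc <- scene_config(noise_sd = 5, motion_sd_px = 1, seed = 11)
  set.seed(123)
  before <- rnorm(1)
  a <- simulate_trial(sc, amplitudes = c(1, 0, 0.3, 0.8))
  b <- simulate_trial(sc, amplitudes = c(1, 0, 0.3, 0.8))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$shifts, b$truth$shifts)
  set.seed(123)
  expect_identical(rnorm(1), before)
})

test_that("glomerulus centers outside the volume are rejected by name", {
  expect_error(
    scene_config(n_glomeruli = 2, glomerulus_centers = list(c(4, 30, 30),
                                                            c(4, 30, 99))),
    "Glomerulus 2")
  expect_error(simulate_trial(plateau_scene(), amplitudes = c(1, 1)),
               "per glomerulus")
})

test_that("study-design experiment has 21 trials, each odorant three times, seeded order", {
  sc <- plateau_scene(volume_shape = c(16, 4, 32, 32), n_glomeruli = 2,
                      glomerulus_radius_vox = 4)
  man <- study_trial_manifest()
  expect_equal(nrow(man), 21)
  tun <- matrix(0.5, 2, 7, dimnames = list(NULL, unique(man$odorant)))
  ex <- simulate_experiment(sc, man, tun, seed = 3)
  expect_length(ex, 21)
  ods <- vapply(ex, function(t) t$odorant, character(1))
  expect_true(all(table(ods) == 3))
  # order randomized within repeat blocks, deterministically
  m1 <- attr(ex, "manifest")
  ex2 <- simulate_experiment(sc, man, tun, seed = 3)
  expect_identical(m1, attr(ex2, "manifest"))
  expect_true(all(m1$repeat_index == rep(1:3, each = 7)))
  expect_false(all(m1$trial_index == sort(m1$trial_index)))

  small <- simulate_experiment(
    sc, study_trial_manifest(odorants = c("a", "b"), n_repeats = 1),
    matrix(0, 2, 2, dimnames = list(NULL, c("a", "b"))), seed = 1)
  expect_length(small, 2)
  expect_error(
    simulate_experiment(sc, study_trial_manifest(odorants = c("a", "zz"),
                                                 n_repeats = 1),
                        matrix(0, 2, 1, dimnames = list(NULL, "a"))),
    "zz")
})

test_that("colony track extremes: nobody leaves at k=0,Y0=YM=0; everybody out at YM=1, large k", {
  none <- behavior_scenario(leave_params_young = list(Y0 = 0, YM = 0, k = 0),
                            leave_params_old = list(Y0 = 0, YM = 0, k = 0),
                            sample_interval_s = 10, duration_s = 400, seed = 2)
  tr <- simulate_colony_tracks(none, stimulus_time_s = 270)
  nest <- nest_from_tracks(tr)
  props <- proportion_outside(tr, nest, stimulus_time_s = 270)
  expect_true(all(props$proportion == 0))

  all_out <- behavior_scenario(
    leave_params_young = list(Y0 = 0.01, YM = 1, k = 5),
    leave_params_old = list(Y0 = 0.01, YM = 1, k = 5),
    sample_interval_s = 10, duration_s = 400, seed = 2)
  tr2 <- simulate_colony_tracks(all_out, stimulus_time_s = 270)
  props2 <- proportion_outside(tr2, nest_from_tracks(tr2),
                               stimulus_time_s = 270)
  late <- props2[props2$time_s >= 20, ]
  expect_true(all(late$proportion == 1))
})

test_that("empirical leave proportions converge to the generating logistic (n = 10,000)", {
  big <- behavior_scenario(
    n_young = 10000, n_old = 10000,
    leave_params_young = list(Y0 = 0.05, YM = 0.8, k = 0.08),
    leave_params_old = list(Y0 = 0.05, YM = 0.5, k = 0.04),
    sample_interval_s = 10, duration_s = 340, seed = 8)
  tr <- simulate_colony_tracks(big, stimulus_time_s = 270)
  nest <- nest_from_tracks(tr, window_s = 260)
  props <- proportion_outside(tr, nest, stimulus_time_s = 270)
  truth <- attr(tr, "truth")
  for (i in seq_len(nrow(props))) {
    p <- truth$expected_proportion[
      truth$time_s == props$time_s[i] + 270 &
        truth$age_class == props$age_class[i]]
    se <- sqrt(p * (1 - p) / props$n_total[i])
    expect_lt(abs(props$proportion[i] - p), max(3 * se, 1e-9))
  }
  expect_error(behavior_scenario(sample_interval_s = 0), "sample_interval_s")
})
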