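test_that("roi_mean is the arithmetic mean over masked pixels", {
  map <- matrix(0.3, 6, 6)
  r <- roi_rect("a", c(0, 0, 3, 3), c(6, 6))
  expect_equal(roi_mean(map, r), 0.3)
  m2 <- matrix(0, 6, 6)
  m2[1, 1] <- 0.1; m2[2, 1] <- 0.5
  mask <- matrix(FALSE, 6, 6); mask[1:2, 1] <- TRUE
  expect_equal(roi_mean(m2, roi("b", mask)), 0.3)
  set.seed(8)
  rnd <- matrix(rnorm(36), 6, 6)
  rmask <- matrix(runif(36) < 0.4, 6, 6)
  rmask[1] <- TRUE
  expect_equal(roi_mean(rnd, roi("c", rmask)), mean(rnd[rmask]))
  expect_error(roi_mean(rnd, roi_rect("d", c(0, 0, 2, 2), c(9, 9))),
               "does not match")
})

test_that("whole-AL mean reflects the active fraction and response breadth ordering", {
  # one blob at 1.0 over 10% of the AL, rest 0 -> AL mean 0.10
  map <- matrix(0, 10, 10)
  map[1:10, 1] <- 1
  al <- roi("AL", matrix(TRUE, 10, 10))
  expect_equal(whole_al_mean(map, al), 0.10)
  expect_equal(whole_al_mean(matrix(0, 10, 10), al), 0)

  broad_tr <- simulate_trial(plateau_scene(), amplitudes = rep(1, 4))
  sparse_tr <- simulate_trial(plateau_scene(), amplitudes = c(1, 0, 0, 0))
  al2 <- roi("AL", matrix(TRUE, 64, 64))
  expect_gt(whole_al_mean(build_response_map(broad_tr$volume), al2),
            whole_al_mean(build_response_map(sparse_tr$volume), al2))
})

test_that("responding-ROI calls average across trials with an inclusive 0.2 threshold", {
  shape <- c(8, 8)
  r <- roi_rect("g1", c(2, 2, 5, 5), shape)
  mk <- function(v) {
    m <- matrix(0, shape[1], shape[2])
    m[3:5, 3:5] <- v
    m
  }
  calls <- classify_responding_rois(
    maps = list(mk(0.25), mk(0.18), mk(0.20)),
    rois = roi_set(list(r)), odorants = rep("odA", 3))
  expect_equal(calls$mean_peak, 0.21)
  expect_true(calls$responds)

  low <- classify_responding_rois(list(mk(0.19), mk(0.19), mk(0.19)),
                                  roi_set(list(r)), rep("odA", 3))
  expect_false(low$responds)

  # boundary: a mean of exactly 0.2 responds (inclusive rule)
  exact <- classify_responding_rois(list(mk(0.2), mk(0.2), mk(0.2)),
                                    roi_set(list(r)), rep("odA", 3))
  expect_equal(exact$mean_peak, 0.2)
  expect_true(exact$responds)
})

test_that("motion-flagged trials are dropped; fully excluded odorants are undetermined", {
  shape <- c(8, 8)
  r <- roi_rect("g1", c(2, 2, 5, 5), shape)
  mk <- function(v) {
    m <- matrix(v, shape[1], shape[2])
    m
  }
  calls <- classify_responding_rois(
    list(mk(0.5), mk(0.01), mk(10), mk(0.01)),
    roi_set(list(r)), odorants = c("a", "a", "b", "b"),
    excluded = c(FALSE, FALSE, TRUE, FALSE))
  a <- calls[calls$odorant == "a", ]
  b <- calls[calls$odorant == "b", ]
  expect_equal(a$n_trials, 2)
  expect_equal(a$mean_peak, 0.255)
  expect_equal(b$mean_peak, 0.01)   # excluded trial dropped

  und <- classify_responding_rois(
    list(mk(0.5), mk(0.4)), roi_set(list(r)), odorants = c("a", "b"),
    excluded = c(FALSE, TRUE))
  bu <- und[und$odorant == "b", ]
  expect_true(is.na(bu$responds))
  expect_equal(bu$n_trials, 0)
  # undetermined calls do not inflate responding counts
  expect_equal(count_responding(und)$n_responding[
    count_responding(und)$odorant == "b"], 0)
})

test_that("counts are invariant to trial order and raising a mean never unflips a call", {
  shape <- c(8, 8)
  rois <- roi_set(list(roi_rect("g1", c(0, 0, 3, 3), shape),
                       roi_rect("g2", c(4, 4, 8, 8), shape)))
  set.seed(14)
  maps <- replicate(6, matrix(runif(64, 0, 0.4), 8, 8), simplify = FALSE)
  ods <- c("a", "b", "a", "b", "a", "b")
  c1 <- count_responding(classify_responding_rois(maps, rois, ods))
  perm <- c(5, 3, 1, 6, 2, 4)
  c2 <- count_responding(classify_responding_rois(maps[perm], rois, ods[perm]))
  expect_equal(dplyr::arrange(c1, odorant), dplyr::arrange(c2, odorant))

  boosted <- lapply(maps, function(m) m + 0.3)
  cb <- classify_responding_rois(boosted, rois, ods)
  c0 <- classify_responding_rois(maps, rois, ods)
  expect_true(all(cb$responds >= c0$responds))
})

test_that("end-to-end: exactly the suprathreshold glomeruli are called responding", {
  sc <- plateau_scene()
  tun <- cbind(odX = c(0, 0.1, 0.5, 1.0))
  man <- study_trial_manifest(odorants = "odX", n_repeats = 3)
  ex <- simulate_experiment(sc, man, tun, seed = 6)
  maps <- lapply(ex, function(tr) build_response_map(tr$volume))
  rois <- ground_truth_rois(ex[[1]]$truth, c(64, 64))
  calls <- classify_responding_rois(maps, rois,
                                    vapply(ex, function(t) t$odorant,
                                           character(1)))
  calls <- dplyr::arrange(calls, roi_label)
  expect_equal(calls$responds, c(0, 0.1, 0.5, 1.0) >= 0.2)
  expect_equal(count_responding(calls)$n_responding, 2)
})

test_that("broad-response panels are flagged via the AL fraction rule", {
  sc <- plateau_scene()
  broad <- simulate_trial(sc, amplitudes = rep(2, 4))
  sparse <- simulate_trial(sc, amplitudes = c(1, 0, 0, 0))
  rois <- ground_truth_rois(broad$truth, c(64, 64))
  al_small <- roi("AL", {
    m <- matrix(FALSE, 64, 64)
    m[12:52, 12:52] <- TRUE   # AL boundary enclosing the glomerular field
    m
  })
  cb <- classify_responding_rois(list(build_response_map(broad$volume)),
                                 rois, "x", al_roi = al_small,
                                 broad_fraction = 0.1)
  cs <- classify_responding_rois(list(build_response_map(sparse$volume)),
                                 rois, "x", al_roi = al_small,
                                 broad_fraction = 0.1)
  expect_true(all(cb$broad_response))
  expect_false(any(cs$broad_response))
})

test_that("candidate ROIs require repeated suprathreshold responses", {
  sc <- plateau_scene(volume_shape = c(20, 4, 48, 48), n_glomeruli = 1,
                      glomerulus_centers = list(c(2, 24, 24)))
  hit <- lapply(1:3, function(i) {
    build_response_map(simulate_trial(sc, amplitudes = 1, seed = i)$volume)
  })
  rs <- candidate_rois_from_trials(hit, threshold = 0.2)
  expect_equal(length(rs), 1)
  expect_true(rs[[1]]$mask[24, 24])

  miss <- c(hit[1], lapply(2:3, function(i) {
    build_response_map(simulate_trial(sc, amplitudes = 0, seed = i)$volume)
  }))
  expect_equal(length(candidate_rois_from_trials(miss, threshold = 0.2)), 0)
  empty <- lapply(1:2, function(i) matrix(0, 8, 8))
  expect_equal(length(candidate_rois_from_trials(empty)), 0)
})

test_that("glomerular traces: constant movies, AUC arithmetic and linearity", {
  arr <- array(100, c(45, 5, 12, 12))
  vol <- volume_series(arr, frame_period_s = 0.83)
  r <- roi_rect("g", c(4, 4, 8, 8), c(12, 12), kind = "plane_centered",
                z_center = 3)
  tr <- glomerular_trace(vol, r)
  expect_true(all(tr$fold_change == 0))
  expect_equal(trace_auc(tr), 0)

  # fold change 0.1 from frame 6 onward -> AUC = 35 * 0.1 = 3.5
  arr2 <- arr
  arr2[6:45, , , ] <- 110
  tr2 <- glomerular_trace(volume_series(arr2, frame_period_s = 0.83), r)
  expect_equal(trace_auc(tr2), 3.5)

  # linearity: scaling the response scales the AUC
  arr3 <- arr
  arr3[6:45, , , ] <- 130
  tr3 <- glomerular_trace(volume_series(arr3), r)
  expect_equal(trace_auc(tr3), 3 * trace_auc(tr2))

  # additivity over disjoint windows partitioning 6-40
  aucs <- sum(tr3$fold_change[6:20]) + sum(tr3$fold_change[21:40])
  expect_equal(trace_auc(tr3), aucs)

  short <- volume_series(arr2[1:30, , , ])
  expect_warning(trs <- glomerular_trace(short, r), "AUC")
  expect_true(is.na(trace_auc(trs)))
  expect_equal(nrow(trs), 30)

  # edge z_center uses the available planes, with a note
  redge <- roi_rect("e", c(4, 4, 8, 8), c(12, 12), kind = "plane_centered",
                    z_center = 1)
  expect_message(glomerular_trace(vol, redge), "edge")
})

test_that("3-plane max-Z projection precedes the fold-change computation", {
  # response lives only in the plane above z_center: the projected trace
  # must still see it
  arr <- array(100, c(45, 3, 8, 8))
  arr[9:14, 3, , ] <- 150
  r <- roi_rect("g", c(2, 2, 6, 6), c(8, 8), kind = "plane_centered",
                z_center = 2)
  tr <- glomerular_trace(volume_series(arr), r)
  expect_equal(tr$fold_change[10], 0.5)
})

test_that("cohort comparisons: degenerate equality, extreme separation, null calibration", {
  expect_message(eq <- compare_cohorts(c(1, 1, 1), c(1, 1, 1)), "convention")
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  sep <- compare_cohorts(c(1, 2, 3), c(101, 102, 103))
  expect_lt(sep$p_value, 0.01)
  sepw <- compare_cohorts(c(1, 2, 3), c(101, 102, 103), test = "wilcoxon")
  expect_lt(sepw$p_value, 0.11)   # rank test floor at n = 3 per group

  # Welch matches the vetted reference implementation
  set.seed(2)
  a <- rnorm(8); b <- rnorm(6, 0.5)
  got <- compare_cohorts(a, b)
  ref <- t.test(a, b)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value)

  # type-I error under the null across 1000 seeded replicates
  set.seed(77)
  rej <- mean(replicate(1000, {
    compare_cohorts(rnorm(6), rnorm(6))$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.014 + 1e-9)
})
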