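test_that("nest center is the coordinate-wise median of early positions", {
  tr <- tibble::tibble(time_s = rep(c(0, 60), each = 1), ant_id = 1,
                       age_class = "young", x_cm = 1, y_cm = 1)
  n1 <- nest_from_tracks(tr)
  expect_equal(unname(n1$center_cm), c(1, 1))
  expect_equal(n1$radius_cm, 0.25)

  pts <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2), c(1, 1))
  tr2 <- tibble::tibble(time_s = 0, ant_id = 1:5, age_class = "young",
                        x_cm = pts[, 1], y_cm = pts[, 2])
  expect_equal(unname(nest_from_tracks(tr2)$center_cm), c(1, 1))

  set.seed(4)
  tr3 <- tibble::tibble(time_s = runif(200, 0, 290), ant_id = rep(1:20, 10),
                        age_class = "old", x_cm = rnorm(200), y_cm = rnorm(200))
  n3 <- nest_from_tracks(tr3)
  inwin <- tr3[tr3$time_s <= 300, ]
  expect_equal(unname(n3$center_cm),
               c(median(inwin$x_cm), median(inwin$y_cm)))
  expect_error(nest_from_tracks(tr3[tr3$time_s > 400, ]), "window")
})

test_that("outside-nest rule is strict on the body-radius margin", {
  nest <- structure(list(center_cm = c(x = 0, y = 0), radius_cm = 0.25),
                    class = "nest_model")
  mk <- function(d) tibble::tibble(time_s = 0, ant_id = 1,
                                   age_class = "young", x_cm = d, y_cm = 0)
  at50 <- proportion_outside(mk(0.50), nest, stimulus_time_s = 0,
                             grid_s = 0)
  expect_equal(at50$proportion, 1)   # 0.50 > 0.40
  at40 <- proportion_outside(mk(0.40), nest, stimulus_time_s = 0,
                             grid_s = 0)
  expect_equal(at40$proportion, 0)   # boundary: not strictly greater
})

test_that("proportions recover the simulator's exact bookkeeping and handle gaps", {
  sc <- behavior_scenario(n_young = 50, n_old = 50, sample_interval_s = 10,
                          duration_s = 340, seed = 31)
  tr <- simulate_colony_tracks(sc, stimulus_time_s = 270)
  nest <- structure(list(center_cm = c(x = 0, y = 0), radius_cm = 0.25),
                    class = "nest_model")
  props <- proportion_outside(tr, nest, stimulus_time_s = 270)
  # generator places "outside" ants strictly beyond the margin, so counts
  # equal the number of generated outside draws exactly
  manual <- tr %>%
    dplyr::filter(.data$time_s >= 210, .data$time_s <= 330) %>%
    dplyr::mutate(time_rel = .data$time_s - 270,
                  outside = sqrt(.data$x_cm^2 + .data$y_cm^2) > 0.40) %>%
    dplyr::group_by(.data$time_rel, .data$age_class) %>%
    dplyr::summarise(p = mean(.data$outside), .groups = "drop")
  joined <- merge(props, manual, by.x = c("time_s", "age_class"),
                  by.y = c("time_rel", "age_class"))
  expect_equal(joined$proportion, joined$p)

  # an ant absent near a gridpoint is excluded from that total
  gap <- tr[!(tr$ant_id == 1 & tr$time_s == 270), ]
  expect_message(
    pg <- proportion_outside(gap, nest, stimulus_time_s = 270,
                             match_tol_s = 4),
    "lacked")
  expect_equal(sum(pg$n_total[pg$time_s == 0]), 99)
})

test_that("logistic curve obeys its closed-form anchors and the fit recovers parameters", {
  expect_equal(logistic_growth(0, 0.2, 0.9, 0.3), 0.2)
  expect_lt(abs(logistic_growth(1e6, 0.05, 0.8, 0.1) - 0.8), 1e-12)
  expect_equal(logistic_growth(5, 0, 0.8, 0.1), 0)
  expect_equal(logistic_growth(c(-3, 7), 0.4, 0.4, 2), c(0.4, 0.4))

  tt <- seq(-10, 60, by = 10)
  y <- logistic_growth(tt, 0.05, 0.8, 0.08)
  fit <- fit_logistic_growth(tt, y)
  expect_lt(max(abs(coef(fit) - c(Y0 = 0.05, YM = 0.8, k = 0.08)) /
                  c(0.05, 0.8, 0.08)), 1e-4)
  expect_lt(fit$ss_resid, 1e-12)
  expect_equal(fit$df, 5)
  expect_equal(tidy(fit)$term, c("Y0", "YM", "k"))

  # noisy recovery: the mean estimate over 100 seeded replicates stays
  # within 15% of every generating parameter
  set.seed(55)
  ests <- replicate(100, {
    yn <- y + rnorm(length(y), 0, 0.03)
    coef(fit_logistic_growth(tt, yn))
  })
  rel_bias <- abs(rowMeans(ests) - c(0.05, 0.8, 0.08)) / c(0.05, 0.8, 0.08)
  expect_lt(max(rel_bias), 0.15)

  cst <- fit_logistic_growth(tt, rep(0.3, 8))
  expect_equal(unname(coef(cst)), c(0.3, 0.3, 0))
  expect_equal(cst$ss_resid, 0)
  expect_error(fit_logistic_growth(1:3, c(0.1, 0.2, 0.3)), "at least 4")
})

test_that("logistic fit is consistent under time-axis shifts (closed-form transport)", {
  tt <- seq(0, 70, by = 10)
  y <- logistic_growth(tt, 0.1, 0.7, 0.06)
  f0 <- fit_logistic_growth(tt, y)
  f1 <- fit_logistic_growth(tt - 20, y)
  # shifting time by s redefines Y0 at the new origin, leaves YM and k
  expect_equal(unname(coef(f1)["YM"]), unname(coef(f0)["YM"]), tolerance = 1e-4)
  expect_equal(unname(coef(f1)["k"]), unname(coef(f0)["k"]), tolerance = 1e-4)
  expect_equal(unname(coef(f1)["Y0"]),
               logistic_growth(20, 0.1, 0.7, 0.06), tolerance = 1e-4)
})

test_that("quadratic fits match the normal-equations oracle", {
  tt <- seq(-10, 60, by = 10)
  y <- 0.002 * tt^2 - 0.01 * tt + 0.3
  f <- fit_quadratic(tt, y)
  expect_equal(unname(coef(f)), c(0.002, -0.01, 0.3))
  expect_lt(f$ss_resid, 1e-20)

  fc <- fit_quadratic(tt, rep(0.4, 8))
  expect_equal(unname(coef(fc)), c(0, 0, 0.4))

  set.seed(9)
  yr <- rnorm(8)
  fr <- fit_quadratic(tt, yr)
  orc <- oracle_quadratic(tt, yr)
  expect_equal(unname(coef(fr)), orc$coef)
  expect_equal(fr$ss_resid, orc$ss)
  expect_error(fit_quadratic(rep(c(1, 2), 4), rnorm(8)), "Rank")
})

test_that("extra-SS F statistic follows the formula, with correct bookkeeping", {
  # direct formula check: ss_null 10 (df 20), ss_alt 8 (df 17)
  F_manual <- ((10 - 8) / 3) / (8 / 17)
  expect_equal(F_manual, 1.4166667, tolerance = 1e-6)
  p_manual <- pf(F_manual, 3, 17, lower.tail = FALSE)

  set.seed(12)
  tt <- seq(-10, 60, by = 10)
  d <- dplyr::bind_rows(
    tibble::tibble(time_s = tt, group = "young",
                   proportion = logistic_growth(tt, 0.05, 0.8, 0.1) +
                     rnorm(8, 0, 0.02)),
    tibble::tibble(time_s = tt, group = "old",
                   proportion = logistic_growth(tt, 0.05, 0.4, 0.05) +
                     rnorm(8, 0, 0.02)))
  cmp <- extra_ss_f_test(d)
  expect_equal(cmp$df_null, 13)
  expect_equal(cmp$df_alt, 10)
  expect_equal(cmp$df_num, 3)
  expect_lte(cmp$ss_alt, cmp$ss_null + 1e-10)
  F_check <- ((cmp$ss_null - cmp$ss_alt) / 3) / (cmp$ss_alt / 10)
  expect_equal(cmp$F, F_check)
  expect_equal(cmp$p_value, pf(F_check, 3, 10, lower.tail = FALSE))
  g <- glance(cmp)
  expect_equal(g$p_value, cmp$p_value)
  expect_true(all(c("single", "separate") %in% tidy(cmp)$model))

  # too few points per group fails before any F statistic is formed
  expect_error(extra_ss_f_test(d[c(1:4, 9:11), ]), "at least 4")
  expect_lt(p_manual, 1)  # sanity on the direct-formula oracle
})

test_that("a 3-fold rate difference at low noise prefers separate curves", {
  set.seed(3)
  tt <- seq(-10, 60, by = 10)
  d <- dplyr::bind_rows(
    tibble::tibble(time_s = tt, group = "a",
                   proportion = logistic_growth(tt, 0.05, 0.7, 0.05) +
                     rnorm(8, 0, 0.01)),
    tibble::tibble(time_s = tt, group = "b",
                   proportion = logistic_growth(tt, 0.05, 0.7, 0.15) +
                     rnorm(8, 0, 0.01)))
  cmp <- extra_ss_f_test(d)
  expect_equal(cmp$preferred, "separate")
  expect_lt(cmp$p_value, 0.05)
})

test_that("quadratic-family comparison works for non-sigmoidal (vehicle) responses", {
  set.seed(21)
  tt <- seq(-10, 60, by = 10)
  d <- dplyr::bind_rows(
    tibble::tibble(time_s = tt, group = "young",
                   proportion = 0.1 + 0.001 * tt + rnorm(8, 0, 0.01)),
    tibble::tibble(time_s = tt, group = "old",
                   proportion = 0.1 + 0.001 * tt + rnorm(8, 0, 0.01)))
  cmp <- extra_ss_f_test(d, model_family = "quadratic")
  expect_equal(cmp$model_family, "quadratic")
  expect_lte(cmp$ss_alt, cmp$ss_null + 1e-12)
  expect_equal(cmp$preferred, "single")
})

test_that("tracking CSV round-trips and validates its header", {
  dir <- withr::local_tempdir()
  sc <- behavior_scenario(n_young = 3, n_old = 3, sample_interval_s = 60,
                          duration_s = 300, seed = 1)
  tr <- simulate_colony_tracks(sc)
  p <- file.path(dir, "tracks.csv")
  write_tracks_csv(tr, p)
  back <- read_tracks_csv(p)
  expect_equal(back$x_cm, tr$x_cm)
  expect_equal(back$age_class, tr$age_class)
  bad <- file.path(dir, "bad.csv")
  write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_tracks_csv(bad), "lacks")
})
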