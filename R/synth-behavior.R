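#' Scenario for synthetic colony alarm-behavior tracks
#'
#' Emulates the mixed-age colony bioassay: young and old ants rest in a
#' tight nest pile; after an alarm stimulus each cohort leaves the nest
#' with its own logistic dynamics. Defaults mirror the assay design (12
#' young + 12 old ants, 0.25 cm nest circle, ~4.5 min of baseline then 5
#' min of response); the leave-curve parameters are arbitrary plausible
#' values, since the source data report no fitted constants.
#'
#' @param n_young,n_old Ant counts per cohort (>= 1).
#' @param nest_center_cm Nest center `c(x, y)` in cm.
#' @param nest_radius_cm Nest radius (default 0.25 cm).
#' @param arena_radius_cm Arena radius; ants outside the nest are placed
#'   uniformly between the nest margin and this radius.
#' @param body_radius_cm Body margin: "outside" ants are placed strictly
#'   beyond `nest_radius + body_radius` so centroid-based counting agrees
#'   with the generating labels exactly.
#' @param leave_params_young,leave_params_old Lists `(Y0, YM, k)` of
#'   [logistic_growth()] parameters governing each cohort's expected
#'   proportion outside the nest versus time since stimulus; require
#'   `0 <= Y0 <= YM <= 1` and `k >= 0`.
#' @param sample_interval_s Tracking cadence in seconds (> 0).
#' @param duration_s Recording length (default 570 s: 270 s baseline +
#'   300 s response).
#' @param seed Integer seed.
#' @return An object of class `behavior_scenario`.
#' @export
behavior_scenario <- function(n_young = 12, n_old = 12,
                              nest_center_cm = c(0, 0),
                              nest_radius_cm = 0.25,
                              arena_radius_cm = 3,
                              body_radius_cm = 0.15,
                              leave_params_young = list(Y0 = 0.05, YM = 0.8,
                                                        k = 0.08),
                              leave_params_old = list(Y0 = 0.05, YM = 0.5,
                                                      k = 0.04),
                              sample_interval_s = 1,
                              duration_s = 570,
                              seed = 1L) {
  check_scalar_number(n_young, "n_young", lower = 1)
  check_scalar_number(n_old, "n_old", lower = 1)
  check_scalar_number(nest_radius_cm, "nest_radius_cm", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(sample_interval_s, "sample_interval_s", lower = 0,
                      strict_lower = TRUE)
  for (p in list(young = leave_params_young, old = leave_params_old)) {
    if (!(p$Y0 >= 0 && p$Y0 <= p$YM && p$YM <= 1 && p$k >= 0)) {
      abort("Leave parameters must satisfy 0 <= Y0 <= YM <= 1 and k >= 0.")
    }
  }
  if (arena_radius_cm <= nest_radius_cm + body_radius_cm) {
    abort("`arena_radius_cm` must exceed the nest circle plus body margin.")
  }
  structure(
    list(n_young = as.integer(n_young), n_old = as.integer(n_old),
         nest_center_cm = nest_center_cm, nest_radius_cm = nest_radius_cm,
         arena_radius_cm = arena_radius_cm, body_radius_cm = body_radius_cm,
         leave_params_young = leave_params_young,
         leave_params_old = leave_params_old,
         sample_interval_s = sample_interval_s, duration_s = duration_s,
         seed = as.integer(seed)),
    class = "behavior_scenario")
}

#' Simulate colony tracking data with known leave dynamics
#'
#' At each sampled timepoint every ant is outside the nest with probability
#' given by its cohort's leave curve - the baseline rate `Y0` before the
#' stimulus, [logistic_growth()] of time since stimulus afterwards - drawn
#' independently per sample (no dwell-time persistence; see the methods
#' vignette). Ants inside the nest are placed uniformly within the nest
#' circle; ants outside are placed uniformly in the annulus strictly beyond
#' `nest_radius + body_radius`, so [proportion_outside()] recovers the
#' generating labels exactly.
#'
#' @param scenario A [behavior_scenario()].
#' @param stimulus_time_s Stimulus placement time in seconds (default 270).
#' @return Tracking tibble (`time_s`, `ant_id`, `age_class`, `x_cm`,
#'   `y_cm`) with the per-cohort expected-proportion table as attribute
#'   `"truth"`.
#' @export
simulate_colony_tracks <- function(scenario, stimulus_time_s = 270) {
  stopifnot(inherits(scenario, "behavior_scenario"))
  check_scalar_number(stimulus_time_s, "stimulus_time_s", lower = 0)
  times <- seq(0, scenario$duration_s, by = scenario$sample_interval_s)
  cohorts <- tibble(
    ant_id = seq_len(scenario$n_young + scenario$n_old),
    age_class = rep(c("young", "old"), c(scenario$n_young, scenario$n_old)))
  p_out <- function(t, pars) {
    ifelse(t < stimulus_time_s, pars$Y0,
           logistic_growth(t - stimulus_time_s, pars$Y0, pars$YM, pars$k))
  }
  inner <- scenario$nest_radius_cm + scenario$body_radius_cm
  with_local_seed(scenario$seed, {
    rows <- purrr::map_dfr(seq_along(times), function(i) {
      t <- times[i]
      p <- ifelse(cohorts$age_class == "young",
                  p_out(t, scenario$leave_params_young),
                  p_out(t, scenario$leave_params_old))
      outside <- runif(nrow(cohorts)) < p
      n <- nrow(cohorts)
      # uniform over the disc / the annulus strictly beyond the margin
      r <- ifelse(outside,
                  sqrt(runif(n, (inner * 1.0001)^2,
                             scenario$arena_radius_cm^2)),
                  scenario$nest_radius_cm * sqrt(runif(n)) * 0.9)
      th <- runif(n, 0, 2 * pi)
      tibble(time_s = t, ant_id = cohorts$ant_id,
             age_class = cohorts$age_class,
             x_cm = scenario$nest_center_cm[1] + r * cos(th),
             y_cm = scenario$nest_center_cm[2] + r * sin(th))
    })
    truth <- purrr::map_dfr(c("young", "old"), function(a) {
      pars <- if (a == "young") scenario$leave_params_young
              else scenario$leave_params_old
      tibble(time_s = times, age_class = a,
             expected_proportion = p_out(times, pars))
    })
    attr(rows, "truth") <- truth
    rows
  })
}
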