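#' Run the full synthetic-to-statistics pipeline from a config file
#'
#' Wires the stages end to end: simulate an odor-panel imaging experiment
#' -> stabilize -> response maps -> responding-ROI classification, AL means
#' and glomerular traces, plus the colony bioassay branch: simulate (or
#' load) tracks -> nest -> outside-nest proportions -> logistic fits and
#' the extra sum-of-squares F test. All stage parameters, including the
#' mandatory `seed`, come from a YAML config; outputs land in `out_dir`
#' with a manifest carrying the package version and a config hash, so a
#' rerun of the same config reproduces every file byte for byte.
#'
#' Config schema (YAML; all windows 1-based, defaults in parentheses):
#' ```
#' seed: 42                       # required
#' imaging:
#'   scene:    {volume_shape: [45,8,64,64], n_glomeruli: 4, noise_sd: 5, ...}
#'   stimulus: {trigger_frame: 3, delay_s: 3, duration_s: 5}
#'   tuning:   {odorants: [...], amplitudes: [[...], ...]}  # glomerulus x odorant
#'   manifest: {concentration_pct: 48, n_repeats: 3}
#'   baseline_frames: [1, 5]      # (1-5)
#'   peak_frames: [9, 14]         # (9-14)
#'   auc_frames: [6, 40]          # (6-40)
#'   min_filter_radius: 2
#'   clip: [-1, 4]
#'   threshold: 0.2
#'   artifact_threshold_px: 5
#' behavior:
#'   scenario: {n_young: 12, n_old: 12, ...}   # or tracks: path.csv
#'   stimulus_time_s: 270
#'   nest_radius_cm: 0.25
#'   body_radius_cm: 0.15
#'   model_family: logistic_growth
#' ```
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly; see the written `manifest.yaml` for the
#'   file inventory and trial exclusions.
#' @export
run_pipeline <- function(config, out_dir) {
  config_hash <- NA_character_
  if (is.character(config)) {
    config_hash <- unname(tools::md5sum(config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a YAML path or a list.")
  if (is.null(config$seed)) abort("Config error at `seed`: a seed is required.")
  check_scalar_number(config$seed, "seed")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  outputs <- character()
  exclusions <- tibble(trial_index = integer(), odorant = character(),
                       max_jump_px = numeric())

  if (!is.null(config$imaging)) {
    im <- config$imaging
    windows <- list(
      baseline = seq(im$baseline_frames[1] %||% 1, im$baseline_frames[2] %||% 5),
      peak = seq(im$peak_frames[1] %||% 9, im$peak_frames[2] %||% 14),
      auc = seq(im$auc_frames[1] %||% 6, im$auc_frames[2] %||% 40))
    scene_args <- im$scene %||% list()
    if (!is.null(scene_args$volume_shape)) {
      scene_args$volume_shape <- unlist(scene_args$volume_shape)
    }
    scene_args$seed <- config$seed
    scene <- tryCatch(do.call(scene_config, scene_args),
                      error = function(e) {
                        abort(sprintf("Config error at `imaging.scene`: %s",
                                      conditionMessage(e)))
                      })
    tun <- im$tuning
    if (is.null(tun)) abort("Config error at `imaging.tuning`: required.")
    tuning <- do.call(rbind, lapply(tun$amplitudes, unlist))
    colnames(tuning) <- unlist(tun$odorants)
    manifest <- study_trial_manifest(
      odorants = unlist(tun$odorants),
      concentration_pct = im$manifest$concentration_pct %||% 48,
      n_repeats = im$manifest$n_repeats %||% 3)
    timing <- do.call(stimulus_timing, im$stimulus %||% list())
    logf("simulate: %d trials, scene %s", nrow(manifest),
         paste(scene$volume_shape, collapse = "x"))
    trials <- simulate_experiment(scene, manifest, tuning, timing = timing,
                                  seed = config$seed)

    thr_art <- im$artifact_threshold_px %||% 5
    maps <- list()
    odorants <- character()
    shifts_all <- list()
    excluded <- logical()
    for (i in seq_along(trials)) {
      tr <- trials[[i]]
      st <- stabilize_series(tr$volume, baseline_frames = windows$baseline)
      fl <- flag_motion_artifact(st$shifts, threshold_px = thr_art)
      logf("trial %d (%s): max shift jump %.2f px%s", tr$trial_index,
           tr$odorant, attr(fl, "max_jump_px"),
           if (fl) " -> EXCLUDED (motion artifact)" else "")
      if (fl) {
        exclusions <- bind_rows(exclusions,
                                tibble(trial_index = tr$trial_index,
                                       odorant = tr$odorant,
                                       max_jump_px = attr(fl, "max_jump_px")))
      }
      excluded[i] <- as.logical(fl)
      maps[[i]] <- build_response_map(
        st$volume, baseline_frames = windows$baseline,
        peak_frames = windows$peak,
        min_filter_radius = im$min_filter_radius %||% 2,
        clip = unlist(im$clip %||% c(-1, 4)))
      odorants[i] <- tr$odorant
      shifts_all[[i]] <- st$shifts %>% mutate(trial_index = tr$trial_index)
      map_path <- file.path(out_dir, sprintf("map_trial%02d.tif",
                                             tr$trial_index))
      write_map_tiff(maps[[i]], map_path)
      outputs <- c(outputs, basename(map_path))
    }
    write.csv(bind_rows(shifts_all), file.path(out_dir, "shifts.csv"),
              row.names = FALSE)

    shape_yx <- scene$volume_shape[3:4]
    rois <- ground_truth_rois(trials[[1]]$truth, shape_yx)
    al_mask <- matrix(TRUE, shape_yx[1], shape_yx[2])
    al_roi <- roi("AL", al_mask)
    calls <- classify_responding_rois(maps, rois, odorants,
                                      threshold = im$threshold %||% 0.2,
                                      excluded = excluded, al_roi = al_roi)
    write.csv(calls, file.path(out_dir, "calls.csv"), row.names = FALSE)
    write.csv(count_responding(calls), file.path(out_dir, "counts.csv"),
              row.names = FALSE)
    al_means <- tibble(
      trial_index = vapply(trials, function(tr) tr$trial_index, numeric(1)),
      odorant = odorants, excluded = excluded,
      al_mean = vapply(maps, function(m) whole_al_mean(m, al_roi), numeric(1)))
    write.csv(al_means, file.path(out_dir, "whole_al_means.csv"),
              row.names = FALSE)

    trois <- ground_truth_rois(trials[[1]]$truth, shape_yx,
                               kind = "plane_centered")
    traces <- purrr::map_dfr(seq_along(trials), function(i) {
      purrr::map_dfr(trois, function(r) {
        tr <- glomerular_trace(trials[[i]]$volume, r,
                               baseline_frames = windows$baseline,
                               auc_frames = windows$auc)
        tibble(trial_index = trials[[i]]$trial_index, odorant = odorants[i],
               roi_label = attr(tr, "roi_label"), frame = tr$frame,
               time_s = tr$time_s, fold_change = tr$fold_change,
               auc = attr(tr, "auc"))
      })
    })
    write.csv(traces, file.path(out_dir, "traces.csv"), row.names = FALSE)
    write.csv(exclusions, file.path(out_dir, "exclusions.csv"),
              row.names = FALSE)
    outputs <- c(outputs, "shifts.csv", "calls.csv", "counts.csv",
                 "whole_al_means.csv", "traces.csv", "exclusions.csv")
  }

  if (!is.null(config$behavior)) {
    bh <- config$behavior
    stim_t <- bh$stimulus_time_s %||% 270
    if (!is.null(bh$tracks)) {
      tracks <- read_tracks_csv(bh$tracks)
    } else {
      sc_args <- bh$scenario %||% list()
      sc_args$seed <- config$seed
      scenario <- tryCatch(do.call(behavior_scenario, sc_args),
                           error = function(e) {
                             abort(sprintf("Config error at `behavior.scenario`: %s",
                                           conditionMessage(e)))
                           })
      tracks <- simulate_colony_tracks(scenario, stimulus_time_s = stim_t)
      write_tracks_csv(tracks, file.path(out_dir, "tracks.csv"))
      outputs <- c(outputs, "tracks.csv")
    }
    nest <- nest_from_tracks(tracks, radius_cm = bh$nest_radius_cm %||% 0.25)
    props <- proportion_outside(tracks, nest, stimulus_time_s = stim_t,
                                body_radius_cm = bh$body_radius_cm %||% 0.15)
    write.csv(props, file.path(out_dir, "proportions.csv"), row.names = FALSE)
    logf("behavior: nest at (%.3g, %.3g), %d gridpoints",
         nest$center_cm[1], nest$center_cm[2], length(unique(props$time_s)))
    win <- props %>% filter(.data$time_s >= -10, .data$time_s <= 60) %>%
      rename(group = "age_class")
    cmp <- extra_ss_f_test(win,
                           model_family = bh$model_family %||% "logistic_growth")
    jsonlite::write_json(
      list(model_family = cmp$model_family, F = cmp$F, df_num = cmp$df_num,
           df_den = cmp$df_den, p_value = cmp$p_value,
           preferred = cmp$preferred, ss_null = cmp$ss_null,
           ss_alt = cmp$ss_alt,
           group_estimates = lapply(cmp$group_fits,
                                    function(f) as.list(f$coefficients))),
      file.path(out_dir, "curve_comparison.json"), auto_unbox = TRUE,
      digits = NA)
    logf("behavior: F(%d, %d) = %.4g, p = %.4g -> %s", cmp$df_num,
         cmp$df_den, cmp$F, cmp$p_value, cmp$preferred)
    outputs <- c(outputs, "proportions.csv", "curve_comparison.json")
  }

  yaml::write_yaml(
    list(package = "antalarm",
         version = as.character(packageVersion("antalarm")),
         config_hash = config_hash, seed = config$seed,
         outputs = sort(outputs),
         n_excluded_trials = nrow(exclusions)),
    file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
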