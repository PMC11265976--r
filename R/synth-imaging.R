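#' Scene configuration for synthetic calcium-imaging trials
#'
#' Describes a small antennal lobe as a set of spherical glomerular blobs in
#' a scanned volume. The real acquisition scans 512 x 512 x 33 voxels every
#' 0.83 s; the default desk-scale scene keeps the 0.83 s volume period and
#' the frame-window semantics (45 frames covers the 6-40 AUC window) at
#' 64 x 64 x 8 voxels with 4 glomeruli, small enough for seconds-level
#' tests.
#'
#' @param volume_shape `c(n_frames, n_z, n_y, n_x)` voxel counts, all >= 1.
#' @param frame_period_s Seconds per volume scan (> 0).
#' @param n_glomeruli Number of glomerular blobs.
#' @param glomerulus_centers Optional list/matrix of 1-based `(z, y, x)`
#'   centers (one row per glomerulus); auto-placed on an in-plane grid at
#'   the middle plane when `NULL`.
#' @param glomerulus_radius_vox In-plane blob radius in pixels.
#' @param glomerulus_z_radius_vox Axial half-extent in planes (z steps are
#'   coarser than xy pixels, so the blob is an oblate spheroid in voxels).
#' @param baseline_intensity Resting blob fluorescence (arbitrary units).
#' @param background_intensity Mean non-glomerular fluorescence; kept well
#'   above zero so fold change is defined everywhere.
#' @param background_texture_rel Relative amplitude of the static spatial
#'   texture multiplying the background (default 0.2). Real tissue has
#'   structured autofluorescence in every plane; without it, planes that
#'   contain no glomerulus would be featureless and unregisterable. Set 0
#'   for a flat background.
#' @param tuning Optional glomerulus x odorant matrix of peak fold-change
#'   amplitudes (all >= -1); column names are odorant names.
#' @param rise_tau_s,decay_tau_s Response kinetic time constants (seconds,
#'   > 0). `decay_tau_s = Inf` gives a sustained (non-decaying) response.
#' @param noise_sd Additive Gaussian noise SD on intensities (>= 0).
#' @param noise_model `"gaussian"` (default), `"poisson"` (shot noise with
#'   the signal as rate), or `"none"`.
#' @param motion_sd_px Per-frame step SD of the integer 2D random-walk
#'   drift applied rigidly to all planes of a frame (>= 0).
#' @param quantize Round intensities to integer counts (like a detector);
#'   keeps TIFF round-trips exact. Default TRUE.
#' @param seed Integer seed; every simulation from this scene is a pure
#'   function of (scene, timing, amplitudes).
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(volume_shape = c(45, 8, 64, 64),
                         frame_period_s = 0.83,
                         n_glomeruli = 4,
                         glomerulus_centers = NULL,
                         glomerulus_radius_vox = 6,
                         glomerulus_z_radius_vox = 2,
                         baseline_intensity = 1000,
                         background_intensity = 100,
                         background_texture_rel = 0.2,
                         tuning = NULL,
                         rise_tau_s = 1,
                         decay_tau_s = 5,
                         noise_sd = 10,
                         noise_model = c("gaussian", "poisson", "none"),
                         motion_sd_px = 0,
                         quantize = TRUE,
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (length(volume_shape) != 4L || any(volume_shape < 1)) {
    abort("`volume_shape` must be c(n_frames, n_z, n_y, n_x), all >= 1.")
  }
  check_scalar_number(frame_period_s, "frame_period_s", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(rise_tau_s, "rise_tau_s", lower = 0, strict_lower = TRUE)
  if (!(is.numeric(decay_tau_s) && length(decay_tau_s) == 1 && decay_tau_s > 0)) {
    abort("`decay_tau_s` must be > 0 (Inf allowed for sustained responses).")
  }
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  check_scalar_number(motion_sd_px, "motion_sd_px", lower = 0)
  check_scalar_number(baseline_intensity, "baseline_intensity", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(background_intensity, "background_intensity", lower = 0)
  check_scalar_number(background_texture_rel, "background_texture_rel",
                      lower = 0, upper = 0.9)
  if (!is.null(tuning)) {
    tuning <- as.matrix(tuning)
    if (nrow(tuning) != n_glomeruli) {
      abort("`tuning` must have one row per glomerulus.")
    }
    if (any(tuning < -1)) abort("Tuning amplitudes must be >= -1.")
  }
  if (is.null(glomerulus_centers)) {
    glomerulus_centers <- default_centers(n_glomeruli, volume_shape)
  } else {
    glomerulus_centers <- do.call(rbind, lapply(glomerulus_centers, as.numeric))
    if (is.null(dim(glomerulus_centers)) || ncol(glomerulus_centers) != 3L ||
        nrow(glomerulus_centers) != n_glomeruli) {
      abort("`glomerulus_centers` must give (z, y, x) for each glomerulus.")
    }
  }
  for (g in seq_len(n_glomeruli)) {
    cc <- glomerulus_centers[g, ]
    if (cc[1] < 1 || cc[1] > volume_shape[2] ||
        cc[2] < 1 || cc[2] > volume_shape[3] ||
        cc[3] < 1 || cc[3] > volume_shape[4]) {
      abort(sprintf("Glomerulus %d center (%s) lies outside the volume.",
                    g, paste(cc, collapse = ", ")))
    }
  }
  structure(
    list(volume_shape = as.integer(volume_shape),
         frame_period_s = frame_period_s,
         n_glomeruli = as.integer(n_glomeruli),
         glomerulus_centers = glomerulus_centers,
         glomerulus_radius_vox = glomerulus_radius_vox,
         glomerulus_z_radius_vox = glomerulus_z_radius_vox,
         baseline_intensity = baseline_intensity,
         background_intensity = background_intensity,
         background_texture_rel = background_texture_rel,
         tuning = tuning,
         rise_tau_s = rise_tau_s, decay_tau_s = decay_tau_s,
         noise_sd = noise_sd, noise_model = noise_model,
         motion_sd_px = motion_sd_px,
         quantize = isTRUE(quantize),
         seed = as.integer(seed)),
    class = "scene_config"
  )
}

# spread glomeruli over a fraction grid at the middle plane
default_centers <- function(n, shape) {
  fr <- expand.grid(y = c(0.3, 0.7, 0.5), x = c(0.3, 0.7, 0.5))
  fr <- fr[order(fr$y != fr$x), ][seq_len(min(n, 9L)), , drop = FALSE]
  if (n > 9L) abort("Auto-placement supports at most 9 glomeruli; give centers.")
  zc <- ceiling(shape[2] / 2)
  cbind(z = rep(zc, n), y = round(fr$y * shape[3]), x = round(fr$x * shape[4]))
}

#' Response kinetics: double-exponential rise/decay
#'
#' `g(s) = (1 - exp(-s/rise)) * exp(-s/decay)` for time-since-odor-arrival
#' `s > 0`, zero before, renormalized so its maximum is 1; a glomerulus with
#' programmed amplitude `a` then peaks at fold change exactly `a`. With
#' `decay_tau_s = Inf` the response saturates at 1 and is sustained.
#'
#' @param s Seconds since odor arrival (vectorised).
#' @param rise_tau_s,decay_tau_s Time constants (s).
#' @return Kinetic envelope values in `[0, 1]`.
#' @export
response_kinetics <- function(s, rise_tau_s, decay_tau_s) {
  g <- ifelse(s > 0,
              (1 - exp(-s / rise_tau_s)) *
                (if (is.finite(decay_tau_s)) exp(-s / decay_tau_s) else 1),
              0)
  if (is.finite(decay_tau_s)) {
    s_peak <- rise_tau_s * log1p(decay_tau_s / rise_tau_s)
    gmax <- (1 - exp(-s_peak / rise_tau_s)) * exp(-s_peak / decay_tau_s)
    g <- g / gmax
  }
  g
}

sphere_offsets <- function(r_xy, r_z) {
  g <- expand.grid(dz = -ceiling(r_z):ceiling(r_z),
                   dy = -ceiling(r_xy):ceiling(r_xy),
                   dx = -ceiling(r_xy):ceiling(r_xy))
  keep <- (g$dz / max(r_z, 0.5))^2 + (g$dy / r_xy)^2 + (g$dx / r_xy)^2 <= 1
  as.matrix(g[keep, , drop = FALSE])
}

#' Simulate one imaging trial with known ground truth
#'
#' Renders each glomerulus as a constant-intensity spheroid at
#' `baseline_intensity`, multiplied during the response by
#' `1 + a * g(t - t0)` where `a` is the glomerulus's programmed peak fold
#' change, `g` the renormalized [response_kinetics()] envelope and `t0` the
#' trigger time plus the valve delay. An integer 2D random-walk drift
#' (shared by all planes of a frame), additive noise, and optional integer
#' quantization are then applied. The returned ground truth records the
#' centers, amplitudes and per-frame applied shifts, so downstream stages
#' can be validated exactly.
#'
#' @param scene A [scene_config()].
#' @param timing A [stimulus_timing()].
#' @param amplitudes Numeric vector of per-glomerulus peak fold changes
#'   (length `n_glomeruli`, all >= -1).
#' @param metadata Trial metadata list passed to [volume_series()].
#' @param seed Seed override; defaults to `scene$seed`.
#' @return A list with elements `volume` (a [volume_series()]) and `truth`
#'   (list: `glomeruli` tibble with centers/amplitudes, `shifts` tibble with
#'   the per-frame applied `(dy, dx)`, plus the scene and timing used).
#' @export
simulate_trial <- function(scene, timing = stimulus_timing(),
                           amplitudes = rep(1, scene$n_glomeruli),
                           metadata = list(), seed = NULL) {
  stopifnot(inherits(scene, "scene_config"))
  if (length(amplitudes) != scene$n_glomeruli) {
    abort("`amplitudes` must have one value per glomerulus.")
  }
  if (any(amplitudes < -1)) abort("Amplitudes must be >= -1.")
  seed <- seed %||% scene$seed
  d <- scene$volume_shape
  nt <- d[1]
  t_frame <- (seq_len(nt) - 1) * scene$frame_period_s
  t0 <- (timing$trigger_frame - 1) * scene$frame_period_s + timing$delay_s
  g <- response_kinetics(t_frame - t0, scene$rise_tau_s, scene$decay_tau_s)
  offs <- sphere_offsets(scene$glomerulus_radius_vox,
                         scene$glomerulus_z_radius_vox)

  with_local_seed(seed, {
    shifts <- matrix(0L, nt, 2, dimnames = list(NULL, c("dy", "dx")))
    if (scene$motion_sd_px > 0 && nt > 1) {
      steps <- matrix(as.integer(round(rnorm(2 * (nt - 1), 0,
                                             scene$motion_sd_px))),
                      ncol = 2)
      shifts[-1, ] <- apply(steps, 2, cumsum)
    }
    # static blocky background texture; drifts with the frame shifts (torus
    # roll) so every plane carries registerable structure
    texture <- array(0, d[2:4])
    block <- matrix(1, 8, 8)
    for (z in seq_len(d[2])) {
      coarse <- matrix(rnorm(ceiling(d[3] / 8) * ceiling(d[4] / 8)),
                       ceiling(d[3] / 8))
      tex <- kronecker(coarse, block)[seq_len(d[3]), seq_len(d[4])]
      texture[z, , ] <- scene$background_intensity *
        pmax(1 + scene$background_texture_rel * tex, 0.1)
    }
    roll <- function(n, s) ((seq_len(n) - 1 - s) %% n) + 1
    arr <- array(0, dim = d)
    for (t in seq_len(nt)) {
      frame <- matrix(0, d[3] * d[4], d[2])
      # frame as [y*x, z] scratch; background first, then blobs on top
      for (z in seq_len(d[2])) {
        frame[, z] <- texture[z, roll(d[3], shifts[t, "dy"]),
                              roll(d[4], shifts[t, "dx"])]
      }
      for (gl in seq_len(scene$n_glomeruli)) {
        cc <- scene$glomerulus_centers[gl, ]
        z <- offs[, "dz"] + cc[1]
        y <- offs[, "dy"] + cc[2] + shifts[t, "dy"]
        x <- offs[, "dx"] + cc[3] + shifts[t, "dx"]
        ok <- z >= 1 & z <= d[2] & y >= 1 & y <= d[3] & x >= 1 & x <= d[4]
        val <- scene$baseline_intensity * (1 + amplitudes[gl] * g[t])
        idx <- cbind(y[ok] + (x[ok] - 1) * d[3], z[ok])
        frame[idx] <- pmax(frame[idx], val)
      }
      arr[t, , , ] <- aperm(array(frame, c(d[3], d[4], d[2])), c(3, 1, 2))
    }
    if (scene$noise_model == "gaussian" && scene$noise_sd > 0) {
      arr <- arr + rnorm(length(arr), 0, scene$noise_sd)
    } else if (scene$noise_model == "poisson") {
      arr <- array(rpois(length(arr), pmax(arr, 0)), dim = d)
    }
    arr[arr < 0] <- 0
    if (scene$quantize) arr <- round(arr)

    truth <- list(
      glomeruli = tibble(
        glomerulus = seq_len(scene$n_glomeruli),
        z = scene$glomerulus_centers[, 1],
        y = scene$glomerulus_centers[, 2],
        x = scene$glomerulus_centers[, 3],
        radius_vox = scene$glomerulus_radius_vox,
        amplitude = amplitudes),
      shifts = tibble(frame = seq_len(nt),
                      dy = shifts[, "dy"], dx = shifts[, "dx"]),
      kinetics = tibble(frame = seq_len(nt), time_s = t_frame, g = g),
      scene = scene, timing = timing, seed = seed)
    list(volume = volume_series(arr, frame_period_s = scene$frame_period_s,
                                stimulus = timing, metadata = metadata),
         truth = truth)
  })
}

#' Build ROIs at the simulator's ground-truth glomerulus positions
#'
#' Convenience for validation runs: one disc ROI per glomerulus, shrunk by
#' `margin_px` so the ROI stays inside the flat top of the rendered blob
#' (the minimum filter erodes the blob rim by its radius). `kind` selects
#' map-space ROIs or plane-centered ROIs for trace extraction.
#'
#' @param truth Ground-truth list from [simulate_trial()] (`$truth`).
#' @param shape_yx Map dimensions `c(n_y, n_x)`.
#' @param margin_px Radial shrink in pixels (default 3).
#' @param kind ROI kind, see [roi()].
#' @return A [roi_set()] labelled `glom_1`, `glom_2`, ...
#' @export
ground_truth_rois <- function(truth, shape_yx, margin_px = 3,
                              kind = c("projection_2d", "plane_centered")) {
  kind <- match.arg(kind)
  gl <- truth$glomeruli
  rois <- lapply(seq_len(nrow(gl)), function(i) {
    r <- max(gl$radius_vox[i] - margin_px, 1)
    yy <- matrix(seq_len(shape_yx[1]), shape_yx[1], shape_yx[2])
    xx <- matrix(seq_len(shape_yx[2]), shape_yx[1], shape_yx[2], byrow = TRUE)
    mask <- (yy - gl$y[i])^2 + (xx - gl$x[i])^2 <= r^2
    roi(sprintf("glom_%d", gl$glomerulus[i]), mask, kind = kind,
        z_center = if (kind == "plane_centered") gl$z[i] else NA_integer_)
  })
  roi_set(rois)
}

#' Trial manifest following the study design
#'
#' Seven odorants, each presented three times in randomized blocks, for 21
#' odor stimulus trials per animal. Odorants default to a standard panel:
#' the two alarm pheromone components, general odorants, and the solvent
#' control.
#'
#' @param odorants Character vector of odorant names.
#' @param concentration_pct Single concentration per animal (typically 3 or
#'   48, percent v/v).
#' @param n_repeats Presentations per odorant (default 3).
#' @return A tibble with columns `trial_index`, `odorant`,
#'   `concentration_pct`, `repeat_index` (one block per repeat; use
#'   [simulate_experiment()] to randomize order within blocks).
#' @export
study_trial_manifest <- function(odorants = c("4-methyl-3-heptanone",
                                              "4-methyl-3-heptanol",
                                              "ethylpyrazine",
                                              "propionic acid",
                                              "3-hexanone",
                                              "isopropanol",
                                              "paraffin oil"),
                                 concentration_pct = 48,
                                 n_repeats = 3) {
  tibble(
    trial_index = seq_len(length(odorants) * n_repeats),
    odorant = rep(odorants, times = n_repeats),
    concentration_pct = concentration_pct,
    repeat_index = rep(seq_len(n_repeats), each = length(odorants))
  )
}

#' Simulate a full odor-panel experiment
#'
#' One trial per manifest row, with presentation order randomized within
#' each repeat block (the study presented its odor panel in a randomized
#' sequence repeated three times). Per-glomerulus amplitudes come from the
#' tuning matrix column for each trial's odorant.
#'
#' @param scene A [scene_config()].
#' @param manifest A manifest tibble as from [study_trial_manifest()].
#' @param tuning Glomerulus x odorant amplitude matrix with column names
#'   covering every odorant in the manifest; defaults to `scene$tuning`.
#' @param timing A [stimulus_timing()] shared by all trials.
#' @param seed Experiment seed (drives both trial order and per-trial
#'   noise/motion); defaults to `scene$seed`.
#' @return A list of trials (each as returned by [simulate_trial()], with
#'   odorant metadata attached), with the randomized manifest (including
#'   `random_order_position`) as attribute `"manifest"`.
#' @export
simulate_experiment <- function(scene, manifest = study_trial_manifest(),
                                tuning = NULL, timing = stimulus_timing(),
                                seed = NULL) {
  stopifnot(inherits(scene, "scene_config"))
  tuning <- tuning %||% scene$tuning
  if (is.null(tuning)) abort("No tuning matrix given (and scene has none).")
  tuning <- as.matrix(tuning)
  missing_od <- setdiff(unique(manifest$odorant), colnames(tuning))
  if (length(missing_od)) {
    abort(sprintf("Odorant(s) missing from tuning matrix: %s",
                  paste(missing_od, collapse = ", ")))
  }
  seed <- seed %||% scene$seed
  ord <- with_local_seed(seed, {
    unlist(lapply(split(seq_len(nrow(manifest)), manifest$repeat_index),
                  sample), use.names = FALSE)
  })
  manifest <- manifest[ord, ]
  manifest$random_order_position <- seq_len(nrow(manifest))
  trials <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    md <- list(odorant = row$odorant,
               concentration_pct = row$concentration_pct,
               repeat_index = row$repeat_index,
               trial_index = row$trial_index)
    trials[[i]] <- simulate_trial(
      scene, timing = timing, amplitudes = tuning[, row$odorant],
      metadata = md,
      seed = (seed + 1009L * row$trial_index) %% .Machine$integer.max)
    trials[[i]]$odorant <- row$odorant
    trials[[i]]$repeat_index <- row$repeat_index
    trials[[i]]$trial_index <- row$trial_index
  }
  attr(trials, "manifest") <- as_tibble(manifest)
  trials
}
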