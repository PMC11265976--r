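#' Mean of a 2D map over an ROI mask
#'
#' @param map Numeric matrix (e.g. a [build_response_map()] result).
#' @param roi An [roi()] whose mask matches the map's dimensions.
#' @return Scalar arithmetic mean over the masked pixels.
#' @export
roi_mean <- function(map, roi) {
  if (!inherits(roi, "roi")) abort("`roi` must be an roi object.")
  if (!all(dim(roi$mask) == dim(map))) {
    abort(sprintf("ROI '%s' mask (%s) does not match map (%s).", roi$label,
                  paste(dim(roi$mask), collapse = "x"),
                  paste(dim(map), collapse = "x")))
  }
  if (!any(roi$mask)) abort(sprintf("ROI '%s' has an empty mask.", roi$label))
  mean(map[roi$mask])
}

#' Mean peak fold change across the entire antennal lobe
#'
#' Large-scale AL activation: the mean response-map value inside a single
#' ROI drawn around the AL boundary (one AL ROI per animal, drawn on a
#' max-Z projection of raw fluorescence).
#'
#' @param map A response map.
#' @param al_roi The whole-AL boundary [roi()].
#' @return Scalar mean peak fold change over the AL.
#' @export
whole_al_mean <- function(map, al_roi) roi_mean(map, al_roi)

#' Classify responding ROIs across an odor panel
#'
#' For every ROI x odorant, the ROI-mean peak fold change is averaged
#' across that odorant's (non-excluded) trials; the ROI is called
#' responding when that across-trial mean is `>= threshold` (inclusive,
#' default 0.2). Trials flagged for motion artifacts are dropped before
#' averaging; an odorant with no usable trial yields an undetermined call
#' (`responds = NA`), never `FALSE`.
#'
#' When the whole-AL ROI is supplied, each odorant's across-trial mean map
#' is additionally checked for broad activation: if more than
#' `broad_fraction` of AL pixels exceed the threshold the call rows carry
#' `broad_response = TRUE`, flagging panels where discrete responding
#' glomeruli cannot be counted meaningfully.
#'
#' @param maps List of response maps (one per trial).
#' @param rois A [roi_set()] of glomerulus-scale ROIs in map space.
#' @param odorants Character vector: the odorant of each trial in `maps`.
#' @param threshold Responding threshold on the across-trial mean
#'   (default 0.2).
#' @param excluded Logical vector flagging trials to drop (e.g. from
#'   [flag_motion_artifact()]); default none.
#' @param al_roi Optional whole-AL [roi()] enabling the broad-response flag.
#' @param broad_fraction AL-pixel fraction above threshold that triggers the
#'   broad-response flag (default 0.25).
#' @return A tibble with one row per ROI x odorant: `roi_label`, `odorant`,
#'   `n_trials`, `mean_peak`, `responds`, `threshold` (and
#'   `broad_response` when `al_roi` is given), with the per-odorant
#'   responding-ROI counts as attribute `"n_responding"` (also via
#'   [count_responding()]).
#' @export
classify_responding_rois <- function(maps, rois, odorants, threshold = 0.2,
                                     excluded = NULL, al_roi = NULL,
                                     broad_fraction = 0.25) {
  if (length(odorants) != length(maps)) {
    abort("`odorants` must name the odorant of every trial map.")
  }
  excluded <- excluded %||% rep(FALSE, length(maps))
  if (length(excluded) != length(maps)) {
    abort("`excluded` must have one flag per trial map.")
  }
  per_trial <- purrr::map_dfr(seq_along(maps), function(i) {
    tibble(trial = i, odorant = odorants[i], excluded = excluded[i],
           roi_label = vapply(rois, function(r) r$label, character(1)),
           roi_mean = vapply(rois, function(r) roi_mean(maps[[i]], r),
                             numeric(1)))
  })
  calls <- per_trial %>%
    filter(!.data$excluded) %>%
    group_by(.data$roi_label, .data$odorant) %>%
    summarise(n_trials = dplyr::n(), mean_peak = mean(.data$roi_mean),
              .groups = "drop")
  # odorants whose trials were all excluded: undetermined, not FALSE
  all_pairs <- tidyr::expand_grid(
    roi_label = vapply(rois, function(r) r$label, character(1)),
    odorant = unique(odorants))
  calls <- all_pairs %>%
    left_join(calls, by = c("roi_label", "odorant")) %>%
    mutate(n_trials = tidyr::replace_na(.data$n_trials, 0L),
           responds = dplyr::if_else(.data$n_trials > 0,
                                     .data$mean_peak >= threshold, NA),
           threshold = threshold)
  if (!is.null(al_roi)) {
    broad <- purrr::map_dfr(unique(odorants), function(od) {
      use <- which(odorants == od & !excluded)
      if (!length(use)) return(tibble(odorant = od, broad_response = NA))
      mm <- Reduce(`+`, maps[use]) / length(use)
      frac <- mean(mm[al_roi$mask] > threshold)
      tibble(odorant = od, broad_response = frac > broad_fraction)
    })
    calls <- left_join(calls, broad, by = "odorant")
  }
  n_resp <- calls %>%
    group_by(.data$odorant) %>%
    summarise(n_responding = sum(.data$responds, na.rm = TRUE),
              .groups = "drop")
  attr(calls, "n_responding") <- n_resp
  calls
}

#' @rdname classify_responding_rois
#' @param calls A call table from `classify_responding_rois()`.
#' @export
count_responding <- function(calls) {
  attr(calls, "n_responding") %||%
    (calls %>%
       group_by(.data$odorant) %>%
       summarise(n_responding = sum(.data$responds, na.rm = TRUE),
                 .groups = "drop"))
}

#' Propose candidate ROIs from repeated suprathreshold responses
#'
#' Automates the "responded in at least two trials" screening step:
#' pixels exceeding `threshold` in at least `min_trials` of the supplied
#' maps are grouped into connected components, and components within
#' glomerulus-scale area bounds become candidate ROIs. Intended as an aid
#' for drawing curated ROIs, not a replacement.
#'
#' @param maps List of response maps (>= 2).
#' @param threshold Pixel threshold (default 0.2).
#' @param min_trials Minimum number of maps a pixel must exceed the
#'   threshold in (default 2).
#' @param min_area,max_area Component area bounds in pixels.
#' @return A [roi_set()] of `projection_2d` ROIs labelled `cand_1`,
#'   `cand_2`, ... (possibly empty).
#' @export
candidate_rois_from_trials <- function(maps, threshold = 0.2, min_trials = 2,
                                       min_area = 5, max_area = Inf) {
  if (length(maps) < 2) abort("Need at least 2 trial maps.")
  counts <- Reduce(`+`, lapply(maps, function(m) unclass(m) > threshold))
  mask <- counts >= min_trials
  if (!any(mask)) return(roi_set(list()))
  labels <- label_components(mask)
  ids <- setdiff(unique(as.vector(labels)), 0)
  rois <- list()
  for (id in ids) {
    comp <- labels == id
    if (sum(comp) >= min_area && sum(comp) <= max_area) {
      rois[[length(rois) + 1L]] <-
        roi(sprintf("cand_%d", length(rois) + 1L), comp)
    }
  }
  roi_set(rois)
}

# 4-connected component labelling; EBImage::bwlabel when available,
# otherwise a small BFS fallback so the helper works without it.
label_components <- function(mask) {
  if (requireNamespace("EBImage", quietly = TRUE)) {
    return(matrix(as.integer(EBImage::bwlabel(mask)), nrow(mask), ncol(mask)))
  }
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  todo <- which(mask & lab == 0L)
  ny <- nrow(mask)
  while (length(todo)) {
    cur <- cur + 1L
    queue <- todo[1]
    lab[queue] <- cur
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      y <- (i - 1L) %% ny + 1L; x <- (i - 1L) %/% ny + 1L
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        yy <- y + d[1]; xx <- x + d[2]
        if (yy >= 1 && yy <= ny && xx >= 1 && xx <= ncol(mask)) {
          j <- yy + (xx - 1L) * ny
          if (mask[j] && lab[j] == 0L) {
            lab[j] <- cur
            queue <- c(queue, j)
          }
        }
      }
    }
    todo <- which(mask & lab == 0L)
  }
  lab
}

#' Fold-change time course of one glomerulus
#'
#' Per frame, the maximum-intensity projection across the plane containing
#' the glomerulus center and the planes directly above and below it (planes
#' at the volume edge use the available neighbors); fold change of that
#' projected series against its frames 1-5 baseline; then the ROI mean per
#' frame. The response magnitude (AUC) is the sum of the trace over frames
#' 6-40; movies shorter than the AUC window return the trace with `auc`
#' absent and a warning.
#'
#' @param vol A (stabilized) [volume_series()].
#' @param roi A `plane_centered` [roi()] with `z_center` set.
#' @param baseline_frames,auc_frames 1-based windows (defaults 1:5, 6:40).
#' @param epsilon Undefined-baseline threshold, see [fold_change()].
#' @return A `glomerular_trace` tibble (`frame`, `time_s`, `fold_change`)
#'   with attributes `roi_label`, `auc`, `auc_frames`, `planes_used`,
#'   `frame_period_s`.
#' @export
glomerular_trace <- function(vol, roi, baseline_frames = 1:5,
                             auc_frames = 6:40, epsilon = NULL) {
  stopifnot(inherits(vol, "volume_series"))
  if (roi$kind != "plane_centered" || is.na(roi$z_center)) {
    abort("`roi` must be plane_centered with a z_center.")
  }
  d <- dim(vol$data)
  planes <- intersect(roi$z_center + (-1:1), seq_len(d[2]))
  if (!roi$z_center %in% seq_len(d[2])) {
    abort(sprintf("z_center %d outside the volume (%d planes).",
                  roi$z_center, d[2]))
  }
  if (length(planes) < 3) {
    inform(sprintf(
      "glomerular_trace('%s'): z_center %d at volume edge; using %d plane(s).",
      roi$label, roi$z_center, length(planes)))
  }
  proj <- Reduce(pmax, lapply(planes, function(p) vol$data[, p, , ]))
  nt <- d[1]
  b <- colMeans(proj[baseline_frames, , , drop = FALSE], dims = 1)
  epsilon <- epsilon %||% (1e-6 * max(vol$data))
  undef <- b <= epsilon
  bsafe <- ifelse(undef, 1, b)
  fc <- (proj - rep(bsafe, each = nt)) / rep(bsafe, each = nt)
  if (any(undef)) fc[rep(undef, each = nt)] <- 0
  if (!all(dim(roi$mask) == d[3:4])) {
    abort(sprintf("ROI '%s' mask does not match the plane shape.", roi$label))
  }
  fcm <- matrix(fc, nrow = nt)
  trace <- rowMeans(fcm[, which(roi$mask), drop = FALSE])
  auc <- NA_real_
  if (nt >= max(auc_frames)) {
    auc <- sum(trace[auc_frames])
  } else {
    warn(sprintf("Movie has %d frames; AUC window needs %d. AUC not computed.",
                 nt, max(auc_frames)))
  }
  out <- tibble(frame = seq_len(nt),
                time_s = (seq_len(nt) - 1) * vol$frame_period_s,
                fold_change = trace)
  structure(out, roi_label = roi$label, auc = auc, auc_frames = auc_frames,
            planes_used = planes, frame_period_s = vol$frame_period_s,
            class = c("glomerular_trace", class(out)))
}

#' @rdname glomerular_trace
#' @param trace A `glomerular_trace`.
#' @export
trace_auc <- function(trace) attr(trace, "auc")

#' Compare a measurement between age cohorts
#'
#' Two-sided Welch's t test (unequal variances, Welch-Satterthwaite degrees
#' of freedom) or Wilcoxon rank-sum test (with continuity correction in the
#' normal approximation) between two groups of per-animal values. If both
#' groups are constant and equal, the comparison is degenerate and `p = 1`
#' is returned by convention (with a message).
#'
#' @param values_young,values_old Numeric vectors (n >= 2 per group for
#'   `welch_t`, n >= 1 for `wilcoxon`).
#' @param test `"welch_t"` or `"wilcoxon"`.
#' @return One-row tibble: `test`, `statistic`, `p_value`, `n_young`,
#'   `n_old`.
#' @export
compare_cohorts <- function(values_young, values_old,
                            test = c("welch_t", "wilcoxon")) {
  test <- match.arg(test)
  ny <- length(values_young); no <- length(values_old)
  if (!ny || !no) abort("Both groups must be nonempty.")
  if (test == "welch_t" && (ny < 2 || no < 2)) {
    abort("Welch's t test needs at least 2 values per group.")
  }
  degenerate <- sd(values_young) == 0 && sd(values_old) == 0 &&
    mean(values_young) == mean(values_old)
  if (degenerate) {
    inform("Both groups constant and equal; returning p = 1 by convention.")
    res <- list(statistic = 0, p.value = 1)
  } else if (test == "welch_t") {
    res <- t.test(values_young, values_old, var.equal = FALSE)
  } else {
    res <- suppressWarnings(wilcox.test(values_young, values_old))
  }
  tibble(test = test, statistic = unname(res$statistic),
         p_value = res$p.value, n_young = ny, n_old = no)
}
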