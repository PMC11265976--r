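#' Plot a peak-response map
#'
#' Diverging raster of the clipped max-Z peak fold change, zero-centered so
#' suppression (towards -1) and excitation (towards the clip ceiling) read
#' directly off the color.
#'
#' @param object A `response_map` from [build_response_map()].
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot response_map
#' @export
autoplot.response_map <- function(object, ...) {
  prov <- attr(object, "provenance")
  lims <- prov$clip %||% range(object)
  df <- tidyr::expand_grid(y = seq_len(nrow(object)),
                           x = seq_len(ncol(object)))
  df$value <- as.vector(unclass(object))   # column-major: y fastest, matches
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient2(low = "steelblue4", mid = "black", high = "yellow",
                         midpoint = 0, limits = lims,
                         name = "peak dF/F") +
    coord_fixed(expand = FALSE) +
    ggplot2::scale_y_reverse() +
    labs(x = NULL, y = NULL, title = "Peak fold-change response map") +
    theme_minimal()
}

#' Plot a glomerular fold-change trace
#'
#' Line plot of the 3-plane max-Z fold-change time course with the AUC
#' window shaded.
#'
#' @param object A `glomerular_trace` from [glomerular_trace()].
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot glomerular_trace
#' @export
autoplot.glomerular_trace <- function(object, ...) {
  af <- attr(object, "auc_frames")
  per <- attr(object, "frame_period_s")
  gg <- ggplot(object, aes(x = .data$time_s, y = .data$fold_change)) +
    ggplot2::annotate("rect", xmin = (min(af) - 1) * per,
                      xmax = (max(af) - 1) * per,
                      ymin = -Inf, ymax = Inf, alpha = 0.08, fill = "orange") +
    geom_line(linewidth = 0.6) +
    labs(x = "time (s)", y = "fold change (dF/F)",
         title = sprintf("Glomerulus %s%s", attr(object, "roi_label"),
                         if (is.na(attr(object, "auc"))) ""
                         else sprintf("  (AUC = %.3g)", attr(object, "auc")))) +
    theme_minimal()
  gg
}

#' Plot grouped proportions with shared and separate fitted curves
#'
#' Points are the observed proportions per group; solid lines the separate
#' per-group fits, the dashed line the single pooled curve the F test
#' compares them against.
#'
#' @param object A `curve_comparison` from [extra_ss_f_test()].
#' @param n_curve Number of curve evaluation points (default 200).
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot curve_comparison
#' @export
autoplot.curve_comparison <- function(object, n_curve = 200, ...) {
  pts <- purrr::map_dfr(object$groups, function(g) {
    f <- object$group_fits[[g]]
    tibble(group = g, t = f$data$t, y = f$data$y)
  })
  tt <- seq(min(pts$t), max(pts$t), length.out = n_curve)
  curves <- purrr::map_dfr(object$groups, function(g) {
    tibble(group = g, t = tt, y = predict(object$group_fits[[g]], tt))
  })
  pooled <- tibble(t = tt, y = predict(object$null_fit, tt))
  ggplot(pts, aes(x = .data$t, y = .data$y, color = .data$group)) +
    geom_point(alpha = 0.8) +
    geom_line(data = curves, linewidth = 0.7) +
    geom_line(data = pooled, aes(color = NULL), linetype = "dashed",
              color = "grey30") +
    labs(x = "time from stimulus (s)", y = "proportion outside nest",
         title = sprintf("F(%d, %d) = %.3g, p = %.3g (%s curves preferred)",
                         object$df_num, object$df_den, object$F,
                         object$p_value, object$preferred)) +
    theme_minimal()
}

#' Plot outside-nest proportions per cohort
#'
#' @param props A [proportion_outside()] table.
#' @return A ggplot of proportion versus time, colored by cohort when
#'   present.
#' @export
plot_proportions <- function(props) {
  has_cohort <- "age_class" %in% names(props)
  aes_map <- if (has_cohort) {
    aes(x = .data$time_s, y = .data$proportion, color = .data$age_class)
  } else {
    aes(x = .data$time_s, y = .data$proportion)
  }
  ggplot(props, aes_map) +
    geom_point() + geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::ylim(0, 1) +
    labs(x = "time from stimulus (s)", y = "proportion outside nest",
         color = "cohort") +
    theme_minimal()
}
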