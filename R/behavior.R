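#' Define the nest from early tracking data
#'
#' The nest center is the coordinate-wise median location of all ants over
#' all samples in the first `window_s` seconds (default the first 5 min,
#' before any stimulus), and the nest is the circle of `radius_cm` around
#' it (default 0.25 cm).
#'
#' @param tracks Tracking tibble with columns `time_s`, `ant_id`,
#'   `age_class`, `x_cm`, `y_cm` (see [read_tracks_csv()]).
#' @param window_s Window end in seconds (default 300).
#' @param radius_cm Nest radius in cm (default 0.25).
#' @return A `nest_model`: list with `center_cm = c(x, y)` and `radius_cm`.
#' @export
nest_from_tracks <- function(tracks, window_s = 300, radius_cm = 0.25) {
  check_scalar_number(radius_cm, "radius_cm", lower = 0, strict_lower = TRUE)
  w <- tracks[tracks$time_s <= window_s, ]
  if (!nrow(w)) abort("No tracking samples inside the nest-definition window.")
  structure(list(center_cm = c(x = median(w$x_cm), y = median(w$y_cm)),
                 radius_cm = radius_cm),
            class = "nest_model")
}

#' @export
print.nest_model <- function(x, ...) {
  cat(sprintf("<nest_model> center (%.3g, %.3g) cm, radius %.3g cm\n",
              x$center_cm[1], x$center_cm[2], x$radius_cm))
  invisible(x)
}

#' Proportion of ants outside the nest on a 10 s grid
#'
#' At each gridpoint (seconds relative to stimulus placement, t = 0), an
#' ant is outside the nest when its centroid distance from the nest center
#' strictly exceeds `radius + body_radius` - the body-radius margin stands
#' in for the stricter requirement that no part of the ant's body touch the
#' nest circle, which centroids alone cannot express. Each ant contributes its nearest
#' tracking sample within `match_tol_s`; ants with no sample near a
#' gridpoint are excluded from that timepoint's total (and counted in the
#' `n_missing` column).
#'
#' @param tracks Tracking tibble (`time_s`, `ant_id`, `age_class`, `x_cm`,
#'   `y_cm`).
#' @param nest A [nest_from_tracks()] result.
#' @param stimulus_time_s Absolute time at which the stimulus was placed.
#' @param body_radius_cm Body margin in cm (default 0.15).
#' @param grid_s Relative timepoints (default `seq(-60, 60, 10)`, the
#'   minute before and after the stimulus counted every 10 s).
#' @param match_tol_s Sample-matching tolerance (default 5 s).
#' @param by_cohort Split proportions by `age_class` (default TRUE); set
#'   FALSE for colony totals.
#' @return Tibble with `time_s` (relative), `age_class` (unless
#'   `by_cohort = FALSE`), `n_outside`, `n_total`, `n_missing`,
#'   `proportion`.
#' @export
proportion_outside <- function(tracks, nest, stimulus_time_s,
                               body_radius_cm = 0.15,
                               grid_s = seq(-60, 60, by = 10),
                               match_tol_s = 5, by_cohort = TRUE) {
  check_scalar_number(body_radius_cm, "body_radius_cm", lower = 0)
  lim <- nest$radius_cm + body_radius_cm
  n_ants <- dplyr::n_distinct(tracks$ant_id)
  out <- purrr::map_dfr(grid_s, function(g) {
    target <- stimulus_time_s + g
    near <- tracks %>%
      filter(abs(.data$time_s - target) <= match_tol_s) %>%
      group_by(.data$ant_id) %>%
      slice_min(abs(.data$time_s - target), n = 1, with_ties = FALSE) %>%
      ungroup()
    near <- near %>%
      mutate(outside = sqrt((.data$x_cm - nest$center_cm[1])^2 +
                              (.data$y_cm - nest$center_cm[2])^2) > lim)
    grp <- if (by_cohort) near %>% group_by(.data$age_class) else near
    grp %>%
      summarise(n_outside = sum(.data$outside), n_total = dplyr::n(),
                .groups = "drop") %>%
      mutate(time_s = g)
  })
  per_time <- tapply(out$n_total, out$time_s, sum)
  if (any(per_time < n_ants)) {
    inform("Some ants lacked a tracking sample near one or more gridpoints.")
  }
  cols <- c("time_s", if (by_cohort) "age_class", "n_outside", "n_total")
  out %>%
    mutate(n_missing = if (by_cohort) NA_integer_ else n_ants - .data$n_total,
           proportion = .data$n_outside / .data$n_total) %>%
    select(all_of(cols), "n_missing", "proportion") %>%
    arrange(.data$time_s)
}

#' Logistic growth curve
#'
#' `Y(t) = Y0 * YM / ((YM - Y0) * exp(-k t) + Y0)`: proportion `Y0` at
#' t = 0 growing sigmoidally to plateau `YM` at rate `k` (1/s). The
#' degenerate `YM = Y0` case is the constant `Y0`.
#'
#' @param t Time in seconds (vectorised).
#' @param Y0 Proportion at t = 0, in `[0, 1]`.
#' @param YM Plateau proportion, in `[0, 1]`.
#' @param k Growth rate (1/s, >= 0).
#' @return Curve values.
#' @export
logistic_growth <- function(t, Y0, YM, k) {
  if (Y0 == 0 || YM == 0) return(rep(0, length(t)))
  Y0 * YM / ((YM - Y0) * exp(-k * t) + Y0)
}

logistic_starts <- function(t, y) {
  y0 <- min(max(y[which.min(t)], 0.01), 0.99)
  ym <- min(max(max(y), y0 + 0.01), 1)
  # crude 10%-90% rise-time rate estimate on the post-stimulus points
  yn <- (y - y0) / max(ym - y0, 1e-6)
  ord <- order(t)
  t10 <- t[ord][which(yn[ord] >= 0.1)[1]]
  t90 <- t[ord][which(yn[ord] >= 0.9)[1]]
  k0 <- if (!is.na(t10) && !is.na(t90) && t90 > t10) log(81) / (t90 - t10)
        else 0.1
  # deterministic multi-start fan over the rate (and a plateau tweak)
  list(
    c(Y0 = y0, YM = ym, k = k0),
    c(Y0 = y0, YM = ym, k = k0 / 3),
    c(Y0 = y0, YM = ym, k = k0 * 3),
    c(Y0 = y0, YM = min(1, ym * 0.8 + 0.1), k = k0 / 10),
    c(Y0 = min(0.5, y0 * 2 + 0.01), YM = ym, k = k0 * 10)
  )
}

#' Fit a logistic growth curve by bounded least squares
#'
#' Nonlinear least squares (Levenberg-Marquardt via `minpack.lm::nlsLM`)
#' of [logistic_growth()] to proportion data, with `Y0, YM` bounded to
#' `[0, 1]` and `k >= 0`. Initialization is deterministic: `Y0` from the
#' earliest observation, `YM` from the maximum, `k` from the 10%-90% rise
#' time, fanned into five starts over the rate; the best converged fit by
#' residual sum of squares is kept. Constant data are returned directly as
#' the degenerate constant curve.
#'
#' @param t Timepoints in seconds (t = 0 at stimulus placement; the study
#'   window is -10 s to +60 s).
#' @param y Proportions in `[0, 1]`, same length as `t` (>= 4 points).
#' @param weights Optional observation weights (default equal).
#' @param starts Optional list of named start vectors overriding the
#'   built-in multi-start rule.
#' @return A `logistic_growth_fit`: coefficients `Y0`, `YM`, `k`, residual
#'   sum of squares `ss_resid`, `n_points`, `n_params = 3`,
#'   `df = n_points - 3`, the data, and fitted values. Supports
#'   [predict()], [tidy()] and [glance()].
#' @export
fit_logistic_growth <- function(t, y, weights = NULL, starts = NULL) {
  if (length(t) != length(y)) abort("`t` and `y` must have equal length.")
  if (length(t) < 4) abort("Need at least 4 points to fit 3 parameters.")
  if (any(!is.finite(y))) abort("`y` must be finite.")
  # noisy observed proportions may stray slightly outside [0, 1]; only the
  # parameters are bounded
  dat <- data.frame(t = t, y = y)
  weights <- weights %||% rep(1, length(y))
  if (sd(y) == 0) {
    est <- c(Y0 = y[1], YM = y[1], k = 0)
    return(new_logistic_fit(est, dat, fitted = rep(y[1], length(y)),
                            converged = TRUE))
  }
  starts <- starts %||% logistic_starts(t, y)
  best <- NULL
  last_err <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ Y0 * YM / ((YM - Y0) * exp(-k * t) + Y0),
        data = dat, start = as.list(st), weights = weights,
        lower = c(Y0 = 0, YM = 0, k = 0), upper = c(Y0 = 1, YM = 1, k = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      last_err <- fit
      next
    }
    ss <- sum(stats::resid(fit)^2)
    if (is.null(best) || ss < best$ss) best <- list(fit = fit, ss = ss)
  }
  if (is.null(best)) {
    abort(sprintf("Logistic fit failed from all starts (last error: %s).",
                  conditionMessage(last_err)))
  }
  est <- coef(best$fit)
  new_logistic_fit(est, dat, fitted = as.numeric(stats::fitted(best$fit)),
                   converged = TRUE)
}

new_logistic_fit <- function(est, dat, fitted, converged) {
  ss <- sum((dat$y - fitted)^2)
  structure(
    list(coefficients = est, ss_resid = ss, n_points = nrow(dat),
         n_params = 3L, df = nrow(dat) - 3L, data = as_tibble(dat),
         fitted = fitted, converged = converged,
         model_family = "logistic_growth"),
    class = "logistic_growth_fit")
}

#' @export
print.logistic_growth_fit <- function(x, ...) {
  cat(sprintf(
    "<logistic_growth_fit> Y0 = %.4g, YM = %.4g, k = %.4g /s (SS %.4g, df %d)\n",
    x$coefficients["Y0"], x$coefficients["YM"], x$coefficients["k"],
    x$ss_resid, x$df))
  invisible(x)
}

#' @export
predict.logistic_growth_fit <- function(object, t = NULL, ...) {
  t <- t %||% object$data$t
  logistic_growth(t, object$coefficients["Y0"], object$coefficients["YM"],
                  object$coefficients["k"])
}

#' @method tidy logistic_growth_fit
#' @export
tidy.logistic_growth_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients))
}

#' @method glance logistic_growth_fit
#' @export
glance.logistic_growth_fit <- function(x, ...) {
  tibble(ss_resid = x$ss_resid, n_points = x$n_points, df = x$df,
         converged = x$converged)
}

#' Fit a quadratic (2nd-order polynomial) trend
#'
#' Ordinary least squares of `y = a t^2 + b t + c`, the model family used
#' when responses (e.g. to the vehicle control) are not sigmoidal.
#'
#' @param t,y Numeric vectors (>= 4 points; at least 3 distinct `t`).
#' @return A `quadratic_fit` with coefficients `a`, `b`, `c`, `ss_resid`,
#'   `n_points`, `n_params = 3`, `df`. Supports [predict()], [tidy()],
#'   [glance()].
#' @export
fit_quadratic <- function(t, y) {
  if (length(t) != length(y)) abort("`t` and `y` must have equal length.")
  if (length(t) < 4) abort("Need at least 4 points to fit 3 parameters.")
  if (length(unique(t)) < 3) abort("Rank-deficient design: need 3 distinct t.")
  fit <- lm(y ~ I(t^2) + t)
  est <- c(a = unname(coef(fit)[2]), b = unname(coef(fit)[3]),
           c = unname(coef(fit)[1]))
  structure(
    list(coefficients = est, ss_resid = sum(stats::resid(fit)^2),
         n_points = length(y), n_params = 3L, df = length(y) - 3L,
         data = tibble(t = t, y = y),
         fitted = as.numeric(stats::fitted(fit)),
         model_family = "quadratic"),
    class = "quadratic_fit")
}

#' @export
print.quadratic_fit <- function(x, ...) {
  cat(sprintf("<quadratic_fit> a = %.4g, b = %.4g, c = %.4g (SS %.4g, df %d)\n",
              x$coefficients["a"], x$coefficients["b"], x$coefficients["c"],
              x$ss_resid, x$df))
  invisible(x)
}

#' @export
predict.quadratic_fit <- function(object, t = NULL, ...) {
  t <- t %||% object$data$t
  object$coefficients["a"] * t^2 + object$coefficients["b"] * t +
    object$coefficients["c"]
}

#' @method tidy quadratic_fit
#' @export
tidy.quadratic_fit <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @method glance quadratic_fit
#' @export
glance.quadratic_fit <- function(x, ...) {
  tibble(ss_resid = x$ss_resid, n_points = x$n_points, df = x$df)
}

fit_family <- function(t, y, model_family, starts = NULL) {
  if (model_family == "logistic_growth") fit_logistic_growth(t, y,
                                                             starts = starts)
  else fit_quadratic(t, y)
}

#' Extra sum-of-squares F test for shared versus separate curves
#'
#' Tests whether one curve suffices for all groups (age cohorts, or
#' stimuli) or the data are better fit by separate curves per group. The
#' null model fits a single parameter set to the pooled data
#' (`ss_null`, `df_null = N - p`); the alternative fits each group
#' independently (`ss_alt` = summed group SS, `df_alt = N - G p`). Then
#'
#' `F = ((ss_null - ss_alt) / (df_null - df_alt)) / (ss_alt / df_alt)`
#'
#' with p-value from the F distribution on `(df_null - df_alt, df_alt)`
#' degrees of freedom; separate curves are preferred when `p < alpha`.
#' Should a group fit land above the pooled fit (nested models forbid it
#' beyond round-off), the group is refit seeded from the pooled estimates
#' and the SS difference floored at zero.
#'
#' @param data Tibble of grouped response series.
#' @param time,proportion,group Columns (tidy-eval) holding the timepoints
#'   (seconds, t = 0 at stimulus), the proportions, and the grouping factor;
#'   defaults `time_s`, `proportion`, `group`.
#' @param model_family `"logistic_growth"` (default) or `"quadratic"`.
#' @param alpha Significance level for the preferred-model label
#'   (default 0.05).
#' @return A `curve_comparison`: F statistic, numerator/denominator df,
#'   p-value, `preferred` (`"single"` or `"separate"`), the pooled and
#'   per-group fits, and the SS/df bookkeeping. Supports [tidy()] and
#'   [glance()].
#' @export
extra_ss_f_test <- function(data, time = .data$time_s,
                            proportion = .data$proportion,
                            group = .data$group,
                            model_family = c("logistic_growth", "quadratic"),
                            alpha = 0.05) {
  model_family <- match.arg(model_family)
  t_all <- eval_tidy(enquo(time), data)
  y_all <- eval_tidy(enquo(proportion), data)
  g_all <- as.character(eval_tidy(enquo(group), data))
  groups <- unique(g_all)
  if (length(groups) < 2) abort("Need at least 2 groups to compare curves.")
  n_total <- length(y_all)
  p <- 3L
  null_fit <- fit_family(t_all, y_all, model_family)
  group_fits <- lapply(groups, function(g) {
    fit_family(t_all[g_all == g], y_all[g_all == g], model_family)
  })
  names(group_fits) <- groups
  # nested models: pooled SS can never beat the summed group SS; retry any
  # group from the pooled solution if the optimizer left one above it
  ss_alt <- sum(vapply(group_fits, function(f) f$ss_resid, numeric(1)))
  if (model_family == "logistic_growth" &&
      ss_alt > null_fit$ss_resid * (1 + 1e-8)) {
    for (g in groups) {
      refit <- tryCatch(
        fit_logistic_growth(t_all[g_all == g], y_all[g_all == g],
                            starts = list(null_fit$coefficients)),
        error = function(e) NULL)
      if (!is.null(refit) && refit$ss_resid < group_fits[[g]]$ss_resid) {
        group_fits[[g]] <- refit
      }
    }
    ss_alt <- sum(vapply(group_fits, function(f) f$ss_resid, numeric(1)))
  }
  df_null <- n_total - p
  df_alt <- n_total - length(groups) * p
  if (df_alt <= 0) {
    abort("Too few points: denominator degrees of freedom would be <= 0.")
  }
  df_num <- df_null - df_alt
  ss_drop <- max(null_fit$ss_resid - ss_alt, 0)
  F_stat <- (ss_drop / df_num) / (ss_alt / df_alt)
  p_value <- pf(F_stat, df_num, df_alt, lower.tail = FALSE)
  structure(
    list(model_family = model_family,
         ss_null = null_fit$ss_resid, df_null = df_null,
         ss_alt = ss_alt, df_alt = df_alt,
         F = F_stat, df_num = df_num, df_den = df_alt,
         p_value = p_value,
         preferred = if (p_value < alpha) "separate" else "single",
         alpha = alpha, groups = groups,
         null_fit = null_fit, group_fits = group_fits),
    class = "curve_comparison")
}

#' @export
print.curve_comparison <- function(x, ...) {
  cat(sprintf("<curve_comparison> %s curves, %d groups (%s)\n",
              x$model_family, length(x$groups),
              paste(x$groups, collapse = ", ")))
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g -> %s curve(s) preferred\n",
              x$df_num, x$df_den, x$F, x$p_value, x$preferred))
  cat(sprintf("  SS: single %.4g (df %d) vs separate %.4g (df %d)\n",
              x$ss_null, x$df_null, x$ss_alt, x$df_alt))
  invisible(x)
}

#' @method tidy curve_comparison
#' @export
tidy.curve_comparison <- function(x, ...) {
  bind_rows(
    tibble(model = "single", group = "pooled",
           term = names(x$null_fit$coefficients),
           estimate = unname(x$null_fit$coefficients)),
    purrr::map_dfr(x$groups, function(g) {
      tibble(model = "separate", group = g,
             term = names(x$group_fits[[g]]$coefficients),
             estimate = unname(x$group_fits[[g]]$coefficients))
    })
  )
}

#' @method glance curve_comparison
#' @export
glance.curve_comparison <- function(x, ...) {
  tibble(model_family = x$model_family, statistic = x$F,
         df_num = x$df_num, df_den = x$df_den, p_value = x$p_value,
         ss_null = x$ss_null, ss_alt = x$ss_alt, preferred = x$preferred)
}

#' Read / write tracking tables
#'
#' Plain CSV with header `time_s, ant_id, age_class, x_cm, y_cm` - the
#' layout colony-tracker exports are reshaped into.
#'
#' @param path CSV path.
#' @return [read_tracks_csv()]: a tibble. [write_tracks_csv()]: `path`,
#'   invisibly.
#' @export
read_tracks_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "ant_id", "age_class", "x_cm", "y_cm")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(sprintf("Tracking CSV lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  as_tibble(df)
}

#' @rdname read_tracks_csv
#' @param tracks Tracking tibble.
#' @export
write_tracks_csv <- function(tracks, path) {
  write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}
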