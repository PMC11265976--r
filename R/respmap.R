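#' Per-pixel fluorescence baseline
#'
#' The baseline is the per-pixel mean of the first five frames (1-based
#' frames 1-5 by default), acquired before calcium responses are typically
#' detected.
#'
#' @param movie A [volume_series()] or 4D array `[frame, z, y, x]`.
#' @param baseline_frames 1-based frame window (default 1:5).
#' @return Numeric array `[z, y, x]` of per-pixel baselines.
#' @export
compute_baseline <- function(movie, baseline_frames = 1:5) {
  arr <- if (inherits(movie, "volume_series")) movie$data else movie
  if (dim(arr)[1] < max(baseline_frames)) {
    abort(sprintf("Movie has %d frames; baseline window needs %d.",
                  dim(arr)[1], max(baseline_frames)))
  }
  colMeans(arr[baseline_frames, , , , drop = FALSE], dims = 1)
}

#' Fold change (dF/F) of a movie against a per-pixel baseline
#'
#' `FC_t = (F_t - B) / B` per pixel. Pixels whose baseline does not exceed
#' `epsilon` (default `1e-6` of the movie's intensity scale) have undefined
#' fold change; they are masked, set to 0, and counted.
#'
#' @param movie A [volume_series()] or 4D array.
#' @param baseline Array `[z, y, x]` from [compute_baseline()]; computed
#'   from `baseline_frames` if omitted.
#' @param baseline_frames Used when `baseline` is missing.
#' @param epsilon Baseline values `<= epsilon` are treated as undefined.
#' @return 4D array of fold-change values with attributes
#'   `undefined_mask` (logical `[z, y, x]`), `n_undefined`, and
#'   `baseline_frames`. Every defined value is `>= -1`.
#' @export
fold_change <- function(movie, baseline = NULL, baseline_frames = 1:5,
                        epsilon = NULL) {
  arr <- if (inherits(movie, "volume_series")) movie$data else movie
  baseline <- baseline %||% compute_baseline(arr, baseline_frames)
  if (!all(dim(baseline) == dim(arr)[-1])) {
    abort("`baseline` shape must match the movie's spatial shape.")
  }
  epsilon <- epsilon %||% (1e-6 * max(arr))
  nt <- dim(arr)[1]
  undef <- baseline <= epsilon
  bsafe <- ifelse(undef, 1, baseline)
  brep <- rep(bsafe, each = nt)           # frame index varies fastest
  fc <- (arr - brep) / brep
  if (any(undef)) {
    fc[rep(undef, each = nt)] <- 0
    inform(sprintf("fold_change: %d pixel(s) with baseline <= epsilon masked.",
                   sum(undef)))
  }
  structure(fc, undefined_mask = undef, n_undefined = sum(undef),
            baseline_frames = baseline_frames)
}

#' Peak fold change over the response window
#'
#' Per pixel, the mean fold change over 1-based frames 9-14 (the window in
#' which odor-evoked responses peak at the 0.83 s volume scan rate).
#'
#' @param fc 4D fold-change array from [fold_change()].
#' @param peak_frames 1-based frame window (default 9:14).
#' @return Array `[z, y, x]` of per-pixel peak fold change.
#' @export
peak_fold_change <- function(fc, peak_frames = 9:14) {
  if (dim(fc)[1] < max(peak_frames)) {
    abort(sprintf("Fold-change series has %d frames; peak window needs %d.",
                  dim(fc)[1], max(peak_frames)))
  }
  colMeans(fc[peak_frames, , , , drop = FALSE], dims = 1)
}

#' Minimum (rank) filter over a circular neighborhood
#'
#' Each pixel is replaced by the minimum over the disc of the given radius
#' (pixels with `dy^2 + dx^2 <= radius^2`); edges are handled by
#' nearest-value padding. `radius = 0` is the identity. The square
#' `(2r+1) x (2r+1)` window is available via `shape = "square"`.
#'
#' @param image Numeric matrix.
#' @param radius Neighborhood radius in pixels (default 2).
#' @param shape `"disc"` (default) or `"square"`.
#' @return Filtered matrix; pointwise `<=` the input.
#' @export
minimum_filter <- function(image, radius = 2, shape = c("disc", "square")) {
  shape <- match.arg(shape)
  check_scalar_number(radius, "radius", lower = 0)
  r <- as.integer(ceiling(radius))
  if (r == 0) return(image)
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  if (shape == "disc") {
    offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2 + 1e-9, ]
  }
  ny <- nrow(image); nx <- ncol(image)
  padr <- c(rep(1L, r), seq_len(ny), rep(ny, r))
  padc <- c(rep(1L, r), seq_len(nx), rep(nx, r))
  pad <- image[padr, padc, drop = FALSE]
  out <- matrix(Inf, ny, nx)
  for (i in seq_len(nrow(offs))) {
    out <- pmin(out, pad[(seq_len(ny)) + r + offs$dy[i],
                         (seq_len(nx)) + r + offs$dx[i], drop = FALSE])
  }
  out
}

#' Clip values into a closed range
#'
#' @param x Numeric.
#' @param bounds `c(lo, hi)` (default `c(-1, 4)`, the response-map display
#'   range: fold change cannot fall below -1 and values above 4 are
#'   saturated).
#' @return `x` with values outside `bounds` replaced by the bound.
#' @export
clip_values <- function(x, bounds = c(-1, 4)) {
  pmin(pmax(x, bounds[1]), bounds[2])
}

#' Build a peak-response map from a stabilized movie
#'
#' The full quantification chain, in fixed order: per-pixel baseline (mean
#' of frames 1-5) -> fold change -> per-pixel mean over the peak window
#' (frames 9-14) -> per-plane minimum filter (disc radius 2, noise
#' suppression) -> maximum-intensity projection across z -> clip to
#' `[-1, 4]`. The result is the 2D map on which whole-AL means and
#' responding-ROI classification are computed.
#'
#' @param vol A (stabilized) [volume_series()] or 4D array.
#' @param baseline_frames,peak_frames 1-based frame windows (defaults 1:5
#'   and 9:14); the baseline window must precede the peak window.
#' @param min_filter_radius Minimum-filter radius (default 2; 0 disables).
#' @param min_filter_shape `"disc"` (default) or `"square"`.
#' @param clip Clip bounds (default `c(-1, 4)`).
#' @param epsilon Undefined-baseline threshold, see [fold_change()].
#' @param filter_before_projection Apply the minimum filter per plane before
#'   the max-Z projection (default TRUE, the printed order); FALSE filters
#'   the projected map instead, for sensitivity analysis.
#' @return A `response_map`: numeric matrix `[n_y, n_x]` with a
#'   `provenance` attribute recording every parameter used.
#' @export
build_response_map <- function(vol, baseline_frames = 1:5, peak_frames = 9:14,
                               min_filter_radius = 2,
                               min_filter_shape = c("disc", "square"),
                               clip = c(-1, 4), epsilon = NULL,
                               filter_before_projection = TRUE) {
  min_filter_shape <- match.arg(min_filter_shape)
  if (max(baseline_frames) >= min(peak_frames)) {
    abort("The baseline window must precede the peak window.")
  }
  arr <- if (inherits(vol, "volume_series")) vol$data else vol
  fc <- fold_change(arr, baseline_frames = baseline_frames, epsilon = epsilon)
  peak <- peak_fold_change(fc, peak_frames = peak_frames)
  nz <- dim(peak)[1]
  if (filter_before_projection && min_filter_radius > 0) {
    for (z in seq_len(nz)) {
      peak[z, , ] <- minimum_filter(peak[z, , ], min_filter_radius,
                                    min_filter_shape)
    }
  }
  proj <- peak[1, , ]
  if (nz > 1) for (z in 2:nz) proj <- pmax(proj, peak[z, , ])
  if (!filter_before_projection && min_filter_radius > 0) {
    proj <- minimum_filter(proj, min_filter_radius, min_filter_shape)
  }
  map <- clip_values(proj, clip)
  structure(map,
            provenance = list(baseline_frames = baseline_frames,
                              peak_frames = peak_frames,
                              min_filter_radius = min_filter_radius,
                              min_filter_shape = min_filter_shape,
                              clip = clip,
                              filter_before_projection = filter_before_projection,
                              n_undefined = attr(fc, "n_undefined")),
            class = c("response_map", "matrix", "array"))
}

#' @export
print.response_map <- function(x, ...) {
  p <- attr(x, "provenance")
  cat(sprintf("<response_map> %d x %d px, range [%.3g, %.3g]\n",
              nrow(x), ncol(x), min(x), max(x)))
  if (!is.null(p)) {
    cat(sprintf("  baseline %s, peak %s, min-filter r=%s (%s), clip [%g, %g]\n",
                paste(range(p$baseline_frames), collapse = "-"),
                paste(range(p$peak_frames), collapse = "-"),
                p$min_filter_radius, p$min_filter_shape,
                p$clip[1], p$clip[2]))
  }
  invisible(x)
}

#' Sum-Z projection of a confocal stack
#'
#' Pixel-wise sum across z, as used to quantify baseline GCaMP6s
#' fluorescence from confocal volumes before comparing cohorts.
#'
#' @param zstack 3D array `[z, y, x]`.
#' @return Numeric matrix `[y, x]`.
#' @export
sum_z_projection <- function(zstack) {
  if (!is.array(zstack) || length(dim(zstack)) != 3L || dim(zstack)[1] < 1) {
    abort("`zstack` must be a nonempty 3D array [z, y, x].")
  }
  colSums(zstack, dims = 1)
}

#' Mean intensity within a rectangular ROI
#'
#' @param image Numeric matrix.
#' @param rect 0-based half-open rectangle `c(y0, x0, y1, x1)` (the ROI
#'   JSON convention).
#' @return Scalar mean intensity.
#' @export
rect_roi_mean <- function(image, rect) {
  if (length(rect) != 4L || rect[1] < 0 || rect[2] < 0 ||
      rect[3] > nrow(image) || rect[4] > ncol(image) ||
      rect[3] <= rect[1] || rect[4] <= rect[2]) {
    abort("`rect` must be a 0-based half-open c(y0, x0, y1, x1) inside the image.")
  }
  mean(image[(rect[1] + 1):rect[3], (rect[2] + 1):rect[4]])
}
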