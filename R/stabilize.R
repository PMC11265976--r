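#' Deinterleave an acquisition-ordered page stack into per-plane series
#'
#' Volumetric two-photon stacks arrive with the z index cycling fastest
#' (pages z1t1, z2t1, ..., z1t2, ...). Plane `p` of the result contains
#' pages `p, p + n_z, p + 2 n_z, ...`; interleaving the planes back
#' reproduces the stack exactly.
#'
#' @param stack 3D array `[page, y, x]` or list of 2D matrices.
#' @param n_z Number of z-planes; the page count must be divisible by it.
#' @return List of `n_z` arrays `[frame, y, x]`, one per plane.
#' @export
deinterleave <- function(stack, n_z) {
  if (is.list(stack)) {
    stack <- aperm(simplify2array(stack), c(3, 1, 2))
  }
  stopifnot(length(dim(stack)) == 3L)
  np <- dim(stack)[1]
  if (np %% n_z != 0) {
    abort(sprintf("Page count %d is not divisible by n_z = %d.", np, n_z))
  }
  lapply(seq_len(n_z), function(p) {
    stack[seq(p, np, by = n_z), , , drop = FALSE]
  })
}

#' @rdname deinterleave
#' @param planes List of per-plane `[frame, y, x]` arrays (as returned by
#'   `deinterleave()`).
#' @export
interleave <- function(planes) {
  n_z <- length(planes)
  nt <- dim(planes[[1]])[1]
  out <- array(0, c(nt * n_z, dim(planes[[1]])[2], dim(planes[[1]])[3]))
  for (p in seq_len(n_z)) out[seq(p, nt * n_z, by = n_z), , ] <- planes[[p]]
  out
}

# signed FFT frequency indices 0, 1, ..., -2, -1
fft_freqs <- function(n) {
  c(seq_len(ceiling(n / 2)) - 1L, seq(-floor(n / 2), -1L, length.out = floor(n / 2)))
}

#' Estimate the translation aligning one image to another
#'
#' Cross-correlation registration via FFT: the integer peak of the circular
#' cross-correlation gives the coarse shift; with `upsample > 1` the
#' correlation is re-evaluated on a `1/upsample`-pixel grid in a +-1 px
#' neighborhood of the coarse peak by direct (matrix) DFT, giving subpixel
#' precision of about half the fine grid step. Returns the correction
#' `c(dy, dx)` to apply to `moving` so it aligns with `reference`
#' (if `moving` is `reference` shifted by `(+3, -2)`, the estimate is
#' `(-3, +2)`).
#'
#' @param reference,moving Numeric matrices of identical dimensions;
#'   registration is undefined for constant images (error).
#' @param upsample Subpixel upsampling factor (1 = integer precision).
#' @param normalize `"none"` for plain cross-correlation (robust to noise,
#'   default) or `"phase"` for phase correlation (sharper peak).
#' @return Numeric `c(dy, dx)` correction shift in pixels.
#' @export
estimate_translation <- function(reference, moving, upsample = 1,
                                 normalize = c("none", "phase")) {
  normalize <- match.arg(normalize)
  if (!all(dim(reference) == dim(moving))) {
    abort("`reference` and `moving` must have identical dimensions.")
  }
  if (sd(reference) == 0 || sd(moving) == 0) {
    abort("Registration is undefined for constant images.")
  }
  ny <- nrow(reference); nx <- ncol(reference)
  cp <- fft(reference - mean(reference)) * Conj(fft(moving - mean(moving)))
  if (normalize == "phase") {
    mag <- Mod(cp)
    cp <- cp / pmax(mag, .Machine$double.eps * max(mag))
  }
  cc <- Re(fft(cp, inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  shift <- c(wrap(pk[1], ny), wrap(pk[2], nx))
  if (upsample > 1) {
    # direct inverse DFT of cp on a fine grid around the coarse peak
    ys <- shift[1] + seq(-1, 1, by = 1 / upsample)
    xs <- shift[2] + seq(-1, 1, by = 1 / upsample)
    ey <- exp(2i * pi * outer(ys, fft_freqs(ny)) / ny)
    ex <- exp(2i * pi * outer(fft_freqs(nx), xs) / nx)
    cc_up <- Re(ey %*% cp %*% ex)
    pk_up <- which(cc_up == max(cc_up), arr.ind = TRUE)[1, ]
    shift <- c(ys[pk_up[1]], xs[pk_up[2]])
  }
  unname(shift)
}

#' Translate an image by a (possibly subpixel) shift
#'
#' Samples the input at `(y - dy, x - dx)` with bilinear interpolation;
#' integer shifts are exact. Samples falling outside the image are filled
#' with `fill` (default the image median, which avoids injecting zeros that
#' would bias fold-change baselines).
#'
#' @param image Numeric matrix.
#' @param shift `c(dy, dx)` in pixels.
#' @param fill Fill value for out-of-view pixels.
#' @return Shifted matrix of the same dimensions.
#' @export
apply_shift <- function(image, shift, fill = median(image)) {
  ny <- nrow(image); nx <- ncol(image)
  ys <- seq_len(ny) - shift[1]
  xs <- seq_len(nx) - shift[2]
  y0 <- floor(ys); x0 <- floor(xs)
  wy <- ys - y0; wx <- xs - x0
  # pad so y0/y0+1 lookups are always in range; padded border = NA
  pad <- matrix(NA_real_, ny + 3, nx + 3)
  pad[2:(ny + 1), 2:(nx + 1)] <- image
  gy0 <- pmin(pmax(y0, 0), ny + 1) + 1
  gx0 <- pmin(pmax(x0, 0), nx + 1) + 1
  a <- pad[gy0, gx0, drop = FALSE]
  b <- pad[gy0, gx0 + 1L, drop = FALSE]
  cc <- pad[gy0 + 1L, gx0, drop = FALSE]
  dd <- pad[gy0 + 1L, gx0 + 1L, drop = FALSE]
  wym <- matrix(wy, ny, nx); wxm <- matrix(wx, ny, nx, byrow = TRUE)
  out <- a * (1 - wym) * (1 - wxm) + b * (1 - wym) * wxm +
    cc * wym * (1 - wxm) + dd * wym * wxm
  # any corner NA (outside) -> fill; exact-integer shifts only touch `a`
  inty <- wym == 0; intx <- wxm == 0
  out[inty & intx] <- a[inty & intx]
  out[inty & !intx] <- (a * (1 - wxm) + b * wxm)[inty & !intx]
  out[!inty & intx] <- (a * (1 - wym) + cc * wym)[!inty & intx]
  out[is.na(out)] <- fill
  out
}

#' Stabilize a volumetric movie against rigid in-plane drift
#'
#' For each z-plane independently, frames are registered by
#' [estimate_translation()] to that plane's reference (the mean of the
#' baseline frames, tying the registration target to the fold-change
#' baseline window) and re-sampled by [apply_shift()] with median edge
#' fill. The estimated per-frame corrections are returned as a tidy shift
#' table for quality control and motion-artifact flagging.
#'
#' @param vol A [volume_series()] with at least 2 frames.
#' @param baseline_frames 1-based frames defining each plane's reference
#'   (default 1:5).
#' @param upsample Subpixel upsampling factor (default 10).
#' @param normalize Correlation normalization, see [estimate_translation()].
#' @param refine_iterations Reference-refinement passes (default 2). The
#'   initial reference is the mean of baseline frames that may themselves
#'   carry motion and is therefore blurred, which biases subpixel peaks;
#'   each pass rebuilds the reference from the aligned baseline frames and
#'   re-estimates every shift from the original (once-interpolated) frames.
#' @return List with `volume` (stabilized [volume_series()], same shape and
#'   frame count) and `shifts` (tibble `frame, z, dy, dx` of the applied
#'   corrections).
#' @export
stabilize_series <- function(vol, baseline_frames = 1:5, upsample = 10,
                             normalize = c("none", "phase"),
                             refine_iterations = 2) {
  stopifnot(inherits(vol, "volume_series"))
  normalize <- match.arg(normalize)
  d <- dim(vol$data)
  if (d[1] < 2) abort("Need at least 2 frames to stabilize.")
  baseline_frames <- baseline_frames[baseline_frames <= d[1]]
  if (!length(baseline_frames)) abort("No baseline frames within the movie.")
  out <- vol$data
  shifts <- vector("list", d[2])
  for (z in seq_len(d[2])) {
    plane <- vol$data[, z, , ]
    ref <- colMeans(plane[baseline_frames, , , drop = FALSE], dims = 1)
    sh <- matrix(0, d[1], 2)
    for (pass in seq_len(1 + refine_iterations)) {
      for (t in seq_len(d[1])) {
        sh[t, ] <- estimate_translation(ref, plane[t, , ],
                                        upsample = upsample,
                                        normalize = normalize)
      }
      if (pass > refine_iterations) break
      aligned_base <- lapply(baseline_frames, function(b) {
        apply_shift(plane[b, , ], sh[b, ])
      })
      ref <- Reduce(`+`, aligned_base) / length(aligned_base)
    }
    for (t in seq_len(d[1])) {
      if (any(sh[t, ] != 0)) out[t, z, , ] <- apply_shift(plane[t, , ], sh[t, ])
    }
    shifts[[z]] <- tibble(frame = seq_len(d[1]), z = z,
                          dy = sh[, 1], dx = sh[, 2])
  }
  stab <- vol
  stab$data <- pmax(out, 0)
  list(volume = stab, shifts = bind_rows(shifts))
}

#' Flag a trial whose residual motion exceeds a threshold
#'
#' The study excluded a small number of trials with visible motion
#' artifacts by eye; this automates the rule: a trial is flagged when any
#' frame-to-frame displacement of the (plane-averaged) estimated shift
#' exceeds `threshold_px` (strictly; a jump exactly at the threshold does
#' not flag). The threshold is artifact-defined (default 5 px) and is
#' stored with the result.
#'
#' @param shifts Shift tibble from [stabilize_series()] (columns `frame`,
#'   `z`, `dy`, `dx`).
#' @param threshold_px Flagging threshold in pixels (> 0, default 5).
#' @return Logical scalar with attribute `max_jump_px`.
#' @export
flag_motion_artifact <- function(shifts, threshold_px = 5) {
  check_scalar_number(threshold_px, "threshold_px", lower = 0,
                      strict_lower = TRUE)
  per_frame <- shifts %>%
    group_by(.data$frame) %>%
    summarise(dy = mean(.data$dy), dx = mean(.data$dx), .groups = "drop") %>%
    arrange(.data$frame)
  if (nrow(per_frame) < 2) return(structure(FALSE, max_jump_px = 0))
  jump <- sqrt(diff(per_frame$dy)^2 + diff(per_frame$dx)^2)
  structure(any(jump > threshold_px), max_jump_px = max(jump),
            threshold_px = threshold_px)
}
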