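#' Stimulus timing for one imaging trial
#'
#' Describes when odor reaches the antenna relative to the acquisition
#' clock: a valve trigger is sent at `trigger_frame` (1-based volume index),
#' stimulus air is redirected through the odor vial with a `delay_s` second
#' delay, and odor delivery lasts `duration_s` seconds.
#'
#' @param trigger_frame 1-based volume index at which the valve trigger is
#'   sent.
#' @param delay_s Seconds from trigger to odor arrival at the antenna
#'   (default 3).
#' @param duration_s Seconds of odor delivery (default 5).
#' @return An object of class `stimulus_timing`.
#' @export
stimulus_timing <- function(trigger_frame = 3, delay_s = 3, duration_s = 5) {
  check_scalar_number(trigger_frame, "trigger_frame", lower = 1)
  check_scalar_number(delay_s, "delay_s", lower = 0)
  check_scalar_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  structure(
    list(trigger_frame = as.integer(trigger_frame), delay_s = delay_s,
         duration_s = duration_s),
    class = "stimulus_timing"
  )
}

#' @export
print.stimulus_timing <- function(x, ...) {
  cat(sprintf("<stimulus_timing> trigger frame %d, delay %gs, duration %gs\n",
              x$trigger_frame, x$delay_s, x$duration_s))
  invisible(x)
}

#' One trial's volumetric fluorescence movie
#'
#' Wraps a 4D intensity array indexed `[frame, z, y, x]` together with the
#' acquisition period, stimulus timing, and trial metadata (animal id, age
#' class, odorant, concentration, repeat index). Frame and plane indices are
#' 1-based throughout the package, matching the frame labels used for the
#' baseline (frames 1-5), peak (frames 9-14) and AUC (frames 6-40) windows.
#'
#' @param data Numeric 4D array `[n_frames, n_z, n_y, n_x]`; all values must
#'   be finite and non-negative (arbitrary fluorescence units).
#' @param frame_period_s Seconds per volume scan (default 0.83).
#' @param stimulus A [stimulus_timing()] object.
#' @param metadata Named list of trial fields. Recognised fields:
#'   `ant_id`, `age_class` (one of `"young"`, `"old"`), `odorant`,
#'   `concentration_pct`, `repeat_index`. Extra fields are kept as-is.
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(data, frame_period_s = 0.83,
                          stimulus = stimulus_timing(),
                          metadata = list()) {
  if (!is.array(data) || length(dim(data)) != 4L) {
    abort("`data` must be a 4D array [frame, z, y, x].")
  }
  if (any(!is.finite(data))) abort("`data` must be finite everywhere.")
  if (any(data < 0)) abort("`data` must be non-negative (fluorescence).")
  check_scalar_number(frame_period_s, "frame_period_s", lower = 0,
                      strict_lower = TRUE)
  if (!inherits(stimulus, "stimulus_timing")) {
    abort("`stimulus` must be a stimulus_timing object.")
  }
  ac <- metadata$age_class
  if (!is.null(ac) && !is.na(ac) && !ac %in% c("young", "old")) {
    abort("`metadata$age_class` must be \"young\" or \"old\".")
  }
  structure(
    list(data = data, frame_period_s = frame_period_s, stimulus = stimulus,
         metadata = metadata),
    class = "volume_series"
  )
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<volume_series> %d frames x %d planes x %d x %d px, %.3g s/frame\n",
    d[1], d[2], d[3], d[4], x$frame_period_s))
  md <- x$metadata
  if (length(md)) {
    cat("  metadata:", paste(names(md), unlist(lapply(md, format)),
                             sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname volume_series
#' @param x A `volume_series`.
#' @export
n_frames <- function(x) dim(x$data)[1]

#' @rdname volume_series
#' @export
n_planes <- function(x) dim(x$data)[2]

#' @export
dim.volume_series <- function(x) dim(x$data)

# ---------------------------------------------------------------------------
# TIFF movie I/O.
#
# Canonical interchange is 16-bit multi-page TIFF of integer intensities
# (0..65535), the format volumetric two-photon acquisitions arrive in, with
# a YAML sidecar (<path>.yaml) holding n_z, page layout, frame period,
# stimulus timing and trial metadata. Page layouts:
#   "interleaved" - z cycles fastest (z1t1, z2t1, ..., acquisition order);
#   "plane_major" - all frames of plane 1, then plane 2, ...
# ---------------------------------------------------------------------------

TIFF_MAX <- 65535

sidecar_path <- function(path) paste0(path, ".yaml")

#' Write a volumetric movie as multi-page TIFF plus YAML sidecar
#'
#' Pages are written in acquisition order by default (`"interleaved"`: the
#' z index cycles fastest within each volume scan). Intensities must lie in
#' 0..65535; integer-valued movies round-trip exactly through
#' [read_volume_tiff()].
#'
#' @param vol A [volume_series()].
#' @param path Output TIFF path; the sidecar goes to `<path>.yaml`.
#' @param layout Page order, `"interleaved"` (default) or `"plane_major"`.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(vol, path,
                              layout = c("interleaved", "plane_major")) {
  layout <- match.arg(layout)
  stopifnot(inherits(vol, "volume_series"))
  d <- dim(vol$data)
  if (max(vol$data) > TIFF_MAX) {
    abort(sprintf("Intensities exceed %d; 16-bit TIFF cannot store them.",
                  TIFF_MAX))
  }
  pages <- vector("list", d[1] * d[2])
  i <- 1L
  if (layout == "interleaved") {
    for (t in seq_len(d[1])) for (z in seq_len(d[2])) {
      pages[[i]] <- vol$data[t, z, , ] / TIFF_MAX
      i <- i + 1L
    }
  } else {
    for (z in seq_len(d[2])) for (t in seq_len(d[1])) {
      pages[[i]] <- vol$data[t, z, , ] / TIFF_MAX
      i <- i + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  meta <- list(
    n_z = d[2], n_frames = d[1], layout = layout, scale = TIFF_MAX,
    quantized = all(vol$data == round(vol$data)),
    frame_period_s = vol$frame_period_s,
    stimulus = unclass(vol$stimulus),
    metadata = vol$metadata
  )
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read a volumetric movie from multi-page TIFF
#'
#' Reconstructs a [volume_series()] from a multi-page TIFF and its YAML
#' sidecar. `n_z` and `layout` default to the sidecar values; the page count
#' must be divisible by `n_z`. A voxel written at `(t, z, y, x)` is read
#' back at `(t, z, y, x)` - the reader never reorders axes.
#'
#' @param path TIFF path written by [write_volume_tiff()] (or any multi-page
#'   TIFF with a compatible sidecar).
#' @param n_z Number of z-planes per volume; overrides the sidecar.
#' @param layout Page order; overrides the sidecar.
#' @return A [volume_series()].
#' @export
read_volume_tiff <- function(path, n_z = NULL, layout = NULL) {
  sp <- sidecar_path(path)
  meta <- if (file.exists(sp)) yaml::read_yaml(sp) else NULL
  if (is.null(meta) && (is.null(n_z))) {
    abort(sprintf("Missing sidecar %s and no `n_z` given.", sp))
  }
  n_z <- n_z %||% meta$n_z
  layout <- layout %||% (meta$layout %||% "interleaved")
  layout <- match.arg(layout, c("interleaved", "plane_major"))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) %% n_z != 0) {
    abort(sprintf(
      "Page count %d is not a multiple of n_z = %d (expected %d frames x %d planes).",
      length(pages), n_z, length(pages) %/% n_z + 1L, n_z))
  }
  nt <- length(pages) %/% n_z
  scale <- meta$scale %||% TIFF_MAX
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, dim = c(nt, n_z, ny, nx))
  i <- 1L
  if (layout == "interleaved") {
    for (t in seq_len(nt)) for (z in seq_len(n_z)) {
      arr[t, z, , ] <- pages[[i]] * scale
      i <- i + 1L
    }
  } else {
    for (z in seq_len(n_z)) for (t in seq_len(nt)) {
      arr[t, z, , ] <- pages[[i]] * scale
      i <- i + 1L
    }
  }
  if (isTRUE(meta$quantized %||% TRUE)) arr <- round(arr)
  stim <- if (!is.null(meta$stimulus)) {
    do.call(stimulus_timing, meta$stimulus)
  } else {
    stimulus_timing()
  }
  volume_series(arr,
                frame_period_s = meta$frame_period_s %||% 0.83,
                stimulus = stim,
                metadata = meta$metadata %||% list())
}

#' Write a 2D map (e.g. a response map) as scaled 32-bit TIFF
#'
#' Response-map values live in a small signed range (clipped to `[-1, 4]`),
#' which plain TIFF integer samples cannot hold; the map is affinely scaled
#' into `[0, 1]` for storage and the offset/scale recorded in the sidecar,
#' giving round-trip precision of about `range / 2^32`.
#'
#' @param map Numeric matrix (a [build_response_map()] result works).
#' @param path Output path; sidecar at `<path>.yaml`.
#' @param value_range Storage range; values outside error. Default the map's
#'   clip bounds if present, else its own range.
#' @return `path`, invisibly.
#' @export
write_map_tiff <- function(map, path, value_range = NULL) {
  prov <- attr(map, "provenance")
  value_range <- value_range %||% prov$clip %||% range(map)
  if (value_range[2] <= value_range[1]) value_range[2] <- value_range[1] + 1
  if (any(map < value_range[1]) || any(map > value_range[2])) {
    abort("Map values fall outside `value_range`.")
  }
  scaled <- (unclass(map) - value_range[1]) / diff(value_range)
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  yaml::write_yaml(list(offset = value_range[1], scale = diff(value_range),
                        provenance = prov),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname write_map_tiff
#' @export
read_map_tiff <- function(path) {
  meta <- yaml::read_yaml(sidecar_path(path))
  m <- tiff::readTIFF(path) * meta$scale + meta$offset
  attr(m, "provenance") <- meta$provenance
  class(m) <- c("response_map", class(m))
  m
}

# ---------------------------------------------------------------------------
# ROI sets
# ---------------------------------------------------------------------------

#' Regions of interest over a response map or imaging plane
#'
#' An ROI is a labelled 2D pixel mask, either in max-Z projection space
#' (`kind = "projection_2d"`, e.g. the whole-antennal-lobe boundary ROI or a
#' glomerulus outline on a response map) or in a single imaging plane
#' (`kind = "plane_centered"`, carrying the 1-based `z_center` of the
#' glomerulus for 3-plane trace extraction).
#'
#' @param label Unique ROI label.
#' @param mask Logical matrix (`n_y x n_x`); must contain at least one TRUE
#'   pixel.
#' @param kind `"projection_2d"` or `"plane_centered"`.
#' @param z_center 1-based plane index of the glomerulus center (required
#'   when `kind = "plane_centered"`).
#' @return An object of class `roi`.
#' @export
roi <- function(label, mask, kind = c("projection_2d", "plane_centered"),
                z_center = NA_integer_) {
  kind <- match.arg(kind)
  if (!is.matrix(mask) || !is.logical(mask)) {
    abort("`mask` must be a logical matrix.")
  }
  if (!any(mask)) abort(sprintf("ROI '%s' has an empty mask.", label))
  if (kind == "plane_centered" && is.na(z_center)) {
    abort("plane_centered ROIs need a `z_center`.")
  }
  structure(list(label = as.character(label), kind = kind, mask = mask,
                 z_center = as.integer(z_center)),
            class = "roi")
}

#' @rdname roi
#' @param rect Integer vector `c(y0, x0, y1, x1)`, 0-based half-open (so
#'   `c(0, 0, 2, 2)` is a 4-pixel square), matching the on-disk JSON
#'   convention.
#' @param shape_yx Mask dimensions `c(n_y, n_x)`.
#' @export
roi_rect <- function(label, rect, shape_yx,
                     kind = c("projection_2d", "plane_centered"),
                     z_center = NA_integer_) {
  if (length(rect) != 4L) abort("`rect` must be c(y0, x0, y1, x1).")
  if (rect[3] <= rect[1] || rect[4] <= rect[2]) {
    abort("Half-open rectangle must satisfy y1 > y0 and x1 > x0.")
  }
  if (rect[1] < 0 || rect[2] < 0 || rect[3] > shape_yx[1] ||
      rect[4] > shape_yx[2]) {
    abort("Rectangle extends outside the image.")
  }
  mask <- matrix(FALSE, shape_yx[1], shape_yx[2])
  mask[(rect[1] + 1):rect[3], (rect[2] + 1):rect[4]] <- TRUE
  roi(label, mask, kind = match.arg(kind), z_center = z_center)
}

#' @rdname roi
#' @param rois List of `roi` objects with unique labels.
#' @export
roi_set <- function(rois) {
  if (!length(rois)) return(structure(list(), class = "roi_set"))
  labels <- vapply(rois, function(r) r$label, character(1))
  if (anyDuplicated(labels)) {
    abort(sprintf("Duplicate ROI labels: %s",
                  paste(unique(labels[duplicated(labels)]), collapse = ", ")))
  }
  structure(setNames(rois, labels), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROIs\n", length(x)))
  for (r in x) {
    cat(sprintf("  %s [%s] %d px%s\n", r$label, r$kind, sum(r$mask),
                if (!is.na(r$z_center)) sprintf(", z_center %d", r$z_center)
                else ""))
  }
  invisible(x)
}

#' Read / write ROI sets as JSON
#'
#' The JSON schema stores `shape_yx` plus one record per ROI with `label`,
#' `kind`, optional 0-based `z_center`, and either a 0-based half-open
#' `rect` `[y0, x0, y1, x1]` or an explicit 0-based `pixels` list of
#' `[y, x]` pairs. Rectangle shorthand is expanded to a mask on read;
#' write/read round-trips reproduce the same masks.
#'
#' @param path JSON file path.
#' @return [read_roiset()]: a [roi_set()]. [write_roiset()]: `path`,
#'   invisibly.
#' @export
read_roiset <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  shape <- as.integer(unlist(js$shape_yx))
  rois <- lapply(js$rois, function(rec) {
    z <- if (!is.null(rec$z_center)) as.integer(rec$z_center) + 1L
         else NA_integer_
    if (!is.null(rec$rect)) {
      roi_rect(rec$label, as.integer(unlist(rec$rect)), shape,
               kind = rec$kind, z_center = z)
    } else {
      px <- do.call(rbind, lapply(rec$pixels, as.integer)) + 1L
      if (is.null(px) || nrow(px) == 0) {
        abort(sprintf("ROI '%s' has an empty mask.", rec$label))
      }
      mask <- matrix(FALSE, shape[1], shape[2])
      mask[px] <- TRUE
      roi(rec$label, mask, kind = rec$kind, z_center = z)
    }
  })
  roi_set(rois)
}

#' @rdname read_roiset
#' @param roiset A [roi_set()].
#' @export
write_roiset <- function(roiset, path) {
  if (!length(roiset)) abort("Cannot write an empty roi_set.")
  shape <- dim(roiset[[1]]$mask)
  recs <- lapply(roiset, function(r) {
    px <- which(r$mask, arr.ind = TRUE) - 1L
    rec <- list(label = r$label, kind = r$kind,
                pixels = lapply(seq_len(nrow(px)),
                                function(i) as.integer(px[i, ])))
    if (!is.na(r$z_center)) rec$z_center <- r$z_center - 1L
    rec
  })
  jsonlite::write_json(list(shape_yx = as.integer(shape),
                            rois = unname(recs)),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' Load a volumetric imaging series from an NWB file
#'
#' Maps an NWB acquisition stream (as deposited in neurophysiology archives)
#' onto a [volume_series()]. This is an optional convenience: it needs the
#' `hdf5r` package, and nothing else in the package depends on it. Because
#' NWB layouts vary between deposits, the dataset paths are supplied through
#' `mapping` rather than hard-coded.
#'
#' @param path NWB (HDF5) file path.
#' @param mapping Named list: `data` (path to the 4D or page-series
#'   dataset), optional `rate` (path to the sampling-rate attribute or
#'   dataset), optional `n_z` (planes per volume when the data are stored as
#'   a page series).
#' @return A [volume_series()]; if no stimulus table can be located the
#'   stimulus is left at defaults and a warning is issued.
#' @export
load_nwb_series <- function(path,
                            mapping = list(data = "/acquisition/TwoPhotonSeries/data",
                                           rate = "/acquisition/TwoPhotonSeries/starting_time")) {
  if (!requireNamespace("hdf5r", quietly = TRUE)) {
    abort(paste("load_nwb_series() needs the 'hdf5r' package for HDF5/NWB",
                "access; install it or convert the recording to TIFF and use",
                "read_volume_tiff()."))
  }
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  h5 <- hdf5r::H5File$new(path, mode = "r")
  on.exit(h5$close_all(), add = TRUE)
  if (!h5$exists(mapping$data)) {
    streams <- tryCatch(hdf5r::list.datasets(h5), error = function(e) character())
    abort(sprintf("No imaging series at '%s'. Available datasets: %s",
                  mapping$data, paste(streams, collapse = ", ")))
  }
  raw <- h5[[mapping$data]]$read()
  if (length(dim(raw)) == 3L && !is.null(mapping$n_z)) {
    nz <- mapping$n_z
    nt <- dim(raw)[1] %/% nz
    arr <- array(0, c(nt, nz, dim(raw)[2], dim(raw)[3]))
    for (t in seq_len(nt)) for (z in seq_len(nz)) {
      arr[t, z, , ] <- raw[(t - 1L) * nz + z, , ]
    }
    raw <- arr
  }
  if (length(dim(raw)) != 4L) {
    abort("NWB dataset is not 4D and no `n_z` mapping was given.")
  }
  rate <- NULL
  if (!is.null(mapping$rate) && h5$exists(mapping$rate)) {
    obj <- h5[[mapping$rate]]
    rate <- tryCatch(hdf5r::h5attr(obj, "rate"), error = function(e) NULL)
  }
  period <- if (!is.null(rate) && is.finite(rate) && rate > 0) 1 / rate else 0.83
  stim <- stimulus_timing()
  if (is.null(mapping$stimulus)) {
    warn("No stimulus table mapping given; stimulus timing set to defaults.")
  }
  volume_series(raw, frame_period_s = period, stimulus = stim)
}
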