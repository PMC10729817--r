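#' A single rising-slope z-stack
#'
#' @param planes list of intensity matrices (one per focal plane,
#'   bottom-to-top) or a 3D array \code{[rows, cols, planes]}.
#' @param z_positions focal-plane positions (micrometres), strictly
#'   increasing, one per plane.
#' @param t_start acquisition time of the first plane (seconds).
#' @param index 0-based stack index within its series.
#' @return Object of class \code{"multi_plane_stack"}: a 3D array with
#'   attributes \code{z_positions}, \code{t_start} and \code{index}.
#' @export
multi_plane_stack <- function(planes, z_positions, t_start = 0, index = 0L) {
  if (is.list(planes)) {
    if (any(vapply(planes, is.null, logical(1))))
      stop("ragged stack: missing plane(s) in stack ", index, call. = FALSE)
    dims <- vapply(planes, dim, integer(2))
    if (nrow(unique(t(dims))) != 1)
      stop("ragged stack: plane shapes differ in stack ", index,
           call. = FALSE)
    arr <- array(unlist(planes), dim = c(dim(planes[[1]]), length(planes)))
  } else if (is.array(planes) && length(dim(planes)) == 3) {
    arr <- planes
  } else stop("'planes' must be a list of matrices or a 3D array",
              call. = FALSE)
  if (length(z_positions) != dim(arr)[3])
    stop("'z_positions' must have one entry per plane", call. = FALSE)
  if (any(diff(z_positions) <= 0))
    stop("'z_positions' must be strictly increasing", call. = FALSE)
  structure(arr, z_positions = as.numeric(z_positions),
            t_start = as.numeric(t_start), index = as.integer(index),
            class = c("multi_plane_stack", "array"))
}

#' An ordered time series of rising-slope z-stacks
#'
#' @param stacks list of [multi_plane_stack()] objects, equally spaced in
#'   time by one scan period.
#' @param config the [acquisition_config()] the series was acquired (or
#'   synthesized) under.
#' @param provenance named list (source, software version, seed, ...).
#' @param ground_truth optional per-frame pose log (synthetic series).
#' @param falling optional list of falling-slope frames.
#' @param n_frames_total total camera frames the series derives from
#'   (rising + falling + dropped).
#' @return Object of class \code{"stack_series"}.
#' @export
stack_series <- function(stacks, config, provenance = list(),
                         ground_truth = NULL, falling = NULL,
                         n_frames_total = NA_integer_) {
  structure(list(stacks = stacks, config = config, provenance = provenance,
                 ground_truth = ground_truth, falling = falling,
                 n_frames_total = n_frames_total),
            class = "stack_series")
}

#' @export
print.stack_series <- function(x, ...) {
  cat("Stack series:", length(x$stacks), "rising-slope stacks of",
      if (length(x$stacks)) dim(x$stacks[[1]])[3] else 0, "planes;",
      "scan", x$config$scan_hz, "Hz, fps", x$config$fps, "\n")
  invisible(x)
}

sidecar_required <- c("fps", "scan_hz", "scan_amplitude", "pixel_size")

#' Write a stack series to disk
#'
#' One multi-page TIFF per rising-slope stack (page = focal plane,
#' bottom-to-top) plus a JSON sidecar holding the acquisition metadata,
#' per-stack timing table, intensity calibration, provenance and (for
#' synthetic data) the ground-truth log. Pixels are stored as 16-bit
#' grey levels; the affine intensity calibration recorded in the sidecar
#' restores physical units on read, and the write-read-write cycle is
#' byte-identical.
#'
#' @param series a [stack_series()].
#' @param path output directory (created if needed).
#' @return \code{path}, invisibly.
#' @export
write_series <- function(series, path) {
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stop("cannot create output directory: ", path, call. = FALSE)
  rng <- range(vapply(series$stacks, range, numeric(2)))
  lo <- rng[1]; span <- max(rng[2] - rng[1], 1e-12)
  for (s in series$stacks) {
    i <- attr(s, "index")
    fn <- file.path(path, sprintf("stack_%04d.tif", i))
    pages <- lapply(seq_len(dim(s)[3]), function(p)
      round((s[, , p] - lo) / span * 65535) / 65535)
    ok <- try(tiff::writeTIFF(pages, fn, bits.per.sample = 16), silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("failed writing ", fn, ": ", attr(ok, "condition")$message,
           call. = FALSE)
  }
  side <- list(
    schema_version = 1L,
    acquisition = unclass(series$config),
    intensity = list(offset = lo, span = span, bits = 16L),
    stacks = data.frame(
      index = vapply(series$stacks, attr, integer(1), "index"),
      t_start = vapply(series$stacks, attr, numeric(1), "t_start"),
      n_planes = vapply(series$stacks, function(s) dim(s)[3], integer(1))),
    z_positions = if (length(series$stacks))
      attr(series$stacks[[1]], "z_positions") else numeric(0),
    provenance = series$provenance,
    n_frames_total = series$n_frames_total)
  if (!is.null(series$ground_truth)) {
    side$ground_truth <- series$ground_truth
    side$direction <- attr(series$ground_truth, "direction")
  }
  jsonlite::write_json(side, file.path(path, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a stack series from disk
#'
#' @param path directory produced by [write_series()].
#' @return A [stack_series()].
#' @export
read_series <- function(path) {
  sj <- file.path(path, "sidecar.json")
  if (!file.exists(sj))
    stop("missing sidecar.json in ", path, call. = FALSE)
  side <- jsonlite::read_json(sj, simplifyVector = TRUE)
  missing_fields <- setdiff(sidecar_required, names(side$acquisition))
  if (length(missing_fields))
    stop("sidecar missing required acquisition field(s): ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  acq <- side$acquisition
  cfg <- acquisition_config(fps = acq$fps, scan_hz = acq$scan_hz,
                            scan_amplitude = acq$scan_amplitude,
                            pixel_size = acq$pixel_size,
                            frame_shape = acq$frame_shape %||% c(1L, 1L),
                            duration = acq$duration %||% NA_real_,
                            noise_sd = acq$noise_sd %||% 0,
                            seed = acq$seed %||% NA_integer_)
  lo <- side$intensity$offset; span <- side$intensity$span
  st <- side$stacks
  stacks <- lapply(seq_len(nrow(st)), function(r) {
    fn <- file.path(path, sprintf("stack_%04d.tif", st$index[r]))
    if (!file.exists(fn)) stop("missing stack file: ", fn, call. = FALSE)
    pages <- tiff::readTIFF(fn, all = TRUE)
    if (length(pages) != st$n_planes[r])
      stop("ragged stacks: stack ", st$index[r], " has ", length(pages),
           " pages, sidecar says ", st$n_planes[r], call. = FALSE)
    multi_plane_stack(lapply(pages, function(p) p * span + lo),
                      z_positions = side$z_positions,
                      t_start = st$t_start[r], index = st$index[r])
  })
  gt <- NULL
  if (!is.null(side$ground_truth)) {
    gt <- as.data.frame(side$ground_truth)
    attr(gt, "direction") <- side$direction
  }
  stack_series(stacks, cfg, provenance = side$provenance,
               ground_truth = gt,
               n_frames_total = side$n_frames_total %||% NA_integer_)
}

#' Segment a raw frame stream into rising-slope z-stacks
#'
#' Partitions frames by the phase of the triangular scan. Falling-slope
#' frames are dropped by default or returned (reversed into ascending-z
#' order) when \code{keep_falling} is TRUE; a trailing partial stack is
#' dropped with a warning.
#'
#' @param frames list of intensity matrices, one per camera tick.
#' @param cfg an [acquisition_config()].
#' @param t0 acquisition time of the first frame (seconds; must align with
#'   the scan phase grid).
#' @param keep_falling keep falling-slope stacks.
#' @return A [stack_series()]; counts of rising/falling/dropped frames are
#'   in the \code{provenance} element.
#' @export
segment_rising_slopes <- function(frames, cfg, t0 = 0, keep_falling = FALSE) {
  P <- cfg$planes_per_rising_slope
  n <- length(frames)
  tj <- t0 + (seq_len(n) - 1) / cfg$fps
  scan <- triangular_scan_z(tj, cfg)
  cycle <- floor(tj * cfg$scan_hz + 1e-9)
  rising <- scan$slope == "rising"
  z_planes <- (seq_len(P) - 1) * cfg$plane_spacing
  stacks <- list(); falling <- list()
  dropped <- 0L
  for (cyc in unique(cycle)) {
    sel <- which(cycle == cyc & rising)
    if (length(sel) == P) {
      stacks[[length(stacks) + 1L]] <-
        multi_plane_stack(frames[sel][order(scan$plane[sel])],
                          z_positions = z_planes,
                          t_start = tj[sel[1]],
                          index = length(stacks))
    } else if (length(sel) > 0) {
      dropped <- dropped + length(sel)
    }
    fsel <- which(cycle == cyc & !rising)
    if (keep_falling && length(fsel) == P) {
      falling[[length(falling) + 1L]] <- frames[rev(fsel)]
    }
  }
  if (dropped > 0)
    warning(sprintf("dropped %d frame(s) from partial rising slope(s)",
                    dropped))
  stack_series(stacks, cfg,
               provenance = list(source = "segmented",
                                 n_rising = sum(rising) - dropped,
                                 n_falling = sum(!rising),
                                 n_dropped = dropped),
               falling = if (keep_falling) falling else NULL,
               n_frames_total = n)
}
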