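#' Maximum intensity projection of a z-stack
#'
#' Pixelwise maximum over all focal planes of one rising-slope stack. The
#' projection accumulates, in a single image, the bright features that each
#' appear in only a few focal planes (the one-sided bright border of an
#' inclined head among them).
#'
#' @param stack a [multi_plane_stack()] or a 3D array \code{[rows, cols,
#'   planes]}.
#' @return Intensity matrix of the plane shape.
#' @export
mip <- function(stack) {
  if (!(is.array(stack) && length(dim(stack)) == 3))
    stop("'stack' must be a 3D array of planes", call. = FALSE)
  if (any(dim(stack) == 0) || dim(stack)[3] < 1)
    stop("empty stack", call. = FALSE)
  intensity_image(apply(stack, c(1, 2), max))
}

#' Track the head in a projected image
#'
#' Moment-based tracker: the absolute deviation from the background level is
#' thresholded (Otsu), the largest connected component is taken as the head,
#' and its deviation-weighted centroid and principal second-moment axis give
#' the centre \code{a} and orientation \code{phi} (radians, in \eqn{[0,
#' \pi)}, image coordinates with x = column, y = row). The oriented tip
#' direction is resolved separately from motion, see [track_series()].
#'
#' @param image intensity matrix (typically a [mip()]).
#' @param prev previous pose (used only as fallback context by callers).
#' @param min_area minimum component area in pixels before tracking is
#'   declared lost.
#' @return A head pose: list with elements \code{a} (centre, c(x, y) in
#'   pixels), \code{phi} (axis angle, radians in \eqn{[0, \pi)}),
#'   \code{tip_sign} (NA until disambiguated) and \code{area}.
#' @export
track_head <- function(image, prev = NULL, min_area = 20) {
  dev <- abs(image - stats::median(image))
  mx <- max(dev)
  if (mx <= 0) stop("tracking lost: blank image", call. = FALSE)
  devn <- dev / mx
  thr <- EBImage::otsu(devn, range = c(0, 1))
  bw <- devn > thr
  lab <- EBImage::bwlabel(bw)
  if (max(lab) == 0) stop("tracking lost: no component above threshold",
                          call. = FALSE)
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  if (sizes[big] < min_area)
    stop("tracking lost: largest component below minimum area",
         call. = FALSE)
  sel <- lab == big
  w <- dev * sel
  sw <- sum(w)
  cx <- sum(col(image) * w) / sw
  cy <- sum(row(image) * w) / sw
  mxx <- sum((col(image) - cx)^2 * w) / sw
  myy <- sum((row(image) - cy)^2 * w) / sw
  mxy <- sum((col(image) - cx) * (row(image) - cy) * w) / sw
  phi <- 0.5 * atan2(2 * mxy, mxx - myy)
  if (phi < 0) phi <- phi + pi
  list(a = c(cx, cy), phi = phi, tip_sign = NA_real_, area = sizes[big])
}

#' Track a stack series and orient the head axis
#'
#' Runs [mip()] and [track_head()] on every stack and disambiguates the tip
#' direction from the motion of the centre: the tip leads, so the oriented
#' axis is chosen to agree with the recent displacement direction; when the
#' displacement is below \code{min_step} pixels the previous orientation is
#' kept.
#'
#' @param series a [stack_series()].
#' @param min_step displacement (pixels) below which the previous tip sign
#'   is reused.
#' @return Data frame with one row per stack: \code{t}, \code{x}, \code{y}
#'   (pixels), \code{phi} (unoriented axis), \code{phi_tip} (oriented tip
#'   direction, radians) and \code{tip_sign}.
#' @export
track_series <- function(series, min_step = 0.1) {
  n <- length(series$stacks)
  if (n == 0) stop("empty series", call. = FALSE)
  poses <- vector("list", n)
  for (i in seq_len(n)) {
    m <- mip(series$stacks[[i]])
    poses[[i]] <- tryCatch(track_head(m),
      error = function(e) stop("stack ", i - 1, ": ", conditionMessage(e),
                               call. = FALSE))
  }
  xs <- vapply(poses, function(p) p$a[1], numeric(1))
  ys <- vapply(poses, function(p) p$a[2], numeric(1))
  ts <- vapply(series$stacks, attr, numeric(1), "t_start")
  phis <- vapply(poses, function(p) p$phi, numeric(1))
  # robust axis: when the head is edge-on its deviation image is nearly
  # isotropic and the per-stack axis occasionally locks onto the
  # perpendicular; such outliers (> 30 degrees from the pooled axis,
  # which persists within a record) are replaced by the pooled estimate
  mean2 <- atan2(mean(sin(2 * phis)), mean(cos(2 * phis))) / 2
  if (mean2 < 0) mean2 <- mean2 + pi
  ang_dev <- abs(((phis - mean2 + pi / 2) %% pi) - pi / 2)
  keep_phi <- ang_dev <= pi / 6
  if (any(keep_phi)) {
    mean2 <- atan2(mean(sin(2 * phis[keep_phi])),
                   mean(cos(2 * phis[keep_phi]))) / 2
    if (mean2 < 0) mean2 <- mean2 + pi
    ang_dev <- abs(((phis - mean2 + pi / 2) %% pi) - pi / 2)
    phis[ang_dev > pi / 6] <- mean2
  }
  # the tip leads: project each stack's trailing displacement on its axis
  # and pool the evidence over the record (the heading persists within a
  # record, and per-stack decisions are fragile when the head is edge-on).
  # Axes are aligned to the first stack's before pooling, since phi lives
  # in [0, pi) and flips its vector across that boundary.
  ref <- c(cos(phis[1]), sin(phis[1]))
  align <- vapply(phis, function(p) {
    if (cos(p) * ref[1] + sin(p) * ref[2] >= 0) 1 else -1
  }, numeric(1))
  dp <- rep(0, n)
  for (i in seq_len(n)) {
    j <- max(1, i - 4)
    dx <- xs[i] - xs[j]; dy <- ys[i] - ys[j]
    if (sqrt(dx^2 + dy^2) >= min_step)
      dp[i] <- align[i] * (cos(phis[i]) * dx + sin(phis[i]) * dy)
  }
  if (all(dp == 0)) stop("tip direction undecidable: cell never moved",
                         call. = FALSE)
  tip <- (if (sum(dp) >= 0) 1 else -1) * align
  phi_tip <- ifelse(tip > 0, phis, (phis + pi) %% (2 * pi))
  data.frame(t = ts, x = xs, y = ys, phi = phis, phi_tip = phi_tip,
             tip_sign = tip)
}

#' Probe-segment geometry across the head
#'
#' Constructs the oriented line C through the head centre at the tracked
#' axis angle, the perpendicular line C' crossing it at \code{L/3}
#' micrometres ahead of the centre (toward the tip), and the endpoints b,
#' b' at \code{w} micrometres either side. The handedness is fixed by the
#' imaging geometry: b' lies along the tip direction rotated by +90 degrees
#' in image (x = column, y = row) coordinates, so that the weighted-average
#' position moving from b to b' corresponds to CCW head rotation under the
#' head-to-tail viewing convention.
#'
#' @param pose list with \code{a} (centre, pixels) and \code{phi_tip}
#'   (oriented tip direction, radians); e.g. one row of [track_series()].
#' @param L head long-axis length (micrometres).
#' @param w profile half-length (micrometres).
#' @param N number of sample points from b to b'.
#' @param pixel_size micrometres per pixel.
#' @return List with pixel-coordinate points \code{a}, \code{intersection},
#'   \code{b}, \code{bprime}, the sample positions \code{xs}, \code{ys}
#'   (length N) and the normalized arc-length \code{s} in [0, 1].
#' @export
build_profile_geometry <- function(pose, L = 4.5, w = 2.5, N = 64,
                                   pixel_size = 1) {
  if (L <= 0 || w <= 0) stop("'L' and 'w' must be > 0", call. = FALSE)
  if (!is_count(N) || N < 2) stop("'N' must be an integer >= 2",
                                  call. = FALSE)
  phi <- pose$phi_tip %||% pose$phi
  if (is.null(phi) || is.na(phi))
    stop("pose is not disambiguated: no oriented tip direction",
         call. = FALSE)
  tvec <- c(cos(phi), sin(phi))
  nvec <- c(sin(phi), -cos(phi))   # -90 deg in image coords: the b' side
  d_px <- (L / 3) / pixel_size
  w_px <- w / pixel_size
  inter <- pose$a + d_px * tvec
  b <- inter - w_px * nvec
  bp <- inter + w_px * nvec
  s <- seq(0, 1, length.out = N)
  list(a = pose$a, intersection = inter, b = b, bprime = bp,
       xs = b[1] + s * (bp[1] - b[1]), ys = b[2] + s * (bp[2] - b[2]),
       s = s)
}

# bilinear interpolation of a matrix at fractional (x = col, y = row)
bilinear <- function(image, x, y) {
  nr <- nrow(image); nc <- ncol(image)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  x0 <- pmin(pmax(x0, 1), nc - 1); y0 <- pmin(pmax(y0, 1), nr - 1)
  i00 <- image[cbind(y0, x0)];     i01 <- image[cbind(y0, x0 + 1)]
  i10 <- image[cbind(y0 + 1, x0)]; i11 <- image[cbind(y0 + 1, x0 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

#' Sample the intensity profile along b-b'
#'
#' @param image intensity matrix.
#' @param geom output of [build_profile_geometry()].
#' @return List with \code{values} (N interpolated grey levels, b to b'),
#'   \code{s} (normalized positions) and \code{t} if present on the
#'   geometry. Samples outside the image are clipped to the border with a
#'   warning; a fully out-of-bounds segment is an error.
#' @export
sample_profile <- function(image, geom) {
  nr <- nrow(image); nc <- ncol(image)
  inb <- geom$xs >= 1 & geom$xs <= nc & geom$ys >= 1 & geom$ys <= nr
  if (!any(inb)) stop("profile segment lies outside the image",
                      call. = FALSE)
  if (!all(inb)) warning("profile segment partially outside image; clipped")
  xs <- pmin(pmax(geom$xs, 1), nc)
  ys <- pmin(pmax(geom$ys, 1), nr)
  list(values = bilinear(image, xs, ys), s = geom$s)
}

#' Weighted-average position of an intensity profile
#'
#' The "centre of mass" of the grey levels along the b-b' segment,
#' \deqn{\bar{x} = \sum_i I_i x_i / \sum_i I_i,}
#' with positions normalized to [0, 1] from b to b'. By default the profile
#' minimum is subtracted first so the statistic follows the moving bright
#' feature rather than the flat background (set \code{background = "none"}
#' for raw grey levels).
#'
#' @param profile list with \code{values} and \code{s} (see
#'   [sample_profile()]), or a numeric vector (positions assumed uniform on
#'   [0, 1]).
#' @param background \code{"min"} (subtract profile minimum) or
#'   \code{"none"}.
#' @return Normalized position in [0, 1].
#' @export
weighted_average_position <- function(profile, background = c("min", "none")) {
  background <- match.arg(background)
  if (is.numeric(profile))
    profile <- list(values = profile,
                    s = seq(0, 1, length.out = length(profile)))
  v <- profile$values
  if (any(v < 0)) stop("profile values must be non-negative", call. = FALSE)
  if (background == "min") v <- v - min(v)
  tot <- sum(v)
  if (tot <= 0)
    stop("undefined weighted average: profile has no intensity above ",
         "background", call. = FALSE)
  sum(v * profile$s) / tot
}

#' Default classification parameters
#'
#' @param amp_threshold minimum robust peak-to-peak excursion of the
#'   weighted-average trace (normalized units) for a cell to count as
#'   rotating.
#' @param reset_fraction fraction of the trace range above which a
#'   counter-drift jump is treated as a half-turn reset and discarded.
#' @param min_halfcycles minimum number of half-turn sweeps.
#' @param min_confidence minimum fraction of retained steps agreeing with
#'   the called direction.
#' @param min_stacks minimum trace length.
#' @return Named list of parameters.
#' @export
classify_params <- function(amp_threshold = 0.035, reset_fraction = 0.5,
                            min_halfcycles = 2, min_confidence = 0.6,
                            min_stacks = 8) {
  list(amp_threshold = amp_threshold, reset_fraction = reset_fraction,
       min_halfcycles = min_halfcycles, min_confidence = min_confidence,
       min_stacks = min_stacks)
}

#' Classify rotation direction from a weighted-average trace
#'
#' Implements the direction rule: the cell rotates CCW when the weighted
#' average advances from b to b' between resets (the reset being the abrupt
#' return of the bright border to its starting side once a sweep completes)
#' and CW when it advances from b' to b. The trace amplitude (5th-95th
#' percentile span) gates non-rotating cells. The running drift is
#' estimated from the skewness of the step distribution (a sweep-and-reset
#' sawtooth has many steps one way and few large steps back, so the reset
#' tail dominates the third moment); reset jumps — steps larger than
#' \code{reset_fraction} of the amplitude against the drift — are
#' discarded, and the direction is the magnitude-weighted sign of the
#' retained steps. Confidence is the fraction of retained step mass
#' agreeing with the call. Sweep cycles are counted from alternating
#' extrema with prominence of at least half the amplitude.
#'
#' @param trace list or data.frame with \code{xbar} and \code{t} (seconds),
#'   or a numeric vector of xbar values (unit time steps then).
#' @param params see [classify_params()].
#' @param kymograph optional position-by-time profile matrix (see
#'   [kymograph()]). When supplied, the advance direction is measured
#'   directly as the dominant shift of consecutive profiles
#'   (cross-correlation lag, the slope of the kymograph stripes), which is
#'   considerably more robust than step statistics on the scalar trace;
#'   the trace still provides the amplitude gate and the sweep count.
#' @return A rotation call: list with \code{direction} ("ccw", "cw" or
#'   "non-rotating"), \code{confidence}, \code{amplitude},
#'   \code{frequency_hz} (sweep cycles per second), \code{n_halfcycles}
#'   (sweep segments counted), \code{n_stacks} and \code{low_confidence}
#'   flag.
#' @export
classify_rotation <- function(trace, params = classify_params(),
                              kymograph = NULL) {
  if (is.numeric(trace)) trace <- list(xbar = trace,
                                       t = seq_along(trace) - 1)
  x <- trace$xbar; t <- trace$t
  keep <- is.finite(x)
  x <- x[keep]; t <- t[keep]
  n <- length(x)
  if (n < params$min_stacks)
    stop("insufficient data: trace has ", n, " usable stacks, need >= ",
         params$min_stacks, call. = FALSE)
  qs <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
  amplitude <- qs[2] - qs[1]
  duration <- max(t) - min(t)
  ext <- zigzag_extrema(x, 0.5 * amplitude)
  n_halfcycles <- max(0L, length(ext) - 1L)
  frequency_hz <- if (duration > 0) n_halfcycles / (2 * duration)
                  else NA_real_
  call_out <- function(direction, confidence, low_conf = FALSE) {
    list(direction = direction, confidence = confidence,
         amplitude = amplitude, frequency_hz = frequency_hz,
         n_halfcycles = n_halfcycles, n_stacks = n,
         low_confidence = low_conf)
  }
  if (amplitude < params$amp_threshold)
    return(call_out("non-rotating", 1))
  if (!is.null(kymograph)) {
    lags <- profile_shifts(kymograph)
    nz <- lags[lags != 0]
    if (!length(nz)) return(call_out("non-rotating", 1))
    # the slow border sweep gives many small same-sign lags; the half-turn
    # resets give rare large opposite ones, which are discarded before the
    # majority vote
    m <- sign(sum(sign(nz)))
    if (m == 0) return(call_out("non-rotating", 0, TRUE))
    reset <- abs(nz) >= 0.6 * max(abs(nz)) & sign(nz) == -m & abs(nz) > 2
    kept <- nz[!reset]
    s <- sum(sign(kept))
    if (s == 0) return(call_out("non-rotating", 0, TRUE))
    direction <- if (s > 0) "ccw" else "cw"
    confidence <- mean(sign(kept) == sign(s))
  } else {
    # trace-only: the slow advance dominates the step counts, so the
    # median step gives the drift; half-turn resets (large steps against
    # it) are discarded and the call is the sign majority of the rest
    dx <- diff(x)
    nz <- dx[dx != 0]
    if (!length(nz)) return(call_out("non-rotating", 1))
    drift <- sign(stats::median(nz))
    if (drift == 0) return(call_out("non-rotating", 0, TRUE))
    reset <- abs(dx) > params$reset_fraction * amplitude &
      sign(dx) == -drift
    kept <- dx[!reset & dx != 0]
    if (!length(kept)) return(call_out("non-rotating", 0, TRUE))
    s <- sum(sign(kept))
    if (s == 0) return(call_out("non-rotating", 0, TRUE))
    direction <- if (s > 0) "ccw" else "cw"
    confidence <- mean(sign(kept) == sign(s))
  }
  if (confidence < params$min_confidence ||
      n_halfcycles < params$min_halfcycles)
    return(call_out("non-rotating", confidence, TRUE))
  call_out(direction, confidence)
}

# dominant shift (samples, positive = toward b') between consecutive
# kymograph columns, by maximum cross-correlation of the min-subtracted
# profiles
profile_shifts <- function(kg, maxlag = NULL) {
  N <- nrow(kg); n <- ncol(kg)
  if (is.null(maxlag)) maxlag <- max(3L, N %/% 6L)
  # correlate deviations from the temporal mean profile: the static head
  # structure would otherwise dominate the correlation and pin the lag at
  # zero, hiding the weak moving border
  dm <- kg - rowMeans(kg)
  lags <- integer(n - 1)
  cand <- seq.int(-maxlag, maxlag)
  for (t in seq_len(n - 1)) {
    a <- dm[, t]
    b <- dm[, t + 1]
    cc <- vapply(cand, function(L) {
      ia <- max(1, 1 - L):min(N, N - L)
      sum(a[ia] * b[ia + L])
    }, numeric(1))
    lags[t] <- cand[which.max(cc)]
  }
  lags
}

# alternating extrema of a series with a minimum prominence; returns the
# indices of the turning points
zigzag_extrema <- function(x, prominence) {
  n <- length(x)
  if (n < 3 || prominence <= 0) return(integer(0))
  ext <- integer(0)
  mn_i <- 1; mx_i <- 1
  mode <- 0   # 0 = undecided, +1 rising (seeking max), -1 falling
  for (i in 2:n) {
    if (x[i] < x[mn_i]) mn_i <- i
    if (x[i] > x[mx_i]) mx_i <- i
    if (mode == 0) {
      if (x[i] - x[mn_i] >= prominence) {
        ext <- c(ext, mn_i); mode <- 1; mx_i <- i
      } else if (x[mx_i] - x[i] >= prominence) {
        ext <- c(ext, mx_i); mode <- -1; mn_i <- i
      }
    } else if (mode == 1) {
      if (x[mx_i] - x[i] >= prominence) {
        ext <- c(ext, mx_i); mode <- -1; mn_i <- i
      }
    } else {
      if (x[i] - x[mn_i] >= prominence) {
        ext <- c(ext, mn_i); mode <- 1; mx_i <- i
      }
    }
  }
  ext
}

#' Kymograph of successive b-b' profiles
#'
#' @param profiles list of profiles (see [sample_profile()]) in time order,
#'   all with the same sample count.
#' @return Matrix (position x time): column j is profile j, rows run from b
#'   to b'.
#' @export
kymograph <- function(profiles) {
  ns <- vapply(profiles, function(p) length(p$values), integer(1))
  if (length(unique(ns)) != 1)
    stop("profiles have differing sample counts", call. = FALSE)
  vapply(profiles, function(p) p$values, numeric(ns[1]))
}

#' Full rotation-direction pipeline on a stack series
#'
#' Per stack: maximum intensity projection, head tracking, b-b' profile and
#' weighted-average position; then direction classification on the
#' resulting trace.
#'
#' @param series a [stack_series()].
#' @param L head long-axis length (micrometres) used for the d = L/3
#'   construction.
#' @param w profile half-length (micrometres).
#' @param N samples along b-b'.
#' @param params classification parameters, see [classify_params()].
#' @param background background handling for the weighted average.
#' @return List with \code{call} (see [classify_rotation()]), \code{trace}
#'   (data frame t, xbar), \code{track} (the [track_series()] table),
#'   \code{kymograph} and \code{n_excluded} (stacks with undefined xbar).
#' @export
detect_series <- function(series, L = 4.5, w = 2.5, N = 64,
                          params = classify_params(),
                          background = c("min", "none")) {
  background <- match.arg(background)
  track <- track_series(series)
  pix <- series$config$pixel_size
  n <- nrow(track)
  xbar <- rep(NA_real_, n)
  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    geom <- build_profile_geometry(
      list(a = c(track$x[i], track$y[i]), phi_tip = track$phi_tip[i]),
      L = L, w = w, N = N, pixel_size = pix)
    m <- mip(series$stacks[[i]])
    prof <- sample_profile(m, geom)
    profiles[[i]] <- prof
    xbar[i] <- tryCatch(weighted_average_position(prof, background),
                        error = function(e) NA_real_)
  }
  trace <- data.frame(t = track$t, xbar = xbar)
  kg <- kymograph(profiles)
  call <- classify_rotation(trace[is.finite(trace$xbar), ], params,
                            kymograph = kg[, is.finite(xbar), drop = FALSE])
  list(call = call, trace = trace, track = track, kymograph = kg,
       n_excluded = sum(!is.finite(xbar)))
}
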