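#' Flattened-ellipsoid head phantom
#'
#' The model head is a triaxial ellipsoid with strictly ordered semi-axes
#' (long > wide > thick), matching the flattened shape of the human sperm
#' head, rendered as a weak phase object whose per-pixel phase delay is
#' proportional to the chord thickness along the optical axis. An optional
#' translucent particle rigidly attached near the neck co-rotates with the
#' head and orbits the roll axis.
#'
#' @param semi_axes lengths (micrometres) \code{c(long, wide, thick)} with
#'   \code{long > wide > thick > 0}.
#' @param peak_phase phase delay of the flat-lying head at its thickest point
#'   (radians). The default 0.9 rad corresponds to the optical path of a
#'   head about 1.6 micrometres thick at a refractive-index excess of ~0.05
#'   over the medium.
#' @param face_asymmetry dorso-ventral asymmetry of the paddle-shaped head:
#'   the thickness semi-axis is \code{thick * (1 + face_asymmetry)} on one
#'   face and \code{thick * (1 - face_asymmetry)} on the other. Real heads
#'   have one rounder and one flatter face; a perfectly symmetric ellipsoid
#'   (0) renders a rotation signature with almost no chirality (see the
#'   methods vignette).
#' @param particle optional list with elements \code{radius} (micrometres),
#'   \code{offset} (distance behind the head centre along the axis,
#'   micrometres), \code{ring} (orbit radius about the roll axis,
#'   micrometres) and \code{peak_phase}.
#' @return Object of class \code{"head_phantom"}.
#' @export
head_phantom <- function(semi_axes = c(2.5, 1.6, 0.8), peak_phase = 0.9,
                         face_asymmetry = 0.25, particle = NULL) {
  if (length(semi_axes) != 3 || any(semi_axes <= 0) ||
      !(semi_axes[1] > semi_axes[2] && semi_axes[2] > semi_axes[3]))
    stop("'semi_axes' must satisfy long > wide > thick > 0", call. = FALSE)
  if (face_asymmetry < 0 || face_asymmetry >= 1)
    stop("'face_asymmetry' must be in [0, 1)", call. = FALSE)
  if (!is.null(particle)) {
    particle$radius <- particle$radius %||% 0.5
    particle$offset <- particle$offset %||% 1.5
    particle$ring <- particle$ring %||% 1.2
    particle$peak_phase <- particle$peak_phase %||% 0.9
  }
  structure(list(semi_axes = semi_axes, peak_phase = peak_phase,
                 face_asymmetry = face_asymmetry, particle = particle),
            class = "head_phantom")
}

#' Rigid-body motion model for a swimming, rolling cell
#'
#' The head translates with constant velocity, keeps a fixed in-plane
#' heading, oscillates axially (z-wobble) and rolls about its long axis at a
#' constant rate. Direction labels follow the head-to-tail convention: an
#' observer looking from the tip toward the flagellum, with "up" pointing
#' away from the objective, sees CCW rotation when the roll angle used here
#' increases with time.
#'
#' @param direction \code{"ccw"}, \code{"cw"} or \code{"none"}.
#' @param rotation_hz head rotations per second (must be 0 iff direction is
#'   \code{"none"}).
#' @param swim_velocity 3-vector (micrometres/s) in image coordinates
#'   (x = column, y = row, z = axial, positive away from the objective);
#'   \code{NULL} gives \code{swim_speed} along the heading.
#' @param swim_speed scalar speed used when \code{swim_velocity} is NULL.
#' @param initial_position 3-vector (micrometres), origin at the frame
#'   centre and the bottom of the axial scan.
#' @param initial_heading tip direction, radians in image coordinates
#'   (0 = toward increasing column).
#' @param z_wobble axial oscillation of the head centre:
#'   \code{c(amplitude, hz)} (micrometres, Hz).
#' @return Object of class \code{"motion_model"}.
#' @export
motion_model <- function(direction = c("ccw", "cw", "none"), rotation_hz = 5,
                         swim_velocity = NULL, swim_speed = 40,
                         initial_position = c(0, 0, 10),
                         initial_heading = 0,
                         z_wobble = c(amplitude = 1, hz = NA)) {
  direction <- match.arg(direction)
  if (direction == "none" && rotation_hz != 0) {
    if (missing(rotation_hz)) rotation_hz <- 0
    else stop("direction 'none' requires rotation_hz = 0", call. = FALSE)
  }
  if (direction != "none" && rotation_hz <= 0)
    stop("rotating directions require rotation_hz > 0", call. = FALSE)
  if (is.null(swim_velocity))
    swim_velocity <- swim_speed *
      c(cos(initial_heading), sin(initial_heading), 0)
  wob <- c(amplitude = unname(z_wobble[1]),
           hz = unname(if (is.na(z_wobble[2])) max(rotation_hz, 1)
                       else z_wobble[2]))
  structure(list(direction = direction, rotation_hz = rotation_hz,
                 swim_velocity = swim_velocity,
                 initial_position = initial_position,
                 initial_heading = initial_heading, z_wobble = wob),
            class = "motion_model")
}

direction_sign <- function(direction)
  switch(direction, ccw = 1, cw = -1, none = 0)

#' Acquisition configuration for the multi-plane scan
#'
#' Camera and piezo settings for the triangular axial scan. The number of
#' focal planes per rising slope, \code{fps / (2 * scan_hz)}, must be a
#' positive integer; plane spacing is \code{scan_amplitude} divided by that
#' count. Defaults emulate the acquisition system: 8000 frames/s, 80 Hz
#' triangular scan of 20 micrometres (50 planes per rising slope, 0.4
#' micrometre spacing), 640x480 frames, 3.4 s records.
#'
#' @param fps camera frames per second.
#' @param scan_hz triangular scan frequency (Hz).
#' @param scan_amplitude peak-to-peak axial scan range (micrometres).
#' @param pixel_size micrometres per pixel.
#' @param frame_shape frame size in pixels, \code{c(rows, cols)}.
#' @param duration record length (seconds).
#' @param noise_sd additive Gaussian intensity noise, as a fraction of the
#'   unit background.
#' @param seed integer seed making synthetic records reproducible.
#' @return Object of class \code{"acquisition_config"}.
#' @export
acquisition_config <- function(fps = 8000, scan_hz = 80, scan_amplitude = 20,
                               pixel_size = 0.16,
                               frame_shape = c(480, 640), duration = 3.4,
                               noise_sd = 0.01, seed = 1) {
  planes <- fps / (2 * scan_hz)
  if (!is_count(planes))
    stop("config error: planes_per_rising_slope = fps / (2 * scan_hz) ",
         "must be a positive integer (got ", planes, ")", call. = FALSE)
  if (length(frame_shape) == 1) frame_shape <- c(frame_shape, frame_shape)
  structure(list(fps = fps, scan_hz = scan_hz,
                 scan_amplitude = scan_amplitude, pixel_size = pixel_size,
                 frame_shape = as.integer(frame_shape), duration = duration,
                 noise_sd = noise_sd, seed = seed,
                 planes_per_rising_slope = as.integer(planes),
                 plane_spacing = scan_amplitude / planes),
            class = "acquisition_config")
}

#' Axial position of the triangular focal-plane scan
#'
#' @param t time (seconds, vectorized).
#' @param cfg an [acquisition_config()].
#' @return Data frame with columns \code{z} (focal-plane position,
#'   micrometres above the scan bottom), \code{slope} ("rising" or
#'   "falling") and \code{plane} (0-based plane index on rising slopes, NA
#'   on falling).
#' @export
triangular_scan_z <- function(t, cfg) {
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  P <- cfg$planes_per_rising_slope
  cyc <- (t * cfg$scan_hz) %% 1
  rising <- cyc < 0.5
  z <- ifelse(rising, 2 * cyc, 2 - 2 * cyc) * cfg$scan_amplitude
  plane <- ifelse(rising, floor(2 * cyc * P + 1e-9), NA_real_)
  data.frame(z = z, slope = ifelse(rising, "rising", "falling"),
             plane = as.integer(plane))
}

#' Head pose at a given time
#'
#' @param t time (seconds).
#' @param motion a [motion_model()].
#' @return List with \code{centre} (x, y, z in micrometres), \code{heading}
#'   (radians) and \code{roll} (radians, sign encodes direction).
#' @export
pose_at <- function(t, motion) {
  if (t < 0) stop("'t' must be >= 0", call. = FALSE)
  wob <- motion$z_wobble
  centre <- motion$initial_position + motion$swim_velocity * t +
    c(0, 0, wob["amplitude"] * sin(2 * pi * wob["hz"] * t))
  list(centre = unname(centre), heading = motion$initial_heading,
       roll = direction_sign(motion$direction) * 2 * pi *
         motion$rotation_hz * t)
}

#' Render one camera frame of the phantom scene
#'
#' Multi-slice coherent rendering: the posed 3D head (and optional neck
#' particle) is decomposed into axial slabs; a unit plane wave travelling
#' toward the objective accumulates the phase of each slab's occupancy and
#' is Fresnel-propagated (angular spectrum, paraxial) between slabs, then to
#' the focal plane, and finally low-pass filtered by the objective pupil
#' (with its spherical-aberration phase). The squared modulus is returned;
#' the background intensity is 1. Under this model the through-focus
#' contrast inversion emerges from propagation: the optically denser head
#' acts as a weak converging lens, so it renders bright when behind the
#' focal plane (farther from the objective) and dark in front, as real
#' translucent cells do in bright field.
#'
#' @param pose output of [pose_at()].
#' @param phantom a [head_phantom()].
#' @param focal_z focal-plane position (micrometres, same axis as the pose).
#' @param model an [aberration_model()] (pupil fraction, wavelength and
#'   spherical-aberration phase).
#' @param cfg an [acquisition_config()] (frame shape and pixel size).
#' @param n_slices number of axial slabs.
#' @param prop_sign sign of the propagation phase; the default makes
#'   behind-the-focal-plane objects bright, flip it for an optical train
#'   with the opposite convention.
#' @return Intensity image matrix; a uniform frame with a warning when the
#'   phantom lies outside the field of view.
#' @export
render_frame <- function(pose, phantom, focal_z, model, cfg, n_slices = 10,
                         prop_sign = -1) {
  ef <- exit_field(pose, phantom, model, cfg, n_slices, prop_sign)
  if (!ef$seen) {
    warning("phantom outside field of view; returning empty frame")
    return(intensity_image(matrix(1, cfg$frame_shape[1],
                                  cfg$frame_shape[2])))
  }
  image_at_plane(ef, focal_z)
}

# wave field just below the posed object (multi-slice accumulation),
# reusable across the focal planes of one stack
exit_field <- function(pose, phantom, model, cfg, n_slices = 10,
                       prop_sign = -1) {
  nr <- cfg$frame_shape[1]; nc <- cfg$frame_shape[2]; pix <- cfg$pixel_size
  ax <- phantom$semi_axes; a <- ax[1]; b <- ax[2]; cth <- ax[3]
  fa <- phantom$face_asymmetry %||% 0
  cd2 <- (cth * (1 + fa))^2; cv2 <- (cth * (1 - fa))^2
  X <- matrix((seq_len(nc) - (nc + 1) / 2) * pix, nr, nc, byrow = TRUE)
  Y <- matrix((seq_len(nr) - (nr + 1) / 2) * pix, nr, nc)
  dx <- X - pose$centre[1]; dy <- Y - pose$centre[2]
  tx <- cos(pose$heading); ty <- sin(pose$heading)
  u <- dx * tx + dy * ty          # along the long axis, toward the tip
  v <- -dx * ty + dy * tx         # perpendicular, tip rotated +90 deg
  al <- pose$roll
  uq <- 1 - u^2 / a^2
  prt <- phantom$particle
  rad <- max(b, cth * (1 + fa)) + 0.2
  if (!is.null(prt)) rad <- max(rad, prt$ring + prt$radius + 0.2)
  zs <- seq(pose$centre[3] + rad, pose$centre[3] - rad,
            length.out = n_slices + 1)    # top to bottom
  phase_per_um <- phantom$peak_phase / (2 * cth)
  if (!is.null(prt)) {
    up <- -(a + prt$offset)
    vp <- prt$ring * sin(al)
    zp <- pose$centre[3] + prt$ring * cos(al)
    p_per_um <- prt$peak_phase / (2 * prt$radius)
  }
  fr <- c(0:(ceiling(nr / 2) - 1), -(floor(nr / 2)):-1) / (nr * pix)
  fc <- c(0:(ceiling(nc / 2) - 1), -(floor(nc / 2)):-1) / (nc * pix)
  f2 <- outer(fr^2, fc^2, "+")
  dzs <- zs[1] - zs[2]              # slabs are equally spaced
  Kprop <- exp(prop_sign * 1i * pi * model$wavelength * dzs * f2)
  U <- matrix(1 + 0i, nr, nc)
  seen <- FALSE
  for (k in seq_len(n_slices)) {
    occ <- matrix(0, nr, nc)
    for (zmid in zs[k] - dzs * c(0.25, 0.75)) {
      zrel <- zmid - pose$centre[3]
      eta <- cos(al) * v - sin(al) * zrel
      zeta <- sin(al) * v + cos(al) * zrel
      c2 <- cv2 + (cd2 - cv2) * (zeta >= 0)
      occ <- occ + 0.5 * (eta^2 / b^2 + zeta^2 / c2 <= uq)
      if (!is.null(prt))
        occ <- occ + 0.5 * (p_per_um / phase_per_um) *
          ((u - up)^2 + (v - vp)^2 + (zmid - zp)^2 <= prt$radius^2)
    }
    sel <- occ > 0
    if (any(sel)) {
      seen <- TRUE
      U[sel] <- U[sel] * exp(1i * phase_per_um * dzs * occ[sel])
    }
    if (k < n_slices) U <- ifft2(fft2(U) * Kprop)
  }
  rho2 <- freq_rho2(nr, nc, model$pupil_frac * min(nr, nc) / 2)
  pupil <- (rho2 <= 1) *
    exp(1i * model_scale(model, "convolution") * model$A_s * rho2^2)
  list(FU = fft2(U), z_exit = zs[n_slices], f2 = f2, pupil = pupil,
       lambda = model$wavelength, prop_sign = prop_sign, seen = seen,
       shape = c(nr, nc))
}

# image the cached exit field at one focal plane: propagate the remaining
# distance and apply the pupil in a single frequency-domain pass
image_at_plane <- function(ef, focal_z) {
  K <- exp(ef$prop_sign * 1i * pi * ef$lambda * (ef$z_exit - focal_z) *
             ef$f2) * ef$pupil
  intensity_image(Mod(ifft2(ef$FU * K))^2)
}

#' Generate a synthetic multi-plane acquisition with ground truth
#'
#' Renders one frame per camera tick while the focal plane follows the
#' triangular scan, groups rising-slope frames into z-stacks, adds seeded
#' Gaussian intensity noise, and logs the exact pose and focal plane of
#' every frame. Falling-slope frames are rendered only when
#' \code{keep_falling} is TRUE (they are discarded in the standard analysis);
#' either way they are accounted for in the frame count and the log.
#'
#' @param phantom a [head_phantom()].
#' @param motion a [motion_model()].
#' @param cfg an [acquisition_config()].
#' @param model an [aberration_model()].
#' @param n_slices depth bins per rendered frame.
#' @param keep_falling render and keep falling-slope frames (reversed
#'   stacks) in the \code{falling} element.
#' @param pose_per \code{"frame"} evaluates the pose at every camera tick
#'   (the rotation advances within each stack, as in the physical
#'   acquisition); \code{"stack"} freezes the pose at each rising slope's
#'   mid-time and reuses one propagated field for all of its focal planes,
#'   about an order of magnitude faster (a rising slope lasts 1/160 s, over
#'   which a 3-8 Hz head advances by only 7-18 degrees).
#' @return A \code{"stack_series"} object (see [stack_series()]) whose
#'   \code{ground_truth} element is the per-frame log with the global
#'   direction label attached as an attribute.
#' @export
generate_stack_series <- function(phantom, motion, cfg, model,
                                  n_slices = 10, keep_falling = FALSE,
                                  pose_per = c("frame", "stack")) {
  pose_per <- match.arg(pose_per)
  n_frames <- round(cfg$duration * cfg$fps)
  P <- cfg$planes_per_rising_slope
  frames_per_cycle <- 2L * P
  n_stacks <- n_frames %/% frames_per_cycle
  tj <- (seq_len(n_frames) - 1) / cfg$fps
  scan <- triangular_scan_z(tj, cfg)
  log <- data.frame(frame = seq_len(n_frames) - 1L, t = tj,
                    x = NA_real_, y = NA_real_, z = NA_real_,
                    heading = motion$initial_heading, roll = NA_real_,
                    focal_z = scan$z, slope = scan$slope, plane = scan$plane,
                    stack = ifelse(scan$slope == "rising",
                                   (seq_len(n_frames) - 1L) %/% frames_per_cycle,
                                   NA_integer_))
  log$stack[!is.na(log$stack) & log$stack >= n_stacks] <- NA_integer_
  stacks <- vector("list", n_stacks)
  falling <- if (keep_falling) list() else NULL
  with_seed(cfg$seed, {
    ef <- NULL; ef_stack <- -1L
    for (j in seq_len(n_frames)) {
      p <- pose_at(tj[j], motion)
      log$x[j] <- p$centre[1]; log$y[j] <- p$centre[2]; log$z[j] <- p$centre[3]
      log$roll[j] <- p$roll
      render_it <- scan$slope[j] == "rising" || keep_falling
      if (!render_it) next
      si <- log$stack[j]
      if (pose_per == "frame" || is.na(si) || scan$slope[j] != "rising") {
        img <- suppressWarnings(
          render_frame(p, phantom, scan$z[j], model, cfg, n_slices))
      } else {
        if (si != ef_stack) {
          t_mid <- si / cfg$scan_hz + (P / 2) / cfg$fps
          ef <- exit_field(pose_at(t_mid, motion), phantom, model, cfg,
                           n_slices)
          ef_stack <- si
        }
        img <- if (ef$seen) image_at_plane(ef, scan$z[j]) else {
          warning("phantom outside field of view; returning empty frame")
          intensity_image(matrix(1, cfg$frame_shape[1], cfg$frame_shape[2]))
        }
      }
      if (cfg$noise_sd > 0)
        img <- pmax(img + stats::rnorm(length(img), 0, cfg$noise_sd), 0)
      if (scan$slope[j] == "rising" && !is.na(si)) {
        if (is.null(stacks[[si + 1]]))
          stacks[[si + 1]] <- vector("list", P)
        stacks[[si + 1]][[log$plane[j] + 1L]] <- img
      } else if (keep_falling) {
        falling[[length(falling) + 1L]] <- img
      }
    }
  })
  z_planes <- (seq_len(P) - 1) * cfg$plane_spacing
  mps <- lapply(seq_len(n_stacks), function(si) {
    multi_plane_stack(stacks[[si]], z_positions = z_planes,
                      t_start = (si - 1) / cfg$scan_hz,
                      index = si - 1L)
  })
  attr(log, "direction") <- motion$direction
  stack_series(mps, cfg,
               provenance = list(source = "synthetic",
                                 package_version =
                                   as.character(utils::packageVersion("spinsense")),
                                 seed = cfg$seed),
               ground_truth = log, falling = falling,
               n_frames_total = n_frames)
}
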