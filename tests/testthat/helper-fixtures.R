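# shared fixtures: a small, fast synthetic acquisition used across tests

tiny_cfg <- function(noise_sd = 0, seed = 1, duration = 0.1,
                     planes = 4L, frame = 64L, pixel = 0.12) {
  acquisition_config(fps = 2 * 80 * planes, scan_hz = 80,
                     scan_amplitude = 6, pixel_size = pixel,
                     frame_shape = c(frame, frame), duration = duration,
                     noise_sd = noise_sd, seed = seed)
}

# the validation-suite acquisition: 16 planes of 0.5 um per rising slope
cohort_cfg <- function(noise_sd, seed, duration = 0.5) {
  acquisition_config(fps = 2560, scan_hz = 80, scan_amplitude = 8,
                     pixel_size = 0.10, frame_shape = c(128, 128),
                     duration = duration, noise_sd = noise_sd, seed = seed)
}

cohort_model <- function() aberration_model(A_s = -4e-4, pupil_frac = 0.6)

cohort_motion <- function(direction, rotation_hz, heading, z0,
                          swim_speed = 9) {
  # callers pass speed scaled so total travel stays within the field
  motion_model(direction,
               rotation_hz = if (direction == "none") 0 else rotation_hz,
               swim_speed = swim_speed,
               initial_position = c(-2.2 * cos(heading),
                                    -2.2 * sin(heading), z0),
               initial_heading = heading)
}

run_phantom_cell <- function(direction, rotation_hz, heading, z0,
                             noise_sd, seed,
                             duration = max(0.5, 3 / rotation_hz)) {
  series <- generate_stack_series(
    head_phantom(),
    cohort_motion(direction, rotation_hz, heading, z0,
                  swim_speed = 4.5 / duration),
    cohort_cfg(noise_sd, seed, duration),
    cohort_model(), pose_per = "stack")
  detect_series(series, L = 5, w = 2)
}

# footprint of the standard central square object
rect_footprint <- function(grid = 128, obj_px = 40) {
  m <- matrix(FALSE, grid, grid)
  i0 <- (grid - obj_px) / 2 + 1
  m[i0:(i0 + obj_px - 1), i0:(i0 + obj_px - 1)] <- TRUE
  m
}

half_footprints <- function(grid = 128, obj_px = 40) {
  f <- rect_footprint(grid, obj_px)
  left <- f; left[, (grid / 2 + 1):grid] <- FALSE
  right <- f; right[, 1:(grid / 2)] <- FALSE
  list(left = left, right = right)
}

mirror_cols <- function(m) m[, ncol(m):1]

# centroid of the above-background bright region, x (column) coordinate
bright_region_x <- function(image) {
  w <- pmax(image - stats::median(image), 0)^2
  sum(col(image) * w) / sum(w)
}
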