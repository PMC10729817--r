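test_that("wave aberration follows the defocus + spherical form", {
  m <- aberration_model(A_d = 2, A_s = 3)
  expect_identical(wave_aberration(0, 0, m), 0)
  expect_equal(wave_aberration(1, 0, aberration_model(A_d = 0.7)), 0.7)
  # direct arithmetic at the pupil edge with the printed panel coefficients
  expect_equal(
    wave_aberration(0, 1, aberration_model(A_d = 0.04, A_s = -4e-4)),
    0.0396)
  # rho mixes both coordinates
  expect_equal(wave_aberration(0.6, 0.8, m), 2 * 1 + 3 * 1)
  expect_error(aberration_model(pupil_radius = 0), "pupil_radius")
})

test_that("defocus amplitude sign tracks the object distance", {
  # 1/f = 1/di + 1/d0 with f = 1, di = 2, d0 = 2: focused
  expect_equal(defocus_amplitude_sign(2, 1, 2), 0)
  expect_gt(defocus_amplitude_sign(2.5, 1, 2), 0)  # object farther: A_d > 0
  expect_lt(defocus_amplitude_sign(1.7, 1, 2), 0)  # object nearer: A_d < 0
  expect_error(defocus_amplitude_sign(-1, 1, 2), "d0")
})

test_that("unaberrated psf is a centred, symmetric Airy pattern", {
  h <- psf(aberration_model(), 128)
  mag <- Mod(h)
  ctr <- c(65, 65)
  expect_equal(which(mag == max(mag), arr.ind = TRUE)[1, ],
               c(row = 65, col = 65))
  # radial symmetry: quadrant reflections agree
  expect_equal(mag[65 + 1:20, 65], mag[65 - 1:20, 65], tolerance = 1e-12)
  expect_equal(mag[65, 65 + 1:20], mag[65 + 1:20, 65], tolerance = 1e-12)
})

test_that("psf conserves pupil energy (Parseval)", {
  for (Ad in c(0, 0.3)) {
    m <- aberration_model(A_d = Ad, A_s = -4e-4)
    h <- psf(m, 128)
    P <- sum(spinsense:::freq_rho2(128, 128, 0.35 * 64) <= 1)
    expect_equal(sum(Mod(h)^2), P, tolerance = 1e-9)
  }
})

test_that("psf modulus is even in the defocus amplitude", {
  hp <- psf(aberration_model(A_d = 0.3), 128)
  hm <- psf(aberration_model(A_d = -0.3), 128)
  expect_equal(Mod(hp), Mod(hm), tolerance = 1e-12)
})

test_that("zero-phase object renders a perfectly flat image", {
  obj <- rect_phase_object(phase = 0)
  for (co in list(c(0.3, 0), c(0.04, -4e-4), c(-0.2, 4e-4))) {
    I <- image_weak_phase_object(
      obj, aberration_model(A_d = co[1], A_s = co[2]))
    expect_lt(diff(range(I)) / mean(I), 1e-6)
  }
})

test_that("defocus alone gives no contrast inversion; spherical aberration
           gates the inversion (panel construction)", {
  obj <- rect_phase_object()
  foot <- rect_footprint()
  cs <- function(Ad, As) contrast_stat(
    image_weak_phase_object(obj, aberration_model(A_d = Ad, A_s = As),
                            method = "diffraction"), foot)
  a1 <- cs(0.3, 0);  a2 <- cs(-0.3, 0)
  expect_identical(sign(a1), sign(a2))
  b1 <- cs(0.04, -4e-4); b2 <- cs(-0.04, -4e-4)
  expect_identical(sign(b1), -sign(b2))
  f1 <- cs(0.04, 4e-4); f2 <- cs(-0.04, 4e-4)
  expect_identical(sign(f1), -sign(b1))
  expect_identical(sign(f2), -sign(b2))
})

test_that("through-focus contrast inverts in the scene model", {
  foot <- rect_footprint()
  m <- aberration_model(A_s = -4e-4)
  behind <- image_weak_phase_object(rect_phase_object(height = 2), m)
  front <- image_weak_phase_object(rect_phase_object(height = -2), m)
  expect_gt(contrast_stat(behind, foot), 0)
  expect_lt(contrast_stat(front, foot), 0)
})

test_that("inclined object degenerates to the parallel case and splits
           bright/dark across the tilt axis", {
  m <- aberration_model(A_s = -4e-4, defocus_per_um = 0.09)
  flat <- inclined_plate_object(tilt_deg = 0)
  expect_equal(
    as.numeric(image_inclined_object(flat, m, n_slices = 5)),
    as.numeric(image_weak_phase_object(flat, m)),
    tolerance = 1e-12)
  halves <- half_footprints()
  plate <- inclined_plate_object(tilt_deg = 5)
  I <- image_inclined_object(plate, m, n_slices = 8)
  cl <- contrast_stat(I, halves$left); cr <- contrast_stat(I, halves$right)
  expect_identical(sign(cl), -sign(cr))
  # flipping the tilt swaps which half is bright
  I2 <- image_inclined_object(inclined_plate_object(tilt_deg = -5), m,
                              n_slices = 8)
  expect_identical(sign(contrast_stat(I2, halves$left)), sign(cr))
  # flipping the transfer-sign convention swaps the halves too
  m2 <- aberration_model(A_s = -4e-4, defocus_per_um = 0.09,
                         scale = 25)
  I3 <- image_inclined_object(plate, m2, n_slices = 8)
  expect_identical(sign(contrast_stat(I3, halves$left)), sign(cr))
  expect_error(image_inclined_object(plate, m, n_slices = 1), "n_slices")
})

test_that("spinning plates drift their bright region with the spin
           direction and reset each half turn", {
  obj <- rect_phase_object()
  m <- aberration_model(A_s = -0.004)
  ccw <- render_spinning_sequence(obj, "ccw", 8, m, alpha0 = 0.1 * pi,
                                  revolutions = 0.4)
  cw <- render_spinning_sequence(obj, "cw", 8, m, alpha0 = -0.1 * pi,
                                 revolutions = 0.4)
  cx_ccw <- vapply(ccw, bright_region_x, numeric(1))
  cx_cw <- vapply(cw, bright_region_x, numeric(1))
  expect_true(all(diff(cx_ccw) > 0))   # left to right
  expect_true(all(diff(cx_cw) < 0))    # right to left
  # crossing the half-turn: the bright region jumps back to its start side
  full <- render_spinning_sequence(obj, "ccw", 13, m, alpha0 = 0.08 * pi,
                                   revolutions = 0.9)
  cx <- vapply(full, bright_region_x, numeric(1))
  steps <- diff(cx)
  expect_true(any(steps < -10))                  # one large reset jump
  expect_true(mean(steps[steps > 0] > 0) == 1)   # advances otherwise
  expect_error(render_spinning_sequence(obj, "ccw", 2, m), "n_frames")
  expect_error(
    render_spinning_sequence(rect_phase_object(phase = 0), "ccw", 6, m),
    "empty")
})

test_that("mirroring the plate and reversing the spin mirrors the frames
           pixel-exactly", {
  obj <- rect_phase_object(128, 40)
  # shift the plate off-centre so the mirror is informative
  pm <- matrix(0, 128, 128); pm[45:84, 25:64] <- 0.1
  obj$phase_map <- pm
  m <- aberration_model(A_s = -0.004)
  fr <- render_spinning_sequence(obj, "ccw", 5, m, alpha0 = 0.1 * pi,
                                 revolutions = 0.3)
  objm <- obj; objm$phase_map <- mirror_cols(pm)
  frm <- render_spinning_sequence(objm, "cw", 5, m, alpha0 = -0.1 * pi,
                                  revolutions = 0.3)
  for (k in seq_along(fr))
    expect_equal(as.numeric(mirror_cols(fr[[k]])), as.numeric(frm[[k]]),
                 tolerance = 1e-12)
})
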