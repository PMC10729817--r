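test_that("maximum intensity projection is the pixelwise plane maximum", {
  one <- array(matrix(1:9, 3, 3), c(3, 3, 1))
  expect_equal(as.numeric(mip(one)), as.numeric(one[, , 1]))
  const <- array(rep(c(1, 3, 2), each = 4), c(2, 2, 3))
  expect_true(all(mip(const) == 3))
  two <- array(c(1, 3, 5, 0, 4, 1, 2, 7), c(2, 2, 2))
  expect_equal(as.numeric(mip(two)), c(4, 3, 5, 7))  # elementwise max
  expect_error(mip(matrix(1, 2, 2)), "3D")
  expect_error(mip(array(0, c(2, 2, 0))), "empty")
})

test_that("the moment tracker recovers centre and orientation of a
           synthetic head", {
  blob <- function(n, cx, cy, phi, a = 12, b = 6) {
    X <- matrix(seq_len(n), n, n, byrow = TRUE) - cx
    Y <- matrix(seq_len(n), n, n) - cy
    u <- X * cos(phi) + Y * sin(phi)
    v <- -X * sin(phi) + Y * cos(phi)
    1 + 0.5 * exp(-(u^2 / a^2 + v^2 / b^2))
  }
  for (case in list(c(40.3, 52.7, 0.4), c(60, 30, 2.2), c(50, 50, 0))) {
    I <- blob(96, case[1], case[2], case[3])
    pose <- track_head(I)
    expect_lt(sqrt(sum((pose$a - case[1:2])^2)), 0.5)
    dphi <- abs(pose$phi - (case[3] %% pi))
    expect_lt(min(dphi, pi - dphi), 2 * pi / 180)
  }
  # rotating the image by 90 deg rotates the estimates accordingly
  I <- blob(96, 40, 52, 0.4)
  Ir <- t(I)[, 96:1]   # 90 deg counterclockwise in display terms
  p1 <- track_head(I); p2 <- track_head(Ir)
  dphi <- abs((p1$phi + pi / 2) %% pi - p2$phi)
  expect_lt(min(dphi, pi - dphi), 1e-6)
  expect_error(track_head(matrix(1, 32, 32)), "blank")
})

test_that("profile geometry places the intersection at L/3 ahead and b/b'
           symmetrically with fixed handedness", {
  g <- build_profile_geometry(list(a = c(0, 0), phi_tip = 0),
                              L = 3, w = 2, N = 5, pixel_size = 1)
  expect_equal(g$intersection, c(1, 0))
  expect_equal(g$b, c(1, 2))         # b opposite the -90-degree side
  expect_equal(g$bprime, c(1, -2))
  expect_equal(g$s, c(0, 0.25, 0.5, 0.75, 1))
  # rotating the pose rotates the construction rigidly
  th <- 0.7
  gr <- build_profile_geometry(list(a = c(0, 0), phi_tip = th),
                               L = 3, w = 2, N = 5, pixel_size = 1)
  expect_equal(sqrt(sum((gr$b - gr$bprime)^2)), 4)
  expect_equal(sqrt(sum(gr$intersection^2)), 1)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(as.numeric(R %*% g$bprime), gr$bprime)
  # flipping the tip direction mirrors b and b'
  gf <- build_profile_geometry(list(a = c(0, 0), phi_tip = pi),
                               L = 3, w = 2, N = 5, pixel_size = 1)
  expect_equal(gf$b, c(-1, -2))
  expect_equal(gf$bprime, c(-1, 2))
  expect_error(build_profile_geometry(list(a = c(0, 0), phi_tip = 0),
                                      L = -1), "L")
})

test_that("profile sampling interpolates bilinearly along b-b'", {
  g <- build_profile_geometry(list(a = c(20, 20), phi_tip = 0),
                              L = 6, w = 10, N = 21, pixel_size = 1)
  const <- matrix(2.5, 48, 48)
  expect_equal(sample_profile(const, g)$values, rep(2.5, 21))
  ramp <- matrix(seq_len(48), 48, 48)  # rises along rows
  p <- sample_profile(ramp, g)
  # b sits on the +row side, so the sampled ramp descends from b to b'
  expect_equal(p$values, seq(30, 10, length.out = 21))
  # a bright spot lands at its normalized offset along the segment
  img <- matrix(0, 48, 48); img[26, 22] <- 5   # at s = 0.2 along b->b'
  blur <- img
  ps <- sample_profile(blur, g)
  expect_lt(abs(ps$s[which.max(ps$values)] - 0.2), 0.051)
  out <- build_profile_geometry(list(a = c(500, 500), phi_tip = 0),
                                L = 6, w = 10, N = 21, pixel_size = 1)
  expect_error(sample_profile(const, out), "outside")
})

test_that("weighted average position is the intensity centre of mass", {
  expect_equal(weighted_average_position(rep(3, 11), "none"), 0.5)
  delta <- c(rep(0, 9), 1)
  expect_equal(weighted_average_position(delta, "none"), 1)
  # hand arithmetic: (0 + 2/3 + 2 + 4) / 10
  expect_equal(
    weighted_average_position(list(values = c(1, 2, 3, 4),
                                   s = c(0, 1 / 3, 2 / 3, 1)), "none"),
    0.6667, tolerance = 1e-4)
  expect_error(weighted_average_position(rep(0, 8), "none"), "undefined")
  # min subtraction shifts weight to the moving feature
  prof <- c(10, 10, 10, 11, 10)
  expect_equal(weighted_average_position(prof), 0.75)
})

test_that("adding a constant offset pulls the raw weighted average toward
           the centre monotonically", {
  v <- c(0.1, 0.2, 1.5, 0.4, 0.1, 0.1, 0.1, 0.1)
  xb <- vapply(c(0, 1, 5, 25), function(off)
    weighted_average_position(v + off, "none"), numeric(1))
  expect_true(all(diff(abs(xb - 0.5)) < 0))
})

test_that("sawtooth traces classify by their advance direction", {
  set.seed(42)
  saw <- rep(seq(0.3, 0.7, length.out = 8), 4)    # rise, abrupt reset
  up <- classify_rotation(saw + rnorm(32, 0, 0.004))
  expect_identical(up$direction, "ccw")
  expect_gt(up$confidence, 0.9)
  down <- classify_rotation(1 - saw + rnorm(32, 0, 0.004))
  expect_identical(down$direction, "cw")
  flat <- classify_rotation(0.5 + rnorm(40, 0, 0.005))
  expect_identical(flat$direction, "non-rotating")
  expect_error(classify_rotation(c(0.4, 0.6, 0.5)), "insufficient")
})

test_that("kymographs stack profiles as columns", {
  profs <- lapply(1:5, function(k) list(values = rep(k, 7),
                                        s = seq(0, 1, length.out = 7)))
  kg <- kymograph(profs)
  expect_equal(dim(kg), c(7, 5))
  expect_true(all(kg[, 3] == 3))
  bad <- c(profs, list(list(values = 1:3, s = c(0, 0.5, 1))))
  expect_error(kymograph(bad), "sample counts")
})

test_that("set.seed-free classification is deterministic for a fixed
           trace", {
  saw <- rep(seq(0.35, 0.65, length.out = 10), 3)
  a <- classify_rotation(saw)
  b <- classify_rotation(saw)
  expect_identical(a, b)
})
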