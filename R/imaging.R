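#' Weak phase object on an image grid
#'
#' A translucent object that delays the phase of transmitted light by
#' \code{phase_map} radians per pixel without absorbing it, lying at the
#' axial offsets given by \code{height_map} (micrometres, signed; positive =
#' farther from the objective than the focused object plane, i.e. behind it;
#' 0 = in focus).
#'
#' @param phase_map numeric matrix of phase delays (radians). Values should
#'   stay well below 1 rad for the weak-phase regime (0.1 rad is typical).
#' @param height_map numeric matrix of axial offsets (micrometres), or a
#'   scalar for an object parallel to the lens.
#' @param pixel_pitch pixel size in micrometres.
#' @return An object of class \code{"phase_object"}.
#' @export
phase_object <- function(phase_map, height_map = 0, pixel_pitch = 1) {
  if (!is.matrix(phase_map) || !is.numeric(phase_map))
    stop("'phase_map' must be a numeric matrix", call. = FALSE)
  if (length(height_map) == 1)
    height_map <- matrix(height_map, nrow(phase_map), ncol(phase_map))
  if (!all(dim(height_map) == dim(phase_map)))
    stop("'height_map' must match the shape of 'phase_map'", call. = FALSE)
  if (any(!is.finite(phase_map)) || any(!is.finite(height_map)))
    stop("phase and height maps must be finite", call. = FALSE)
  if (max(abs(phase_map)) > 0.5)
    warning("phase exceeds 0.5 rad; outside the weak-phase regime")
  structure(list(phase_map = phase_map, height_map = height_map,
                 pixel_pitch = pixel_pitch),
            class = "phase_object")
}

# central rectangle of `obj_px` pixels with constant phase: the standard
# simulation target (128x128 grid, 40x40 object)
#' Rectangular test phase object
#'
#' @param grid grid size in pixels (square).
#' @param obj_px side of the central square object in pixels.
#' @param phase phase delay inside the object (radians).
#' @param height constant axial offset (micrometres).
#' @return A [phase_object()].
#' @export
rect_phase_object <- function(grid = 128, obj_px = 40, phase = 0.1,
                              height = 0) {
  m <- matrix(0, grid, grid)
  i0 <- floor((grid - obj_px) / 2) + 1
  i1 <- i0 + obj_px - 1
  m[i0:i1, i0:i1] <- phase
  phase_object(m, height)
}

#' Bright-field image of a weak phase object parallel to the lens
#'
#' Renders the intensity image of a constant-height weak phase object under
#' the given defocus and spherical aberration. Two formation methods are
#' provided:
#' \describe{
#'   \item{\code{"convolution"}}{Shift-invariant coherent imaging: the object
#'     field \eqn{\exp(i\,\phi)} is filtered by the pupil transfer function
#'     \eqn{P \exp(i\,scale\,W)} and squared. This is the scene model used by
#'     the phantom renderer; a zero-phase object yields an exactly uniform
#'     image, and contrast flips sign with the defocus term (the familiar
#'     under/over-focus inversion of phase contrast).}
#'   \item{\code{"diffraction"}}{The object is placed in the aperture plane
#'     and the recorded pattern is the squared modulus of a single Fourier
#'     transform of \eqn{\exp(i(\phi + scale\,W))}, with \eqn{\rho}
#'     normalized at the grid's half-width. Under this construction the
#'     \eqn{\pm A_d} pair of a symmetric object gives mirror-identical
#'     images, so defocus alone produces no contrast inversion, and the
#'     interior contrast sign is controlled by the product
#'     \eqn{A_d \cdot A_s} — the spherical-aberration-gated inversion. The
#'     output is normalized to unit mean.}
#' }
#'
#' @param obj a [phase_object()] with constant height map (the height adds
#'   \code{defocus_per_um * height} to the model's \eqn{A_d}).
#' @param model an [aberration_model()].
#' @param method image-formation construction, see Details.
#' @return Numeric intensity matrix (class \code{"intensity_image"}), all
#'   values non-negative.
#' @export
image_weak_phase_object <- function(obj, model,
                                    method = c("convolution", "diffraction")) {
  method <- match.arg(method)
  h <- unique(as.vector(obj$height_map))
  if (length(h) != 1)
    stop("height map is not constant; use image_inclined_object()",
         call. = FALSE)
  A_d <- model$A_d + model$defocus_per_um * h
  intensity_image(
    image_uniform_defocus(obj$phase_map, model, A_d, method))
}

intensity_image <- function(values) {
  values[values < 0] <- 0   # clip fft round-off
  structure(values, class = c("intensity_image", "matrix", "array"))
}

image_uniform_defocus <- function(phase_map, model, A_d, method) {
  nr <- nrow(phase_map); nc <- ncol(phase_map)
  s <- model_scale(model, method)
  if (method == "convolution") {
    H <- pupil_transfer(model, nr, nc, A_d, s)
    Mod(ifft2(fft2(exp(1i * phase_map)) * H))^2
  } else {
    rho2 <- centred_rho2(nr, nc, min(nr, nc) / 2)
    W <- A_d * rho2 + model$A_s * rho2^2
    I <- Mod(fftshift2(fft2(exp(1i * (phase_map + s * W)))))^2
    I / mean(I)
  }
}

#' Image of an inclined weak phase object
#'
#' Decomposes an object whose height map varies across its footprint into
#' depth bins, images each bin at the defocus amplitude of its mean height
#' (shared spherical aberration), and composites the slice images masked to
#' each slice's footprint. Off-footprint pixels take the mean of the slice
#' images so the defocus halos surrounding the object are retained.
#'
#' @param obj a [phase_object()]; its height map defines the depth bins.
#' @param model an [aberration_model()].
#' @param n_slices number of depth bins (>= 2).
#' @param method image-formation construction, see
#'   [image_weak_phase_object()].
#' @return An intensity image matrix.
#' @export
image_inclined_object <- function(obj, model, n_slices = 7,
                                  method = c("convolution", "diffraction")) {
  method <- match.arg(method)
  if (!is_count(n_slices) || n_slices < 2)
    stop("'n_slices' must be an integer >= 2", call. = FALSE)
  foot <- obj$phase_map != 0
  h <- obj$height_map
  hr <- range(h[foot])
  if (diff(hr) == 0)
    return(image_weak_phase_object(
      phase_object(obj$phase_map, hr[1], obj$pixel_pitch), model, method))
  edges <- seq(hr[1], hr[2], length.out = n_slices + 1)
  # every pixel joins the slice of its (clamped) height, so the halo outside
  # each part of the footprint is rendered at that part's own defocus
  hc <- pmin(pmax(h, hr[1]), hr[2])
  bin <- pmin(findInterval(hc, edges, rightmost.closed = TRUE), n_slices)
  out <- matrix(0, nrow(h), ncol(h))
  for (k in sort(unique(as.vector(bin)))) {
    sel <- bin == k
    infoot <- sel & foot
    A_d <- model$A_d + model$defocus_per_um *
      mean(h[if (any(infoot)) infoot else sel])
    Ik <- image_uniform_defocus(obj$phase_map, model, A_d, method)
    out[sel] <- Ik[sel]
  }
  intensity_image(out)
}

#' Render a spinning-plate image sequence
#'
#' Rotates a thin rectangular plate about its long axis (vertical in the
#' image) and images each pose through the aberrated system. The roll angle
#' convention ties the direction label to the view of an observer looking
#' down the rotation axis from the top of the image: for CCW spin the bright
#' region (the side of the plate behind the focal plane) sweeps from left to
#' right within each half turn, for CW from right to left, and at each half
#' turn it reappears on its starting side.
#'
#' @param obj a [phase_object()] whose non-zero footprint is the unrotated
#'   plate (e.g. [rect_phase_object()]).
#' @param direction \code{"ccw"} or \code{"cw"}.
#' @param n_frames number of frames (>= 3).
#' @param model an [aberration_model()]; \code{model$A_s} should be non-zero
#'   for the panel look, and \code{A_d_max} sets the defocus amplitude at the
#'   plate edge when fully inclined.
#' @param revolutions total rotation rendered over the sequence (default a
#'   half turn).
#' @param A_d_max defocus amplitude at the plate edge at maximum inclination.
#' @param n_slices depth bins per frame.
#' @param alpha0 initial roll angle (radians); frames start just after the
#'   flat pose by default.
#' @return List of intensity images with attribute \code{"roll"} (the roll
#'   angle of each frame, radians).
#' @export
render_spinning_sequence <- function(obj, direction = c("ccw", "cw"),
                                     n_frames = 12, model,
                                     revolutions = 0.5, A_d_max = 0.2,
                                     n_slices = 9, alpha0 = 0.05 * pi) {
  direction <- match.arg(direction)
  if (!is_count(n_frames) || n_frames < 3)
    stop("'n_frames' must be an integer >= 3", call. = FALSE)
  foot <- obj$phase_map != 0
  if (!any(foot)) stop("object footprint is empty", call. = FALSE)
  cols_in <- range(which(colSums(foot) > 0))
  rows_in <- range(which(rowSums(foot) > 0))
  half_w <- (diff(cols_in) + 1) / 2
  cc <- mean(cols_in)
  phase <- max(obj$phase_map)
  sgn <- if (direction == "ccw") 1 else -1
  alphas <- alpha0 + sgn * seq(0, revolutions * 2 * pi, length.out = n_frames)
  nr <- nrow(obj$phase_map); nc <- ncol(obj$phase_map)
  frames <- vector("list", n_frames)
  edges <- seq(-1, 1, length.out = n_slices + 1)
  for (f in seq_len(n_frames)) {
    a <- alphas[f]
    # material coordinate m in [-1, 1] across the plate width; in-plane
    # position m*half_w*cos(a); height sign -m*sin(a) (CCW = roll increasing)
    if (half_w * abs(cos(a)) < 0.5) {
      # edge-on: the projected plate narrows below one pixel
      phi <- matrix(0, nr, nc)
      cc0 <- min(max(1, round(cc)), nc)
      phi[rows_in[1]:rows_in[2], cc0] <- phase
      frames[[f]] <- intensity_image(
        image_uniform_defocus(phi, model, 0, "convolution"))
      next
    }
    out <- matrix(0, nr, nc); halo <- matrix(0, nr, nc)
    filled <- matrix(FALSE, nr, nc)
    for (k in seq_len(n_slices)) {
      mc <- (edges[k] + edges[k + 1]) / 2
      x <- sort(c(edges[k], edges[k + 1]) * half_w * cos(a))
      c0 <- max(1, ceiling(cc + x[1])); c1 <- min(nc, floor(cc + x[2]))
      if (c1 < c0) next
      phi <- matrix(0, nr, nc)
      phi[rows_in[1]:rows_in[2], c0:c1] <- phase
      A_d <- -mc * sin(a) * A_d_max
      Ik <- image_uniform_defocus(phi, model, A_d, "convolution")
      sel <- matrix(FALSE, nr, nc)
      sel[rows_in[1]:rows_in[2], c0:c1] <- TRUE
      out[sel & !filled] <- Ik[sel & !filled]
      filled <- filled | sel
      halo <- halo + Ik / n_slices
    }
    out[!filled] <- halo[!filled]
    frames[[f]] <- intensity_image(out)
  }
  attr(frames, "roll") <- alphas
  frames
}

#' Interior-versus-background contrast statistic
#'
#' Mean intensity over the object footprint eroded by \code{erode} pixels
#' minus the mean over a \code{halo}-pixel annulus outside the footprint.
#' Positive values mean the object interior renders brighter than its
#' surround.
#'
#' @param image intensity matrix.
#' @param footprint logical matrix marking the object's pixels.
#' @param erode erosion depth for the interior (pixels).
#' @param halo width of the exterior annulus (pixels).
#' @return Signed contrast (numeric scalar).
#' @export
contrast_stat <- function(image, footprint, erode = 2, halo = 6) {
  kern_in <- EBImage::makeBrush(2 * erode + 1, shape = "box")
  kern_out <- EBImage::makeBrush(2 * halo + 1, shape = "box")
  interior <- EBImage::erode(footprint * 1, kern_in) > 0.5
  dilated <- EBImage::dilate(footprint * 1, kern_out) > 0.5
  ann <- dilated & !footprint
  mean(image[interior]) - mean(image[ann])
}

# centroid of above-background pixels, weighted by squared excess intensity
bright_centroid_x <- function(image) {
  w <- pmax(image - stats::median(image), 0)^2
  if (sum(w) == 0) return(NA_real_)
  sum(col(image) * w) / sum(w)
}
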