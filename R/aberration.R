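#' Aberration model for a bright-field objective
#'
#' Describes the pupil of the imaging system together with its defocus and
#' primary spherical aberration. The wave aberration across the pupil is
#' \deqn{W(x, y) = A_d \rho^2 + A_s \rho^4,}
#' where \eqn{\rho} is the pupil radius normalized to 1 at the aperture edge,
#' \eqn{A_d} is the defocus amplitude (it changes sign as the object moves
#' through the focused object plane) and \eqn{A_s} the spherical-aberration
#' amplitude, a fixed property of the objective. \eqn{W} multiplies the pupil
#' as \eqn{\exp(i \cdot scale \cdot W)}; the single \code{scale} constant
#' absorbs the wavenumber and the (unknown) physical normalization of the
#' printed coefficients, so only signs and ratios of \eqn{A_d}, \eqn{A_s}
#' carry meaning. Each imaging method has its own calibrated default scale
#' (see [image_weak_phase_object()]).
#'
#' @param A_d defocus amplitude (dimensionless; sign per
#'   [defocus_amplitude_sign()]).
#' @param A_s spherical-aberration amplitude (dimensionless). Its sign
#'   selects which side of the focal plane renders bright; it depends on the
#'   optical design and is therefore configuration, not a constant.
#' @param pupil_radius pupil radius in the units used for the pupil
#'   coordinates handed to [wave_aberration()] (default 1, i.e. coordinates
#'   already normalized).
#' @param pupil_frac radius of the circular aperture as a fraction of the
#'   Nyquist radius of the discrete frequency grid used by the imaging
#'   operators.
#' @param wavelength illumination wavelength in micrometres.
#' @param scale global aberration scale applied as \eqn{\exp(i\,scale\,W)}.
#'   \code{NULL} selects the per-method calibrated default. A negative value
#'   flips the bright/dark contrast convention.
#' @param defocus_per_um conversion from axial offset (micrometres, positive
#'   away from the objective) to defocus amplitude \eqn{A_d}, used when
#'   imaging objects with a height map.
#' @return An object of class \code{"aberration_model"}.
#' @seealso [wave_aberration()], [psf()], [image_weak_phase_object()]
#' @export
aberration_model <- function(A_d = 0, A_s = 0, pupil_radius = 1,
                             pupil_frac = 0.35, wavelength = 0.55,
                             scale = NULL, defocus_per_um = 0.02) {
  stopifnot_scalar(pupil_radius, "pupil_radius")
  stopifnot_scalar(wavelength, "wavelength")
  stopifnot_scalar(pupil_frac, "pupil_frac")
  if (pupil_frac > 1) stop("'pupil_frac' must be <= 1", call. = FALSE)
  stopifnot_scalar(A_d, "A_d", positive = FALSE)
  stopifnot_scalar(A_s, "A_s", positive = FALSE)
  if (!is.null(scale)) stopifnot_scalar(scale, "scale", positive = FALSE)
  structure(
    list(A_d = A_d, A_s = A_s, pupil_radius = pupil_radius,
         pupil_frac = pupil_frac, wavelength = wavelength,
         k = 2 * pi / wavelength, scale = scale,
         defocus_per_um = defocus_per_um),
    class = "aberration_model")
}

#' @export
print.aberration_model <- function(x, ...) {
  cat("Aberration model: A_d =", x$A_d, ", A_s =", x$A_s,
      ", pupil_frac =", x$pupil_frac,
      ", scale =", if (is.null(x$scale)) "(method default)" else x$scale, "\n")
  invisible(x)
}

# calibrated per-method scales (see the methods vignette)
scale_default <- function(method) {
  switch(method, convolution = -25, diffraction = 10000,
         stop("unknown imaging method: ", method, call. = FALSE))
}

model_scale <- function(model, method) model$scale %||% scale_default(method)

#' Wave aberration across the pupil
#'
#' Evaluates \eqn{W = A_d \rho^2 + A_s \rho^4} with
#' \eqn{\rho = \sqrt{x^2 + y^2} / r}, the pupil radius normalized to the
#' aperture edge. \eqn{W(0,0) = 0} for any coefficients.
#'
#' @param x,y pupil-plane coordinates (same units as
#'   \code{model$pupil_radius}); vectors are recycled elementwise.
#' @param model an [aberration_model()].
#' @return Numeric vector of optical-path values.
#' @export
wave_aberration <- function(x, y, model) {
  if (model$pupil_radius == 0)
    stop("invalid aberration model: pupil_radius is 0", call. = FALSE)
  rho2 <- (x^2 + y^2) / model$pupil_radius^2
  model$A_d * rho2 + model$A_s * rho2^2
}

#' Signed defocus amplitude from object, image and focal distances
#'
#' The Gauss lens equation gives \eqn{A_d \propto 1/f - 1/d_i - 1/d_0}:
#' zero when the system is focused, positive when the object is farther from
#' the objective than the focused object plane, negative when nearer.
#'
#' @param d0 object distance (> 0).
#' @param f focal length (> 0).
#' @param di image distance (> 0).
#' @return Signed defocus amplitude (arbitrary units; only the sign and
#'   monotonicity in \code{d0} are meaningful).
#' @export
defocus_amplitude_sign <- function(d0, f, di) {
  stopifnot_scalar(d0, "d0"); stopifnot_scalar(f, "f"); stopifnot_scalar(di, "di")
  1 / f - 1 / di - 1 / d0
}

# binary circular aperture + aberration phase on the fft-ordered frequency grid
pupil_transfer <- function(model, nr, nc, A_d, scale) {
  rho2 <- freq_rho2(nr, nc, model$pupil_frac * min(nr, nc) / 2)
  P <- rho2 <= 1
  W <- A_d * rho2 + model$A_s * rho2^2
  P * exp(1i * scale * W)
}

#' Coherent point spread function
#'
#' Returns the Fourier transform of the circular pupil multiplied by the
#' aberration phase factor, on a centred grid. With \eqn{A_d = A_s = 0} this
#' is the Airy amplitude pattern of the aperture.
#'
#' @param model an [aberration_model()].
#' @param grid_shape integer vector (rows, cols) of the output grid; a single
#'   number gives a square grid.
#' @return Complex matrix; the optical axis is at the grid centre element
#'   (\code{ceiling(n/2) + 1} in each dimension for even n).
#' @export
psf <- function(model, grid_shape = 128) {
  if (length(grid_shape) == 1) grid_shape <- c(grid_shape, grid_shape)
  if (!all(vapply(grid_shape, is_count, logical(1))))
    stop("'grid_shape' must be positive integers", call. = FALSE)
  nr <- grid_shape[1]; nc <- grid_shape[2]
  H <- pupil_transfer(model, nr, nc, model$A_d,
                      model_scale(model, "convolution"))
  fftshift2(fft2(H)) / sqrt(nr * nc)
}
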