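# internal numerics helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

fft2 <- function(m) stats::fft(m)

ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

# swap quadrants so the zero-frequency / optical axis sits at the grid centre
fftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  hr <- ceiling(nr / 2); hc <- ceiling(nc / 2)
  m[c((hr + 1):nr, 1:hr), c((hc + 1):nc, 1:hc)]
}

# squared radial coordinate of the discrete frequency grid, fft ordering,
# normalized so rho = 1 at radius `radius_px` frequency pixels
freq_rho2 <- function(nr, nc, radius_px) {
  fr <- c(0:(ceiling(nr / 2) - 1), -(floor(nr / 2)):-1)
  fc <- c(0:(ceiling(nc / 2) - 1), -(floor(nc / 2)):-1)
  outer(fr^2, fc^2, "+") / radius_px^2
}

# squared radial coordinate over a centred spatial grid, rho = 1 at radius_px
centred_rho2 <- function(nr, nc, radius_px) {
  r <- seq_len(nr) - (nr + 1) / 2
  c <- seq_len(nc) - (nc + 1) / 2
  outer(r^2, c^2, "+") / radius_px^2
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x == round(x) && x > 0

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
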