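#' Validate and construct an image grid
#'
#' An image grid is a plain numeric matrix of gray intensities in
#' \eqn{[0, 1]}, row `i` / column `j` addressing the pixel in image row
#' `i` and column `j`. All package functions that consume images accept
#' any matrix that passes this validator.
#'
#' @param pixels Numeric matrix with finite values in \eqn{[0, 1]}.
#' @return The validated matrix, invisibly classed as `npgtv_image`.
#' @export
image_grid <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image dimensions must be positive", call. = FALSE)
  }
  if (!all(is.finite(pixels))) {
    stop("image intensities must all be finite", call. = FALSE)
  }
  if (min(pixels) < 0 || max(pixels) > 1) {
    stop("image intensities must lie in [0, 1]", call. = FALSE)
  }
  class(pixels) <- c("npgtv_image", class(pixels))
  pixels
}

#' @export
print.npgtv_image <- function(x, ...) {
  cat(sprintf("<npgtv_image> %d x %d, range [%.4f, %.4f]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

# strip the class so arithmetic on pixel matrices stays plain
as_pixels <- function(image) {
  unclass(image)
}

# run `expr` under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L ||
      !is.finite(seed) || seed != round(seed)) {
    stop("a single integer `seed` is required for stochastic generation",
         call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Describe an additive white Gaussian noise model
#'
#' The contamination model is \eqn{u_0 = u + z} with
#' \eqn{z \sim N(0, (\sigma/255)^2)} i.i.d. per pixel: the standard
#' deviation is quoted on the familiar 8-bit gray scale (e.g. 10, 25,
#' 30) and divided by 255 internally to match unit-interval intensities.
#'
#' @param sigma Nonnegative noise standard deviation on the 0-255 scale.
#' @param seed Integer seed controlling the noise realization.
#' @return An object of class `npgtv_noise`.
#' @export
noise_model <- function(sigma, seed) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma < 0) {
    stop("`sigma` must be a single nonnegative number", call. = FALSE)
  }
  if (missing(seed) || is.null(seed)) {
    stop("a `seed` is required: unseeded noise generation is not allowed",
         call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  structure(list(sigma = sigma, seed = as.integer(seed)),
            class = "npgtv_noise")
}

#' @export
print.npgtv_noise <- function(x, ...) {
  cat(sprintf("<npgtv_noise> sigma = %g (8-bit scale, %.5f on [0,1]), seed = %d\n",
              x$sigma, x$sigma / 255, x$seed))
  invisible(x)
}

#' Generate a clean test phantom
#'
#' Seeded phantom images used throughout the test-suite and examples in
#' place of copyrighted benchmark photographs.
#'
#' * `piecewise`: a Voronoi mosaic of `num_regions` constant regions
#'   with distinct, evenly spaced gray levels — the classic
#'   piecewise-constant target that total-variation priors model well.
#' * `ramp`: a smooth diagonal intensity gradient (deterministic).
#' * `texture`: a band-limited pseudo-random texture built from a small
#'   number of oriented sinusoids, rescaled to \eqn{[0, 1]}.
#'
#' @param kind One of `"piecewise"`, `"ramp"`, `"texture"`.
#' @param m,l Image height and width in pixels, both at least 8.
#' @param num_regions Number of constant regions for the piecewise kind
#'   (ignored by the other kinds); at least 1.
#' @param seed Integer seed; identical arguments give bit-identical images.
#' @return An `npgtv_image` matrix of size `m` by `l`.
#' @examples
#' ph <- make_phantom("piecewise", 64, 64, num_regions = 4, seed = 7)
#' length(unique(as.vector(ph)))
#' @export
make_phantom <- function(kind = c("piecewise", "ramp", "texture"),
                         m, l, num_regions = 4L, seed) {
  kind <- match.arg(kind)
  if (!is.numeric(m) || !is.numeric(l) || length(m) != 1L || length(l) != 1L ||
      m != round(m) || l != round(l) || m < 8 || l < 8) {
    stop("`m` and `l` must be integers >= 8", call. = FALSE)
  }
  if (!is.numeric(num_regions) || length(num_regions) != 1L ||
      num_regions != round(num_regions) || num_regions < 1) {
    stop("`num_regions` must be a positive integer", call. = FALSE)
  }
  m <- as.integer(m); l <- as.integer(l)
  num_regions <- as.integer(num_regions)
  px <- with_seed(seed, {
    switch(kind,
      piecewise = phantom_piecewise(m, l, num_regions),
      ramp      = phantom_ramp(m, l),
      texture   = phantom_texture(m, l)
    )
  })
  image_grid(px)
}

phantom_piecewise <- function(m, l, num_regions) {
  if (num_regions == 1L) {
    return(matrix(0.5, m, l))
  }
  # Voronoi mosaic: every seed pixel owns at least itself, so all
  # num_regions levels are realized. Levels sit at the midpoints of
  # equal-width gray bins, away from 0 and 1, so added Gaussian noise
  # is not censored by the [0,1] clip and the additive model stays
  # faithful on every region.
  centers <- sample.int(m * l, num_regions)
  cr <- ((centers - 1L) %% m) + 1L
  cc <- ((centers - 1L) %/% m) + 1L
  levels <- ((seq_len(num_regions) - 0.5) / num_regions)[sample.int(num_regions)]
  rows <- matrix(seq_len(m), m, l)
  cols <- matrix(seq_len(l), m, l, byrow = TRUE)
  d2 <- matrix(0, m * l, num_regions)
  for (k in seq_len(num_regions)) {
    d2[, k] <- (as.vector(rows) - cr[k])^2 + (as.vector(cols) - cc[k])^2
  }
  assign <- max.col(-d2, ties.method = "first")
  matrix(levels[assign], m, l)
}

phantom_ramp <- function(m, l) {
  rows <- matrix(seq_len(m), m, l)
  cols <- matrix(seq_len(l), m, l, byrow = TRUE)
  ((rows - 1) / (m - 1) + (cols - 1) / (l - 1)) / 2
}

phantom_texture <- function(m, l) {
  rows <- matrix(seq_len(m), m, l)
  cols <- matrix(seq_len(l), m, l, byrow = TRUE)
  px <- matrix(0, m, l)
  for (k in 1:4) {
    fr <- stats::runif(1, 1, 5)
    fc <- stats::runif(1, 1, 5)
    ph <- stats::runif(1, 0, 2 * pi)
    amp <- stats::runif(1, 0.5, 1)
    px <- px + amp * sin(2 * pi * (fr * rows / m + fc * cols / l) + ph)
  }
  rng <- range(px)
  if (rng[2] - rng[1] < .Machine$double.eps) {
    matrix(0.5, m, l)
  } else {
    (px - rng[1]) / (rng[2] - rng[1])
  }
}

#' Contaminate an image with additive white Gaussian noise
#'
#' Adds i.i.d. zero-mean Gaussian noise of standard deviation
#' `noise$sigma / 255` (unit intensity scale) to every pixel and clips
#' the result back to \eqn{[0, 1]}. The realization is fully determined
#' by `noise$seed`.
#'
#' @param image An image matrix with intensities in \eqn{[0, 1]}.
#' @param noise A [noise_model()] object.
#' @return An `npgtv_image` of the same dimensions.
#' @export
add_awgn <- function(image, noise) {
  image <- image_grid(as_pixels(image))
  if (!inherits(noise, "npgtv_noise")) {
    stop("`noise` must be created by noise_model()", call. = FALSE)
  }
  if (noise$sigma == 0) {
    return(image)
  }
  z <- with_seed(noise$seed,
                 matrix(stats::rnorm(length(image), 0, noise$sigma / 255),
                        nrow(image), ncol(image)))
  out <- as_pixels(image) + z
  out[out < 0] <- 0
  out[out > 1] <- 1
  image_grid(out)
}
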