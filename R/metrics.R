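#' Peak signal-to-noise ratio
#'
#' Intensities are rescaled to the 0-255 gray range, the mean squared
#' error is taken over all pixels, and
#' \eqn{PSNR = 10 \log_{10}(255^2 / MSE)} in decibels. Identical images
#' give `mse = 0` and an infinite PSNR, reported with the `identical`
#' flag set rather than as an error.
#'
#' @param u,u_hat Reference and test images, same dimensions,
#'   intensities in \eqn{[0, 1]}.
#' @return A list of class `npgtv_quality` with `mse` (8-bit scale),
#'   `psnr_db` and `identical`.
#' @export
psnr <- function(u, u_hat) {
  u <- as_pixels(image_grid(as_pixels(u)))
  u_hat <- as_pixels(image_grid(as_pixels(u_hat)))
  if (!all(dim(u) == dim(u_hat))) {
    stop("images must have identical dimensions", call. = FALSE)
  }
  mse <- mean((255 * u - 255 * u_hat)^2)
  if (mse == 0) {
    out <- list(mse = 0, psnr_db = Inf, identical = TRUE)
  } else {
    out <- list(mse = mse, psnr_db = 10 * log10(255^2 / mse),
                identical = FALSE)
  }
  structure(out, class = "npgtv_quality")
}

#' @export
print.npgtv_quality <- function(x, ...) {
  cat(sprintf("<npgtv_quality> mse = %.4f, psnr = %s dB\n", x$mse,
              if (x$identical) "Inf" else sprintf("%.4f", x$psnr_db)))
  invisible(x)
}

# normalized 1-D Gaussian kernel
gaussian_kernel <- function(size = 11L, sigma = 1.5) {
  half <- (size - 1) / 2
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  g / sum(g)
}

# separable 'valid' convolution of a matrix with a 1-D kernel applied
# along both dimensions
conv2_valid <- function(x, g) {
  L <- length(g)
  m <- nrow(x); l <- ncol(x)
  out1 <- matrix(0, m, l - L + 1L)
  for (t in seq_len(L)) {
    out1 <- out1 + g[t] * x[, t:(t + l - L), drop = FALSE]
  }
  out2 <- matrix(0, m - L + 1L, ncol(out1))
  for (t in seq_len(L)) {
    out2 <- out2 + g[t] * out1[t:(t + m - L), , drop = FALSE]
  }
  out2
}

#' Structural similarity index
#'
#' \deqn{SSIM(u, \hat u) = \frac{(2\mu_u\mu_{\hat u} + c_1)(2\sigma_{u\hat u} + c_2)}
#'   {(\mu_u^2 + \mu_{\hat u}^2 + c_1)(\sigma_u^2 + \sigma_{\hat u}^2 + c_2)}}
#' on the 0-255 scale with the conventional stabilizers
#' \eqn{c_1 = (0.01 \cdot 255)^2}, \eqn{c_2 = (0.03 \cdot 255)^2}.
#' `"global"` mode evaluates the formula once with whole-image means,
#' variances (unbiased) and covariance; `"windowed"` mode averages it
#' over 11x11 Gaussian-weighted windows (sigma 1.5), the usual benchmark
#' convention, and requires both dimensions to be at least 11.
#'
#' @param u,u_hat Images of identical dimensions, intensities in
#'   \eqn{[0, 1]}.
#' @param mode `"windowed"` (default) or `"global"`.
#' @return A scalar in \eqn{[-1, 1]}; exactly 1 for identical images.
#' @export
ssim <- function(u, u_hat, mode = c("windowed", "global")) {
  mode <- match.arg(mode)
  u <- as_pixels(image_grid(as_pixels(u)))
  u_hat <- as_pixels(image_grid(as_pixels(u_hat)))
  if (!all(dim(u) == dim(u_hat))) {
    stop("images must have identical dimensions", call. = FALSE)
  }
  x <- 255 * u
  y <- 255 * u_hat
  c1 <- (0.01 * 255)^2
  c2 <- (0.03 * 255)^2
  if (mode == "global") {
    mx <- mean(x); my <- mean(y)
    vx <- stats::var(as.vector(x)); vy <- stats::var(as.vector(y))
    cxy <- stats::cov(as.vector(x), as.vector(y))
    return(((2 * mx * my + c1) * (2 * cxy + c2)) /
             ((mx^2 + my^2 + c1) * (vx + vy + c2)))
  }
  if (min(dim(x)) < 11L) {
    stop("windowed SSIM needs both dimensions >= 11; use mode = \"global\"",
         call. = FALSE)
  }
  g <- gaussian_kernel(11L, 1.5)
  mx <- conv2_valid(x, g)
  my <- conv2_valid(y, g)
  vx <- conv2_valid(x * x, g) - mx^2
  vy <- conv2_valid(y * y, g) - my^2
  cxy <- conv2_valid(x * y, g) - mx * my
  smap <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  mean(smap)
}

#' Full quality report for a denoising result
#'
#' Convenience wrapper bundling [psnr()] and [ssim()].
#'
#' @param u,u_hat Reference and test images.
#' @param ssim_mode Passed to [ssim()].
#' @return A list with `mse`, `psnr_db`, `ssim`.
#' @export
quality_report <- function(u, u_hat, ssim_mode = "windowed") {
  p <- psnr(u, u_hat)
  list(mse = p$mse, psnr_db = p$psnr_db,
       ssim = ssim(u, u_hat, mode = ssim_mode))
}
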