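# Spectral pre-filtering of training targets and power-spectral-density
# diagnostics. Natural-image ensembles have radial PSD ~ (nx^2+ny^2)^(-1);
# the high-pass weighting C = (nx^2+ny^2)^q rebalances the under-represented
# high band in the targets presented to the high-band network.

# Dimensionless DFT frequencies (cycles per pixel), DC at index 1.
grid_freqs <- function(n) dft_freqs(n, 1)

#' Evaluate the power-law filter transfer function on the grid
#'
#' Returns `C(nx, ny) = (nx^2 + ny^2)^q` on the unshifted DFT grid in
#' dimensionless grid cycles, normalized to unit maximum so filtered images
#' keep a comparable dynamic range across exponents. The DC element is set
#' to 0 (`dc_policy = "zero"`, removing the mean) or to 1 (`"keep_mean"`).
#' For `q = 0` the filter is the identity.
#'
#' @param filter A [spectral_filter()].
#' @param n Grid side length.
#' @return A real `n x n` matrix with values in `[0, 1]`, DC at `[1, 1]`.
#' @export
filter_transfer <- function(filter, n) {
  if (!inherits(filter, "spectral_filter"))
    stop("`filter` must be a spectral_filter", call. = FALSE)
  n <- as.integer(n)
  nu <- grid_freqs(n)
  nu2 <- outer(nu^2, nu^2, `+`)
  if (filter$q == 0) {
    cc <- matrix(1, n, n)
  } else {
    cc <- nu2^filter$q
    cc[1L, 1L] <- 0
    cc <- cc / max(cc)
  }
  cc[1L, 1L] <- switch(filter$dc_policy, zero = if (filter$q == 0) 1 else 0,
                       keep_mean = 1)
  cc
}

#' Apply a spectral filter to an image
#'
#' Computes `IFFT( FFT(x) * C )` with the transfer function of
#' [filter_transfer()] and discards the (numerically negligible) imaginary
#' residue. With `dc_policy = "zero"` and `q > 0` the result has zero
#' spatial mean.
#'
#' @param image Real matrix.
#' @param filter A [spectral_filter()].
#' @return A real matrix, same shape as `image`.
#' @export
apply_filter <- function(image, filter) {
  assert_image(image, "image")
  n <- nrow(image)
  if (ncol(image) != n) stop("`image` must be square", call. = FALSE)
  cc <- filter_transfer(filter, n)
  Re(stats::fft(stats::fft(image) * cc, inverse = TRUE)) / n^2
}

# Averaged 2D periodogram |FFT(f)|^2 over a list of images (DC at [1,1]).
# Per-image mean removal is the default so the DC spike does not dominate.
psd2d <- function(images, remove_mean = TRUE) {
  if (is.matrix(images)) images <- list(images)
  if (length(images) == 0L) stop("need at least one image", call. = FALSE)
  n <- nrow(images[[1L]])
  acc <- matrix(0, n, ncol(images[[1L]]))
  for (im in images) {
    assert_image(im, "image")
    if (!all(dim(im) == dim(acc))) stop("images must share a common shape", call. = FALSE)
    if (remove_mean) im <- im - mean(im)
    acc <- acc + Mod(stats::fft(im))^2
  }
  acc / length(images)
}

# fftshift for matrices: move DC to the centre.
fftshift2 <- function(x) {
  n <- nrow(x); m <- ncol(x)
  x[c((n %/% 2L + 1L):n, 1L:(n %/% 2L)), c((m %/% 2L + 1L):m, 1L:(m %/% 2L))]
}

#' Average power-spectral-density cross-section of an image set
#'
#' Averages the 2D periodogram over the images and reduces it to a 1D
#' profile: either the centered diagonal cross-section of the shifted 2D
#' PSD (positive-frequency half), or a radially binned average. Frequencies
#' are reported in cycles per pixel (radial frequency for both cuts).
#'
#' @param images A matrix or list of same-shaped square matrices.
#' @param cut `"diagonal"` or `"radial"`.
#' @param remove_mean Remove each image's spatial mean first (default TRUE).
#' @param normalize Scale the profile to unit peak (default TRUE).
#' @return A list of class `psd_profile` with `freqs`, `power`, `cut`,
#'   `n_images`.
#' @export
psd_profile <- function(images, cut = c("diagonal", "radial"),
                        remove_mean = TRUE, normalize = TRUE) {
  cut <- match.arg(cut)
  if (is.matrix(images)) images <- list(images)
  p2 <- psd2d(images, remove_mean = remove_mean)
  n <- nrow(p2)
  if (cut == "diagonal") {
    ps <- fftshift2(p2)
    centre <- n %/% 2L + 1L                     # DC lands here after the shift
    idx <- centre:n
    power <- ps[cbind(idx, idx)]
    freqs <- sqrt(2) * (idx - centre) / n       # radial frequency along the diagonal
  } else {
    nu <- grid_freqs(n)
    r <- sqrt(outer(nu^2, nu^2, `+`))           # cycles/pixel
    k <- round(r * n)                           # integer radial bin
    kmax <- n %/% 2L
    keep <- k <= kmax
    power <- as.vector(tapply(p2[keep], k[keep], mean))
    freqs <- sort(unique(k[keep])) / n
  }
  if (normalize && max(power) > 0) power <- power / max(power)
  structure(list(freqs = freqs, power = power, cut = cut,
                 n_images = length(images)),
            class = "psd_profile")
}

#' Log-log slope of a radial PSD profile
#'
#' Least-squares slope of `log10(power)` against `log10(freq)` over a
#' frequency window, the standard diagnostic for power-law spectra (slope
#' -2a for an ensemble with radial PSD exponent a). The default window is
#' the central decade `[2/n, 20/n]` expressed through the profile's own
#' frequency axis.
#'
#' @param profile A `psd_profile` (radial cut recommended).
#' @param fmin,fmax Frequency window in cycles/pixel; defaults to the
#'   central decade starting at the second radial bin.
#' @return The fitted slope (a single number).
#' @export
psd_loglog_slope <- function(profile, fmin = NULL, fmax = NULL) {
  stopifnot(inherits(profile, "psd_profile"))
  f <- profile$freqs; p <- profile$power
  pos <- f > 0 & p > 0
  f <- f[pos]; p <- p[pos]
  if (is.null(fmin)) fmin <- min(f[f > min(f) * 1.5])   # skip the first bin
  if (is.null(fmax)) fmax <- min(10 * fmin, 0.45)
  keep <- f >= fmin & f <= fmax
  if (sum(keep) < 3L) stop("too few frequency bins in the fit window", call. = FALSE)
  stats::coef(stats::lm(log10(p[keep]) ~ log10(f[keep])))[[2L]]
}
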