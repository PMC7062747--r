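# Coherent defocused-intensity forward model: a thin pure-phase object
# exp(i f) illuminated by a unit plane wave, propagated a distance z by the
# paraxial (Fresnel) operator evaluated in the spatial-frequency domain, and
# measured as intensity with Poisson shot noise at low photon flux.

# DFT frequencies in cycles per metre for an n-point grid of pitch `pitch`,
# DC at index 1 (unshifted layout, as produced by fft()).
dft_freqs <- function(n, pitch) {
  k <- c(0:(n %/% 2L - 1L), (-(n - n %/% 2L)):(-1L))
  k / (n * pitch)
}

#' Fresnel transfer function on the discrete frequency grid
#'
#' Evaluates `exp(-i * pi * lambda * z * (nx^2 + ny^2))` on the unshifted DFT
#' frequency grid of the (optionally zero-padded) array, i.e. the exact
#' frequency-domain form of paraxial free-space propagation over the signed
#' defocus distance. `direction = -1` realizes the inverse operator via
#' `z -> -z`. If the configuration carries a Fourier-plane aperture, all
#' frequencies with radius above the stop are zeroed.
#'
#' @param config An [optical_config()].
#' @param direction `+1` (forward) or `-1` (backward propagation).
#' @param n Grid size to evaluate on; defaults to
#'   `config$grid_n * config$pad_factor`.
#' @return A complex `n x n` matrix, DC at element `[1, 1]`.
#' @export
transfer_function <- function(config, direction = 1, n = NULL) {
  if (!inherits(config, "optical_config"))
    stop("`config` must be an optical_config", call. = FALSE)
  if (!direction %in% c(-1, 1))
    stop("`direction` must be +1 or -1", call. = FALSE)
  if (is.null(n)) n <- config$grid_n * config$pad_factor
  n <- as.integer(n)
  if (n < 2L) stop("degenerate grid", call. = FALSE)
  nu <- dft_freqs(n, config$pixel_pitch)
  nu2 <- outer(nu^2, nu^2, `+`)          # nx^2 + ny^2, cycles^2/m^2
  h <- exp(-1i * pi * config$wavelength * (direction * config$defocus_z) * nu2)
  if (!is.null(config$aperture_na_cycles))
    h[sqrt(nu2) > config$aperture_na_cycles] <- 0 + 0i
  h
}

#' Propagate a complex field by the discrete Fresnel operator
#'
#' Computes `IFFT( FFT(psi) * H )` with the transfer function of
#' [transfer_function()]. With `pad_factor > 1` the field is embedded
#' centrally in a zero-padded array before the transform and cropped back
#' afterwards (linear-convolution behaviour); with `pad_factor = 1` the
#' operator is exactly unitary on the periodic grid.
#'
#' @param field A complex (or real) `grid_n x grid_n` matrix.
#' @param config An [optical_config()].
#' @param direction `+1` forward, `-1` backward.
#' @return A complex matrix of the same size as `field`.
#' @export
propagate <- function(field, config, direction = 1) {
  if (!is.matrix(field)) stop("`field` must be a matrix", call. = FALSE)
  n <- config$grid_n
  if (nrow(field) != n || ncol(field) != n)
    stop("field shape does not match config$grid_n", call. = FALSE)
  if (any(!is.finite(Re(field))) || any(!is.finite(Im(field))))
    stop("`field` contains non-finite values", call. = FALSE)
  np <- n * config$pad_factor
  if (np > n) {
    big <- matrix(0 + 0i, np, np)
    o <- (np - n) %/% 2L
    big[o + seq_len(n), o + seq_len(n)] <- field
  } else {
    big <- field
  }
  h <- transfer_function(config, direction, n = np)
  out <- stats::fft(stats::fft(big) * h, inverse = TRUE) / np^2
  if (np > n) {
    o <- (np - n) %/% 2L
    out <- out[o + seq_len(n), o + seq_len(n)]
  }
  out
}

#' Noiseless defocused intensity of a thin phase object
#'
#' For a phase map `f` (radians) under unit plane-wave illumination, forms
#' the pure-phase object field `exp(i f)` and returns the propagated
#' intensity `|F_z exp(i f)|^2`: the noiseless raw image.
#'
#' @param f Real `grid_n x grid_n` phase matrix in radians.
#' @param config An [optical_config()].
#' @return A nonnegative real matrix of normalized intensity.
#' @export
forward_intensity <- function(f, config) {
  assert_image(f, "f")
  psi <- propagate(exp(1i * f), config, direction = 1)
  Mod(psi)^2
}

#' Apply photon-limited noise to a noiseless intensity image
#'
#' Renormalizes the image so its spatial mean equals the photon flux
#' `photons_p`, draws an independent Poisson count at each pixel, adds
#' Gaussian read noise of sd `gaussian_sigma`, and clips negatives to zero
#' (so that downstream square roots are defined). Draws are deterministic
#' for a given `noise$seed`.
#'
#' @param g0 Nonnegative real matrix (noiseless intensity).
#' @param noise A [noise_spec()].
#' @return A nonnegative real matrix of noisy counts, with attribute
#'   `flux_p` recording the photon flux.
#' @export
apply_noise <- function(g0, noise) {
  assert_image(g0, "g0", nonneg = TRUE)
  if (!inherits(noise, "noise_spec"))
    stop("`noise` must be a noise_spec", call. = FALSE)
  m <- mean(g0)
  if (m <= 0) stop("mean(g0) is zero: normalization undefined", call. = FALSE)
  lambda <- noise$photons_p * g0 / m
  g <- with_local_seed(noise$seed, {
    counts <- stats::rpois(length(lambda), lambda)
    if (noise$gaussian_sigma > 0)
      counts <- counts + stats::rnorm(length(lambda), 0, noise$gaussian_sigma)
    counts
  })
  g <- matrix(pmax(g, 0), nrow(g0), ncol(g0))
  attr(g, "flux_p") <- noise$photons_p
  g
}

# Run `expr` under a given RNG seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
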