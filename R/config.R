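#' Optical configuration for the defocused imaging geometry
#'
#' Bundles the physical parameters that define the coherent forward operator:
#' illumination wavelength, signed defocus distance between the object
#' (conjugate) plane and the detector, the sampling pitch of the square
#' computational grid, and the grid size. An optional circular stop in the
#' Fourier plane band-limits the field; `pad_factor` controls zero-padding
#' during propagation (1 = the exact discrete operator on the periodic grid).
#'
#' Defaults follow a HeNe bench geometry: 632.8 nm illumination, 400 mm
#' defocus, a 256 x 256 phase modulator with 36 micron pixels.
#'
#' @param wavelength Illumination wavelength in metres (> 0).
#' @param defocus_z Signed defocus distance in metres.
#' @param pixel_pitch Grid sampling pitch in metres (> 0).
#' @param grid_n Grid side length in pixels; even, >= 4.
#' @param aperture_na_cycles Optional radius (cycles/m) of a circular
#'   Fourier-plane stop; `NULL` disables it.
#' @param pad_factor Integer zero-padding multiplier (>= 1) applied before
#'   propagation; the result is cropped back to `grid_n`.
#' @return An object of class `optical_config`.
#' @examples
#' cfg <- optical_config(grid_n = 64)
#' cfg$wavelength
#' @export
optical_config <- function(wavelength = 632.8e-9,
                           defocus_z = 0.4,
                           pixel_pitch = 36e-6,
                           grid_n = 256L,
                           aperture_na_cycles = NULL,
                           pad_factor = 1L) {
  stopifnot(is.numeric(wavelength), length(wavelength) == 1L, wavelength > 0)
  stopifnot(is.numeric(defocus_z), length(defocus_z) == 1L, is.finite(defocus_z))
  stopifnot(is.numeric(pixel_pitch), length(pixel_pitch) == 1L, pixel_pitch > 0)
  grid_n <- as.integer(grid_n)
  if (length(grid_n) != 1L || is.na(grid_n) || grid_n < 4L || grid_n %% 2L != 0L)
    stop("`grid_n` must be a single even integer >= 4", call. = FALSE)
  pad_factor <- as.integer(pad_factor)
  if (length(pad_factor) != 1L || is.na(pad_factor) || pad_factor < 1L)
    stop("`pad_factor` must be a single integer >= 1", call. = FALSE)
  if (!is.null(aperture_na_cycles)) {
    stopifnot(is.numeric(aperture_na_cycles), length(aperture_na_cycles) == 1L,
              aperture_na_cycles > 0)
  }
  structure(
    list(wavelength = wavelength, defocus_z = defocus_z,
         pixel_pitch = pixel_pitch, grid_n = grid_n,
         aperture_na_cycles = aperture_na_cycles, pad_factor = pad_factor),
    class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat(sprintf("  wavelength : %.4g m\n", x$wavelength))
  cat(sprintf("  defocus z  : %.4g m\n", x$defocus_z))
  cat(sprintf("  pixel pitch: %.4g m\n", x$pixel_pitch))
  cat(sprintf("  grid       : %d x %d (pad_factor %d)\n",
              x$grid_n, x$grid_n, x$pad_factor))
  if (!is.null(x$aperture_na_cycles))
    cat(sprintf("  aperture   : %.4g cycles/m\n", x$aperture_na_cycles))
  invisible(x)
}

#' Photon-limited noise specification
#'
#' Parameterizes the measurement noise: Poisson shot noise at mean photon
#' flux `photons_p` per pixel per frame (the image is renormalized so its
#' spatial mean carries that flux) plus additive zero-mean Gaussian read
#' noise of standard deviation `gaussian_sigma` counts.
#'
#' @param photons_p Mean detected photons per pixel per frame (> 0).
#' @param gaussian_sigma Read-noise standard deviation in counts (>= 0).
#' @param seed Integer RNG seed making draws reproducible.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(photons_p = 1, gaussian_sigma = 0, seed = 1L) {
  stopifnot(is.numeric(photons_p), length(photons_p) == 1L)
  if (!is.finite(photons_p) || photons_p <= 0)
    stop("`photons_p` must be > 0", call. = FALSE)
  stopifnot(is.numeric(gaussian_sigma), length(gaussian_sigma) == 1L,
            gaussian_sigma >= 0)
  structure(list(photons_p = photons_p, gaussian_sigma = gaussian_sigma,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Power-law spectral pre-filter
#'
#' The radially symmetric transfer function `C(nx, ny) = (nx^2 + ny^2)^q`
#' used to high-pass-weight training targets. `q = 0.5` exactly compensates
#' an inverse-quadratic object power spectrum; `q = 0` is the identity.
#' The DC (zero-frequency) value is not defined by the power law for q > 0;
#' `dc_policy` chooses between removing the mean (`"zero"`) or passing it
#' through untouched (`"keep_mean"`).
#'
#' @param q Power-law exponent (>= 0).
#' @param dc_policy One of `"zero"` or `"keep_mean"`.
#' @return An object of class `spectral_filter`.
#' @export
spectral_filter <- function(q = 0.5, dc_policy = c("zero", "keep_mean")) {
  stopifnot(is.numeric(q), length(q) == 1L, is.finite(q), q >= 0)
  dc_policy <- match.arg(dc_policy)
  structure(list(q = q, dc_policy = dc_policy), class = "spectral_filter")
}

#' Specification of a synthetic phase-object ensemble
#'
#' Describes a seeded ensemble of random phase maps whose ensemble-average
#' power spectral density follows the power law `S(nu) ~ (nx^2+ny^2)^(-a)`;
#' `psd_exponent_a = 1` reproduces the inverse-quadratic spectrum of natural
#' images. Each object is affinely rescaled to `[phase_min, phase_max]`
#' radians, emulating projection of a grayscale image onto a phase modulator.
#'
#' @param n_objects Number of objects (>= 1).
#' @param grid_n Grid side length in pixels.
#' @param psd_exponent_a Radial PSD decay exponent a (> 0).
#' @param phase_min,phase_max Phase range in radians (`phase_max > phase_min`).
#' @param seed Integer RNG seed.
#' @return An object of class `object_ensemble_spec`.
#' @export
object_ensemble_spec <- function(n_objects, grid_n = 64L, psd_exponent_a = 1,
                                 phase_min = 0, phase_max = pi, seed = 1L) {
  n_objects <- as.integer(n_objects)
  stopifnot(length(n_objects) == 1L, n_objects >= 1L)
  grid_n <- as.integer(grid_n)
  stopifnot(length(grid_n) == 1L, grid_n >= 4L)
  if (!is.numeric(psd_exponent_a) || psd_exponent_a <= 0)
    stop("`psd_exponent_a` must be > 0", call. = FALSE)
  stopifnot(phase_max > phase_min)
  structure(list(n_objects = n_objects, grid_n = grid_n,
                 psd_exponent_a = psd_exponent_a,
                 phase_min = phase_min, phase_max = phase_max,
                 seed = as.integer(seed)),
            class = "object_ensemble_spec")
}

#' U-net architecture specification
#'
#' @param depth Number of resolution levels below the input level (>= 1).
#' @param base_channels Feature channels at the top level (>= 1); doubled at
#'   each downsampling.
#' @param residual Add the (first channel of the) input to the output, so the
#'   body learns a correction.
#' @param capacity_multiplier Multiplies `base_channels` (capacity-control
#'   experiments; e.g. 3 for a single net matching the capacity of the
#'   low + high + synthesizer triple).
#' @param input_channels Number of input channels (1 for the band nets, 2 for
#'   the synthesizer).
#' @param bypass_channel Optional index of an input channel that is routed
#'   around the network body and concatenated, unmodified, with the body
#'   features at the final convolution (the synthesizer's high-band bypass).
#' @param seed Integer seed for weight initialization.
#' @details Channel widths are scaled by `sqrt(capacity_multiplier)`, so the
#'   trainable parameter count scales approximately linearly with the
#'   multiplier (a multiplier of 3 matches the summed capacity of three
#'   unit-multiplier networks).
#' @return An object of class `unet_spec`.
#' @export
unet_spec <- function(depth = 2L, base_channels = 8L, residual = TRUE,
                      capacity_multiplier = 1, input_channels = 1L,
                      bypass_channel = NULL, seed = 1L) {
  depth <- as.integer(depth); base_channels <- as.integer(base_channels)
  stopifnot(depth >= 1L, base_channels >= 1L, capacity_multiplier >= 1)
  if (!is.null(bypass_channel)) {
    bypass_channel <- as.integer(bypass_channel)
    stopifnot(bypass_channel >= 1L, bypass_channel <= input_channels)
  }
  structure(list(depth = depth, base_channels = base_channels,
                 residual = isTRUE(residual),
                 capacity_multiplier = capacity_multiplier,
                 input_channels = as.integer(input_channels),
                 bypass_channel = bypass_channel,
                 seed = as.integer(seed)),
            class = "unet_spec")
}

#' Training configuration for the LS networks
#'
#' @param scheme `"approximant"` feeds the single-iteration Gerchberg-Saxton
#'   estimate to the networks; `"end_to_end"` feeds the raw intensity.
#' @param epochs Number of passes over the training split (>= 1).
#' @param batch_size Minibatch size (>= 1).
#' @param learning_rate Adam step size.
#' @param q Spectral-filter exponent used for the high-band targets.
#' @param seed Integer seed for data order and weight initialization.
#' @return An object of class `train_config`.
#' @export
train_config <- function(scheme = c("approximant", "end_to_end"),
                         epochs = 20L, batch_size = 50L,
                         learning_rate = 1e-3, q = 0.5, seed = 1L) {
  scheme <- match.arg(scheme)
  epochs <- as.integer(epochs); batch_size <- as.integer(batch_size)
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0, q >= 0)
  structure(list(scheme = scheme, epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, q = q, seed = as.integer(seed)),
            class = "train_config")
}

# shared validation helper: a finite numeric matrix
assert_image <- function(x, name = deparse(substitute(x)), nonneg = FALSE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  if (any(!is.finite(x)))
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  if (nonneg && any(x < 0))
    stop(sprintf("`%s` must be nonnegative", name), call. = FALSE)
  invisible(x)
}
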