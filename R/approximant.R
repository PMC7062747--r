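# Gerchberg-Saxton alternating projections for direct phase retrieval, and
# the single-iteration approximant used as the network input. The iterate
# enforces the measured modulus sqrt(g) in the detector plane and the
# unit-modulus (pure phase) constraint in the object plane.

#' One Gerchberg-Saxton iterate
#'
#' Maps the current phase estimate `f_k` to
#' `arg( F_z^{-1}( sqrt(g) * exp(i arg(F_z exp(i f_k))) ) )`:
#' propagate the unit-modulus object field forward, impose the measured
#' modulus, propagate back, and keep the phase. The result is the principal
#' value in `(-pi, pi]`.
#'
#' @param f_k Real phase matrix (radians), current estimate.
#' @param g Nonnegative measured intensity matrix.
#' @param config An [optical_config()].
#' @return A phase matrix in `(-pi, pi]`.
#' @export
gs_iterate <- function(f_k, g, config) {
  assert_image(f_k, "f_k")
  assert_image(g, "g")
  if (any(g < 0)) stop("`g` has negative entries; clip before calling", call. = FALSE)
  det_field <- propagate(exp(1i * f_k), config, direction = 1)
  corrected <- sqrt(g) * exp(1i * Arg(det_field))
  Arg(propagate(corrected, config, direction = -1))
}

# RMS mismatch between the measured modulus and the modulus of the
# propagated estimate: the residual tracked across GS iterations.
gs_residual <- function(f_k, g, config) {
  det_field <- propagate(exp(1i * f_k), config, direction = 1)
  sqrt(mean((sqrt(g) - Mod(det_field))^2))
}

#' Single-iteration Gerchberg-Saxton approximant
#'
#' The physics-based rough inverse fed to the reconstruction networks: one
#' GS iterate started from the uniform unit field (`f = 0`), i.e.
#' `arg( F_z^{-1}( sqrt(g) * exp(i arg(F_z 1)) ) )` evaluated on the finite
#' frame. Cheap, deterministic, and under strong shot noise of very poor
#' visual quality -- which is exactly the input regime the LS networks are
#' trained for.
#'
#' @param g Nonnegative measured intensity matrix.
#' @param config An [optical_config()].
#' @return A phase matrix in `(-pi, pi]`.
#' @export
approximant <- function(g, config) {
  gs_iterate(matrix(0, nrow(g), ncol(g)), g, config)
}

#' Run several Gerchberg-Saxton iterations
#'
#' Applies [gs_iterate()] repeatedly from `init`, recording the RMS
#' amplitude-mismatch residual before the first and after every iteration.
#' Provided for comparison studies against the single-iteration approximant.
#'
#' @param g Nonnegative measured intensity matrix.
#' @param config An [optical_config()].
#' @param iterations Number of iterations (>= 1).
#' @param init Initial phase matrix; defaults to zeros.
#' @return A list of class `gs_state` with elements `phase_estimate` and
#'   `residual_history` (length `iterations + 1`; element 1 is the residual
#'   of `init`).
#' @export
gs_run <- function(g, config, iterations, init = NULL) {
  iterations <- as.integer(iterations)
  stopifnot(iterations >= 1L)
  if (is.null(init)) init <- matrix(0, nrow(g), ncol(g))
  assert_image(init, "init")
  f <- init
  res <- numeric(iterations + 1L)
  res[1L] <- gs_residual(f, g, config)
  for (k in seq_len(iterations)) {
    f <- gs_iterate(f, g, config)
    res[k + 1L] <- gs_residual(f, g, config)
  }
  structure(list(phase_estimate = f, residual_history = res),
            class = "gs_state")
}
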