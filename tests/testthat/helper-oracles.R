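# Independent oracles and tiny fixtures shared across tests.

# Explicit O(N^4) double-sum DFT implementation of frequency-domain Fresnel
# propagation, written without reference to the FFT path.
dft_propagate_oracle <- function(field, cfg, direction = 1) {
  n <- nrow(field)
  ks <- c(0:(n %/% 2 - 1), (-(n %/% 2)):(-1)) / (n * cfg$pixel_pitch)
  fm <- matrix(0 + 0i, n, n)
  for (u in seq_len(n)) {
    for (v in seq_len(n)) {
      s <- 0 + 0i
      for (x in seq_len(n)) {
        for (y in seq_len(n)) {
          s <- s + field[x, y] *
            exp(-2i * pi * ((x - 1) * (u - 1) + (y - 1) * (v - 1)) / n)
        }
      }
      fm[u, v] <- s
    }
  }
  fm <- fm * exp(-1i * pi * cfg$wavelength * direction * cfg$defocus_z *
                   outer(ks^2, ks^2, `+`))
  out <- matrix(0 + 0i, n, n)
  for (x in seq_len(n)) {
    for (y in seq_len(n)) {
      s <- 0 + 0i
      for (u in seq_len(n)) {
        for (v in seq_len(n)) {
          s <- s + fm[u, v] *
            exp(2i * pi * ((x - 1) * (u - 1) + (y - 1) * (v - 1)) / n)
        }
      }
      out[x, y] <- s / n^2
    }
  }
  out
}

# A small weak-phase object plus its noiseless measurement.
weak_object_fixture <- function(n = 32L, phase_max = 0.5, seed = 3L) {
  cfg <- optical_config(grid_n = n)
  f <- generate_objects(object_ensemble_spec(1L, n, phase_min = 0,
                                             phase_max = phase_max,
                                             seed = seed))[[1L]]
  list(f = f, g0 = forward_intensity(f, cfg), cfg = cfg)
}

# A tiny trained LS bundle for interface-level tests (cached per session).
tiny_bundle_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    dir <- file.path(tempdir(), "lsphase-tiny-ds")
    if (!file.exists(file.path(dir, "manifest.yaml"))) {
      make_dataset(object_ensemble_spec(30L, 16L, seed = 5L),
                   optical_config(grid_n = 16L),
                   noise_spec(1, seed = 5L), spectral_filter(0.5), dir,
                   split_ratios = c(train = 20, validation = 5, test = 5))
    }
    man <- load_manifest(dir)
    us <- unet_spec(depth = 1L, base_channels = 4L, seed = 9L)
    tc <- train_config(epochs = 3L, batch_size = 10L, q = 0.5, seed = 9L)
    net_l <- train_dnn_l(man, us, tc)
    us_h <- us; us_h$seed <- 10L
    net_h <- train_dnn_h(man, us_h, tc)
    us_s <- us; us_s$seed <- 11L
    net_s <- train_dnn_s(man, net_l, net_h, us_s, tc)
    cache <<- list(manifest = man,
                   bundle = ls_bundle(net_l, net_h, net_s, q = 0.5,
                                      scheme = "approximant"))
    cache
  }
})
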