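test_that("generator ensembles follow the requested power law", {
  for (a in c(0.5, 1, 1.5)) {
    objs <- generate_objects(object_ensemble_spec(200L, 64L,
                                                  psd_exponent_a = a,
                                                  seed = 11L))
    slope <- psd_loglog_slope(psd_profile(objs, cut = "radial",
                                          normalize = FALSE))
    expect_lt(abs(slope - (-2 * a)), 0.3)
  }
})

test_that("generation is deterministic and respects the phase range", {
  spec <- object_ensemble_spec(5L, 32L, phase_min = -0.25, phase_max = 1.75,
                               seed = 13L)
  a <- generate_objects(spec)
  b <- generate_objects(spec)
  expect_identical(a, b)
  for (f in a) {
    expect_gte(min(f), -0.25)
    expect_lte(max(f), 1.75)
  }
})

test_that("split sizes follow largest-remainder rounding", {
  s <- lsphase:::split_sizes(22L)
  expect_identical(s, c(train = 20L, validation = 1L, test = 1L))
  expect_identical(sum(lsphase:::split_sizes(1234L)), 1234L)
  s2 <- lsphase:::split_sizes(10450L)
  expect_identical(s2, c(train = 9500L, validation = 450L, test = 500L))
})

test_that("dataset replay is bit-exact and noise is isolated", {
  spec <- object_ensemble_spec(6L, 16L, seed = 21L)
  cfg <- optical_config(grid_n = 16L)
  flt <- spectral_filter(0.5)
  d1 <- file.path(tempdir(), "ds-rep-1")
  d2 <- file.path(tempdir(), "ds-rep-2")
  unlink(c(d1, d2), recursive = TRUE)
  make_dataset(spec, cfg, noise_spec(1, seed = 21L), flt, d1)
  make_dataset(spec, cfg, noise_spec(1, seed = 21L), flt, d2)
  for (fn in setdiff(list.files(d1), "manifest.yaml")) {
    expect_identical(unname(tools::md5sum(file.path(d1, fn))),
                     unname(tools::md5sum(file.path(d2, fn))),
                     label = fn)
  }
  # different flux: same objects, different measurements
  d3 <- file.path(tempdir(), "ds-rep-3")
  unlink(d3, recursive = TRUE)
  make_dataset(spec, cfg, noise_spec(10, seed = 21L), flt, d3)
  expect_identical(unname(tools::md5sum(file.path(d1, "obj00001_f.tsv"))),
                   unname(tools::md5sum(file.path(d3, "obj00001_f.tsv"))))
  g1 <- read_phase_array(file.path(d1, "obj00001_g.tsv"))
  g3 <- read_phase_array(file.path(d3, "obj00001_g.tsv"))
  expect_false(identical(g1, g3))
})

test_that("manifest loading and split access round-trip", {
  spec <- object_ensemble_spec(6L, 16L, seed = 22L)
  dir <- file.path(tempdir(), "ds-man")
  unlink(dir, recursive = TRUE)
  m1 <- make_dataset(spec, optical_config(grid_n = 16L), noise_spec(1, seed = 1L),
                     spectral_filter(0.5), dir)
  m2 <- load_manifest(dir)
  expect_equal(m1$split_sizes, m2$split_sizes)
  tr <- load_split(m2, "train", fields = c("f", "g"))
  expect_length(tr$f, m2$split_sizes$train)
  expect_true(all(vapply(tr$g, function(g) all(g >= 0), TRUE)))
})
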