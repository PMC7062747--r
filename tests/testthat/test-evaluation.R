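test_that("PCC identities hold", {
  set.seed(51)
  a <- matrix(rnorm(64), 8L)
  expect_equal(pcc(a, a), 1, tolerance = 1e-12)
  expect_equal(pcc(a, 2 * a + 5), 1, tolerance = 1e-12)
  # hand-evaluated zero-correlation pattern: cross products cancel
  x <- matrix(c(1, -1, -1, 1), 2L)
  y <- matrix(c(1, -1, 1, -1), 2L)
  expect_equal(pcc(x, y), 0)
  b <- matrix(rnorm(64), 8L)
  expect_equal(pcc(a, b), pcc(b, a), tolerance = 1e-12)
  expect_true(abs(pcc(a, b)) <= 1)
  expect_error(pcc(a, matrix(3, 8L, 8L)), "constant")
})

test_that("PSNR follows its closed form", {
  a <- matrix(runif(64), 8L)
  expect_identical(psnr(a, a, 1), Inf)
  expect_equal(psnr(a, a + 1, 1), 0)                 # MSE = data_range^2
  expect_equal(psnr(a, a + 0.25, 2), 10 * log10(4 / 0.0625))
  # constant shifts of both images leave every metric unchanged
  expect_equal(psnr(a + 3, a + 3.25, 2), psnr(a, a + 0.25, 2))
})

test_that("SSIM matches the independent reference implementation", {
  # frozen oracle: scikit-image structural_similarity on these seeded
  # matrices (gaussian weights, sigma 1.5, no sample-covariance correction)
  reference <- c(0.9449440308, 0.7939552881, 0.6159043728, 0.5012053388,
                 0.3696389560)
  set.seed(4242)
  for (i in 1:5) {
    a <- matrix(runif(32 * 32), 32L)
    b <- a + matrix(rnorm(32 * 32, 0, 0.1 * i), 32L)
    expect_equal(ssim(a, b, data_range = 1), reference[i], tolerance = 1e-6)
  }
  expect_equal(ssim(a, a, data_range = 1), 1, tolerance = 1e-12)
  expect_lt(ssim(a, 1 - a, data_range = 1), 1)
  expect_error(ssim(matrix(0, 8L, 8L), matrix(0, 8L, 8L), 1), "window")
})

test_that("evaluate_bundle tabulates every estimator against the truth", {
  fx <- tiny_bundle_fixture()
  mr <- evaluate_bundle(fx$bundle, fx$manifest)
  expect_s3_class(mr, "metrics_record")
  expect_identical(sort(mr$summary$estimator),
                   sort(c("approximant", "dnn_l", "dnn_s")))
  expect_identical(nrow(mr$per_image), 3L * mr$n_images)
  expect_true(all(abs(mr$per_image$pcc) <= 1))
  expect_true(all(mr$per_image$ssim <= 1))
  expect_equal(mr$flux_p, 1)
  expect_equal(mr$q, 0.5)
  # self-comparison sanity: truth against itself is perfect
  te <- load_split(fx$manifest, "test", fields = "f")
  dr <- fx$manifest$ensemble$phase_max - fx$manifest$ensemble$phase_min
  expect_equal(pcc(te$f[[1L]], te$f[[1L]]), 1, tolerance = 1e-12)
  expect_equal(ssim(te$f[[1L]], te$f[[1L]], dr), 1, tolerance = 1e-12)
})

test_that("split leakage is detected as a protocol error", {
  fx <- tiny_bundle_fixture()
  man2 <- fx$manifest
  # corrupt the manifest: copy a training record into the test split
  leak <- Filter(function(r) r$split == "train", man2$records)[[1L]]
  leak$split <- "test"
  man2$records <- c(man2$records, list(leak))
  expect_error(evaluate_bundle(fx$bundle, man2), "protocol")
})

test_that("spectral comparison normalizes to the ground-truth peak", {
  set.seed(52)
  truth <- lapply(1:5, function(i) matrix(rnorm(256), 16L))
  prof <- spectral_comparison(list(self = truth), truth)
  expect_equal(prof$self$power, prof$ground_truth$power, tolerance = 1e-12)
  expect_equal(max(prof$ground_truth$power), 1)
  blurred <- lapply(truth, function(m) {
    k <- matrix(1 / 9, 3L, 3L)
    # crude 3x3 smoothing: damps the high band
    out <- m
    for (i in 2:15) for (j in 2:15) out[i, j] <- sum(m[(i-1):(i+1), (j-1):(j+1)] * k)
    out
  })
  prof2 <- spectral_comparison(list(blur = blurred), truth)
  tq <- prof2$ground_truth$freqs >= max(prof2$ground_truth$freqs) * 0.75
  expect_lt(sum(prof2$blur$power[tq]), sum(prof2$ground_truth$power[tq]))
})

test_that("metric tables export as CSV", {
  fx <- tiny_bundle_fixture()
  mr <- evaluate_bundle(fx$bundle, fx$manifest)
  path <- tempfile(fileext = ".csv")
  write_metrics_csv(mr, path)
  tab <- utils::read.csv(path)
  expect_identical(nrow(tab), nrow(mr$summary))
  expect_true(all(c("estimator", "mean_pcc", "sd_pcc") %in% names(tab)))
})
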