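# The tiny bundle fixture (30 objects at 16x16, 3 epochs, depth-1 nets) is
# shared across these interface tests; the scientifically scaled benchmark
# lives in the acceptance suite.

test_that("training reduces the loss and keeps the protocol", {
  fx <- tiny_bundle_fixture()
  for (net in list(fx$bundle$model_l, fx$bundle$model_h, fx$bundle$model_s)) {
    h <- net$history
    expect_lt(h$train_loss[nrow(h)], h$train_loss[1L])
    expect_identical(nrow(h), 3L)
    expect_true(net$best_epoch >= 1L && net$best_epoch <= 3L)
    expect_equal(net$best_val_loss, min(h$val_loss))
  }
})

test_that("training is reproducible under identical seeds", {
  fx <- tiny_bundle_fixture()
  us <- unet_spec(depth = 1L, base_channels = 4L, seed = 9L)
  tc <- train_config(epochs = 2L, batch_size = 10L, q = 0.5, seed = 9L)
  n1 <- train_dnn_l(fx$manifest, us, tc)
  n2 <- train_dnn_l(fx$manifest, us, tc)
  expect_identical(n1$history, n2$history)
  expect_identical(n1$params, n2$params)
})

test_that("DNN-H refuses a filter exponent mismatch", {
  fx <- tiny_bundle_fixture()
  us <- unet_spec(depth = 1L, base_channels = 4L, seed = 2L)
  tc <- train_config(epochs = 1L, batch_size = 10L, q = 0.3, seed = 2L)
  expect_error(train_dnn_h(fx$manifest, us, tc), "q = 0.5")
})

test_that("DNN-S demands trained upstream networks of the right roles", {
  fx <- tiny_bundle_fixture()
  us <- unet_spec(depth = 1L, base_channels = 4L, seed = 2L)
  tc <- train_config(epochs = 1L, batch_size = 10L, q = 0.5, seed = 2L)
  expect_error(train_dnn_s(fx$manifest, fx$bundle$model_h, fx$bundle$model_h,
                           us, tc), "DNN-L")
  expect_error(ls_bundle(fx$bundle$model_l, fx$bundle$model_l,
                         fx$bundle$model_s, 0.5, "approximant"))
})

test_that("bundle prediction is deterministic with matching shapes", {
  fx <- tiny_bundle_fixture()
  te <- load_split(fx$manifest, "test", fields = "fhat")
  p1 <- predict(fx$bundle, te$fhat[[1L]])
  p2 <- predict(fx$bundle, te$fhat[[1L]])
  expect_identical(p1, p2)
  expect_identical(dim(p1), dim(te$fhat[[1L]]))
  # reconstruction beats the raw approximant on average over the test split
  teft <- load_split(fx$manifest, "test", fields = c("f", "fhat"))
  preds <- predict(fx$bundle, teft$fhat)
  gain <- mean(mapply(pcc, preds, teft$f)) -
    mean(mapply(pcc, teft$fhat, teft$f))
  expect_gt(gain, 0)
})

test_that("histogram calibration undoes affine distortions", {
  set.seed(41)
  f <- matrix(runif(32 * 32, 0, pi), 32L)
  distorted <- 2.5 * f + 1.2
  cal <- calibrate_phase(distorted, as.vector(f))
  binw <- diff(range(f)) / 100
  expect_lt(max(abs(cal - f)), binw)
  # output support within the reference range
  expect_gte(min(cal), min(f))
  expect_lte(max(cal), max(f))
  # identity when already matched
  cal2 <- calibrate_phase(f, as.vector(f))
  expect_lt(max(abs(cal2 - f)), binw)
  expect_error(calibrate_phase(matrix(1, 8L, 8L), as.vector(f)), "constant")
})

test_that("phase_reference pools training statistics compactly", {
  set.seed(42)
  phases <- lapply(1:3, function(i) matrix(runif(64, 0, 2), 8L))
  ref <- phase_reference(phases, n_quantiles = 64L)
  expect_length(ref$quantiles, 64L)
  expect_equal(ref$n_pixels, 3L * 64L)
  expect_gte(min(ref$quantiles), 0)
  cal <- calibrate_phase(matrix(rnorm(64), 8L), ref)
  expect_true(all(cal >= min(ref$quantiles) & cal <= max(ref$quantiles)))
})

test_that("bundles survive a save/load round trip", {
  fx <- tiny_bundle_fixture()
  dir <- file.path(tempdir(), "bundle-rt")
  unlink(dir, recursive = TRUE)
  save_bundle(fx$bundle, dir)
  b2 <- load_bundle(dir)
  te <- load_split(fx$manifest, "test", fields = "fhat")
  expect_equal(predict(fx$bundle, te$fhat[[1L]]), predict(b2, te$fhat[[1L]]),
               tolerance = 1e-12)
  expect_equal(b2$q, 0.5)
  expect_identical(b2$scheme, "approximant")
})
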