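test_that("NPCC loss matches its defining identities", {
  set.seed(31)
  t0 <- matrix(rnorm(64), 8L)
  expect_equal(npcc_loss(t0, t0), -1, tolerance = 1e-12)
  # affine invariance for positive scale
  for (a in c(0.1, 1, 10)) {
    expect_equal(npcc_loss(a * t0 + 7, t0), -1, tolerance = 1e-6)
  }
  expect_equal(npcc_loss(-t0, t0), 1, tolerance = 1e-12)
  # equals minus the Pearson correlation on singletons
  set.seed(32)
  a <- matrix(rnorm(64), 8L); b <- matrix(rnorm(64), 8L)
  expect_equal(npcc_loss(a, b), -pcc(a, b), tolerance = 1e-7)
  # batch mean over a list
  expect_equal(npcc_loss(list(t0, -t0), list(t0, t0)), 0, tolerance = 1e-12)
})

test_that("constant images give a warned zero NPCC contribution", {
  t0 <- matrix(rnorm(16), 4L)
  expect_warning(v <- npcc_loss(matrix(1, 4L, 4L), t0), "constant")
  expect_equal(v, 0)
})

test_that("im2col and col2im are adjoint", {
  set.seed(33)
  x <- array(rnorm(6 * 6 * 2 * 3), dim = c(6L, 6L, 2L, 3L))
  y <- matrix(rnorm(6 * 6 * 2 * 9 * 3), 6 * 6 * 2, 9 * 3)
  lhs <- sum(lsphase:::im2col(x, 3L) * y)
  rhs <- sum(x * lsphase:::col2im(y, dim(x), 3L))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("U-net gradients match finite differences", {
  spec <- unet_spec(depth = 2L, base_channels = 3L, residual = TRUE,
                    input_channels = 2L, bypass_channel = 2L, seed = 42L)
  params <- unet_init(spec)
  set.seed(7)
  x <- array(rnorm(8 * 8 * 2 * 2), dim = c(8L, 8L, 2L, 2L))
  y <- array(rnorm(8 * 8 * 2 * 1), dim = c(8L, 8L, 2L, 1L))
  fw <- lsphase:::unet_forward(params, spec, x)
  lg <- lsphase:::npcc_with_grad(fw$out, y)
  grads <- lsphase:::unet_backward(params, spec, fw$cache, lg$grad)
  loss_at <- function(p) {
    out <- lsphase:::unet_forward(p, spec, x, keep_cache = FALSE)$out
    lsphase:::npcc_with_grad(out, y)$loss
  }
  eps <- 1e-6
  set.seed(99)
  for (nm in c("enc1_c1", "enc2_c2", "bot_c1", "dec2_c1", "dec1_c2", "head")) {
    for (slot in c("W", "b")) {
      obj <- params[[nm]][[slot]]
      for (i in sample(seq_along(obj), min(4L, length(obj)))) {
        p2 <- params
        p2[[nm]][[slot]][i] <- p2[[nm]][[slot]][i] + eps
        num <- (loss_at(p2) - lg$loss) / eps
        ana <- grads[[nm]][[slot]][i]
        expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-3)
      }
    }
  }
})

test_that("weight initialization is seed-deterministic and shaped by capacity", {
  s1 <- unet_spec(depth = 2L, base_channels = 4L, seed = 5L)
  expect_identical(unet_init(s1), unet_init(s1))
  n_params <- function(sp) sum(vapply(unet_init(sp),
                                      function(p) length(p$W) + length(p$b),
                                      numeric(1L)))
  s3 <- unet_spec(depth = 2L, base_channels = 4L, capacity_multiplier = 3,
                  seed = 5L)
  ratio <- n_params(s3) / n_params(s1)
  expect_gt(ratio, 2)          # parameter count scales ~ multiplier
  expect_lt(ratio, 4.5)
})

test_that("forward output has the input's spatial shape and batch size", {
  spec <- unet_spec(depth = 2L, base_channels = 4L, seed = 1L)
  params <- unet_init(spec)
  x <- array(rnorm(16 * 16 * 3), dim = c(16L, 16L, 3L, 1L))
  out <- lsphase:::unet_forward(params, spec, x, keep_cache = FALSE)$out
  expect_identical(dim(out), c(16L, 16L, 3L, 1L))
})
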