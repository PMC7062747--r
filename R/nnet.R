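# Minimal convolutional-network engine used by the LS scheme: batched
# im2col convolutions running on BLAS, 2x mean-pool / nearest-neighbour
# upsample, ReLU, and an Adam optimizer. Tensors are 4D arrays with
# dimensions (H, W, N, C) -- channels last, so channel concatenation is a
# plain c() on the underlying vector.

# ---- tensor helpers --------------------------------------------------------

# Stack a list of matrices (and optionally a second channel list) into a
# (H, W, N, C) tensor.
as_tensor4 <- function(channel_lists) {
  if (is.matrix(channel_lists[[1L]])) channel_lists <- list(channel_lists)
  n_img <- length(channel_lists[[1L]])
  h <- nrow(channel_lists[[1L]][[1L]]); w <- ncol(channel_lists[[1L]][[1L]])
  n_ch <- length(channel_lists)
  array(unlist(channel_lists, use.names = FALSE), dim = c(h, w, n_img, n_ch))
}

tensor_to_list <- function(x) {
  d <- dim(x)
  lapply(seq_len(d[3L]), function(i) matrix(x[, , i, 1L], d[1L], d[2L]))
}

# ---- convolution -----------------------------------------------------------

# im2col: (H,W,N,C) -> matrix (H*W*N, k*k*C) for a k x k same-padded conv.
# The patch extraction runs in C++ (src/conv_ops.cpp); matmuls stay on BLAS.
im2col <- function(x, k) {
  d <- dim(x)
  if (k == 1L) {
    dim(x) <- c(d[1L] * d[2L] * d[3L], d[4L])
    return(x)
  }
  cpp_im2col(x, d[1L], d[2L], d[3L], d[4L], as.integer(k))
}

# Adjoint of im2col: matrix (H*W*N, k*k*C) -> (H,W,N,C), accumulating
# overlapping contributions.
col2im <- function(cols, dims, k) {
  if (k == 1L) {
    dim(cols) <- dims
    return(cols)
  }
  out <- cpp_col2im(cols, dims[1L], dims[2L], dims[3L], dims[4L], as.integer(k))
  dim(out) <- dims
  out
}

conv_init <- function(k, c_in, c_out, rng_sd = NULL) {
  sd <- if (is.null(rng_sd)) sqrt(2 / (k * k * c_in)) else rng_sd
  list(W = matrix(stats::rnorm(k * k * c_in * c_out, 0, sd), k * k * c_in, c_out),
       b = numeric(c_out), k = k, c_in = c_in, c_out = c_out)
}

conv_forward <- function(x, p) {
  d <- dim(x)
  xc <- im2col(x, p$k)
  y <- xc %*% p$W
  y <- sweep(y, 2L, p$b, `+`)
  dim(y) <- c(d[1L], d[2L], d[3L], p$c_out)
  list(y = y, xc = xc, in_dims = d)
}

conv_backward <- function(dy, cache, p, need_dx = TRUE) {
  d <- dim(dy)
  dym <- dy; dim(dym) <- c(d[1L] * d[2L] * d[3L], d[4L])
  dW <- crossprod(cache$xc, dym)
  db <- colSums(dym)
  dx <- NULL
  if (need_dx) {
    dxc <- tcrossprod(dym, p$W)
    dx <- col2im(dxc, cache$in_dims, p$k)
  }
  list(dx = dx, dW = dW, db = db)
}

relu_forward <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}
relu_backward <- function(dy, mask) dy * mask

# 2x2 mean pool and its adjoint.
pool_forward <- function(x) {
  d <- dim(x)
  o <- seq.int(1L, d[1L], 2L); e <- o + 1L
  (x[o, o, , , drop = FALSE] + x[e, o, , , drop = FALSE] +
   x[o, e, , , drop = FALSE] + x[e, e, , , drop = FALSE]) / 4
}
pool_backward <- function(dy) {
  d <- dim(dy)
  dy[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), , ,
     drop = FALSE] / 4
}

# nearest-neighbour 2x upsample and its adjoint.
up_forward <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), , ,
    drop = FALSE]
}
up_backward <- function(dy) {
  d <- dim(dy)
  o <- seq.int(1L, d[1L], 2L); e <- o + 1L
  dy[o, o, , , drop = FALSE] + dy[e, o, , , drop = FALSE] +
    dy[o, e, , , drop = FALSE] + dy[e, e, , , drop = FALSE]
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- c(a, b)
  dim(out) <- c(da[1L], da[2L], da[3L], da[4L] + db[4L])
  out
}

# ---- NPCC loss -------------------------------------------------------------

#' Negative Pearson correlation training loss
#'
#' The loss used to train all three LS networks: the batch mean of minus
#' the Pearson correlation coefficient between each predicted map and its
#' target, so perfect (positively, affinely related) reconstructions score
#' -1 and anti-correlated ones +1. Scale- and offset-invariant in either
#' argument for positive scale; the quantitative phase scale is restored
#' downstream by histogram matching. A spatially constant map has no
#' defined correlation; its contribution is 0 with a warning (the gradient
#' there is zero).
#'
#' @param prediction,target Matrices, or lists of matrices (a batch), or
#'   `(H, W, N, 1)` arrays.
#' @return A single number in `[-1, 1]`.
#' @export
npcc_loss <- function(prediction, target) {
  npcc_with_grad(as_loss_tensor(prediction), as_loss_tensor(target))$loss
}

as_loss_tensor <- function(x) {
  if (is.list(x)) x <- as_tensor4(x)
  if (is.matrix(x)) dim(x) <- c(nrow(x), ncol(x), 1L, 1L)
  x
}

# loss and gradient wrt prediction, both batch-averaged
npcc_with_grad <- function(pred, target) {
  d <- dim(pred)
  if (!all(d == dim(target))) stop("shape mismatch", call. = FALSE)
  n <- d[3L]
  grad <- array(0, dim = d)
  loss <- 0
  for (i in seq_len(n)) {
    x <- pred[, , i, 1L]; t <- target[, , i, 1L]
    xm <- x - mean(x); tm <- t - mean(t)
    sx <- sqrt(sum(xm^2)); st <- sqrt(sum(tm^2))
    if (sx == 0 || st == 0) {
      warning("constant image in NPCC: contribution set to 0", call. = FALSE)
      next
    }
    rho <- sum(xm * tm) / (sx * st)
    loss <- loss - rho
    grad[, , i, 1L] <- -(tm / (sx * st) - rho * xm / sx^2) / n
  }
  list(loss = loss / n, grad = grad)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(p) list(W = p$W * 0, b = p$b * 0)
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    for (slot in c("W", "b")) {
      g <- grads[[nm]][[slot]]
      state$m[[nm]][[slot]] <- beta1 * state$m[[nm]][[slot]] + (1 - beta1) * g
      state$v[[nm]][[slot]] <- beta2 * state$v[[nm]][[slot]] + (1 - beta2) * g^2
      mhat <- state$m[[nm]][[slot]] / corr1
      vhat <- state$v[[nm]][[slot]] / corr2
      params[[nm]][[slot]] <- params[[nm]][[slot]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}
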