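# Residual U-net built from the primitives in nnet.R. Two 3x3 conv+ReLU
# blocks per level, 2x mean-pool down, nearest-neighbour up with skip
# concatenation, a 1x1 head, an optional global residual connection from
# the first input channel, and an optional bypass channel presented intact
# to the head (the synthesizer's high-band wire).

unet_channels <- function(spec) {
  base <- max(1L, as.integer(round(spec$base_channels *
                                     sqrt(spec$capacity_multiplier))))
  list(enc = base * 2L^(seq_len(spec$depth) - 1L),
       bot = base * 2L^spec$depth)
}

#' Initialize U-net weights
#'
#' He-style Gaussian initialization, deterministic under `spec$seed`.
#'
#' @param spec A [unet_spec()].
#' @return A list of named convolution parameter blocks.
#' @export
unet_init <- function(spec) {
  stopifnot(inherits(spec, "unet_spec"))
  ch <- unet_channels(spec)
  with_local_seed(spec$seed, {
    params <- list()
    c_in <- spec$input_channels
    for (l in seq_len(spec$depth)) {
      params[[paste0("enc", l, "_c1")]] <- conv_init(3L, c_in, ch$enc[l])
      params[[paste0("enc", l, "_c2")]] <- conv_init(3L, ch$enc[l], ch$enc[l])
      c_in <- ch$enc[l]
    }
    params$bot_c1 <- conv_init(3L, c_in, ch$bot)
    params$bot_c2 <- conv_init(3L, ch$bot, ch$bot)
    c_below <- ch$bot
    for (l in rev(seq_len(spec$depth))) {
      params[[paste0("dec", l, "_c1")]] <-
        conv_init(3L, c_below + ch$enc[l], ch$enc[l])
      params[[paste0("dec", l, "_c2")]] <- conv_init(3L, ch$enc[l], ch$enc[l])
      c_below <- ch$enc[l]
    }
    head_in <- ch$enc[1L] + as.integer(!is.null(spec$bypass_channel))
    params$head <- conv_init(1L, head_in, 1L)
    params
  })
}

# One conv + ReLU block; returns output plus caches for the backward pass.
block_fwd <- function(x, p) {
  cv <- conv_forward(x, p)
  rl <- relu_forward(cv$y)
  list(y = rl$y, conv = cv, mask = rl$mask)
}
block_bwd <- function(dy, cache, p, need_dx = TRUE) {
  conv_backward(relu_backward(dy, cache$mask), cache$conv, p, need_dx = need_dx)
}

# Forward pass. x is (H, W, N, C); returns list(out, cache).
unet_forward <- function(params, spec, x, keep_cache = TRUE) {
  cache <- list(x = x, enc = vector("list", spec$depth),
                dec = vector("list", spec$depth))
  cur <- x
  skips <- vector("list", spec$depth)
  for (l in seq_len(spec$depth)) {
    b1 <- block_fwd(cur, params[[paste0("enc", l, "_c1")]])
    b2 <- block_fwd(b1$y, params[[paste0("enc", l, "_c2")]])
    skips[[l]] <- b2$y
    cache$enc[[l]] <- list(b1 = b1, b2 = b2)
    cur <- pool_forward(b2$y)
  }
  bb1 <- block_fwd(cur, params$bot_c1)
  bb2 <- block_fwd(bb1$y, params$bot_c2)
  cache$bot <- list(b1 = bb1, b2 = bb2)
  cur <- bb2$y
  for (l in rev(seq_len(spec$depth))) {
    upv <- up_forward(cur)
    cat_in <- concat_c(upv, skips[[l]])
    d1 <- block_fwd(cat_in, params[[paste0("dec", l, "_c1")]])
    d2 <- block_fwd(d1$y, params[[paste0("dec", l, "_c2")]])
    cache$dec[[l]] <- list(b1 = d1, b2 = d2,
                           c_up = dim(upv)[4L], c_skip = dim(skips[[l]])[4L])
    cur <- d2$y
  }
  feats <- cur
  if (!is.null(spec$bypass_channel)) {
    bp <- x[, , , spec$bypass_channel, drop = FALSE]
    feats <- concat_c(feats, bp)
  }
  hv <- conv_forward(feats, params$head)
  out <- hv$y
  if (spec$residual) out <- out + x[, , , 1L, drop = FALSE]
  cache$head <- hv
  if (!keep_cache) cache <- NULL
  list(out = out, cache = cache)
}

# Backward pass: gradient of the scalar loss wrt every parameter block.
unet_backward <- function(params, spec, cache, dout) {
  grads <- list()
  hb <- conv_backward(dout, cache$head, params$head)
  grads$head <- list(W = hb$dW, b = hb$db)
  dfeats <- hb$dx
  if (!is.null(spec$bypass_channel)) {
    nc <- dim(dfeats)[4L]
    dfeats <- dfeats[, , , seq_len(nc - 1L), drop = FALSE]   # bypass grad unused
  }
  dcur <- dfeats
  dskips <- vector("list", spec$depth)
  for (l in seq_len(spec$depth)) {      # decoder levels, top-down in reverse
    dc <- cache$dec[[l]]
    g2 <- block_bwd(dcur, dc$b2, params[[paste0("dec", l, "_c2")]])
    grads[[paste0("dec", l, "_c2")]] <- list(W = g2$dW, b = g2$db)
    g1 <- block_bwd(g2$dx, dc$b1, params[[paste0("dec", l, "_c1")]])
    grads[[paste0("dec", l, "_c1")]] <- list(W = g1$dW, b = g1$db)
    dskips[[l]] <- g1$dx[, , , dc$c_up + seq_len(dc$c_skip), drop = FALSE]
    dcur <- up_backward(g1$dx[, , , seq_len(dc$c_up), drop = FALSE])
  }
  gb2 <- block_bwd(dcur, cache$bot$b2, params$bot_c2)
  grads$bot_c2 <- list(W = gb2$dW, b = gb2$db)
  gb1 <- block_bwd(gb2$dx, cache$bot$b1, params$bot_c1)
  grads$bot_c1 <- list(W = gb1$dW, b = gb1$db)
  dcur <- gb1$dx
  for (l in rev(seq_len(spec$depth))) { # encoder levels, bottom-up
    dskip_total <- pool_backward(dcur) + dskips[[l]]
    g2 <- block_bwd(dskip_total, cache$enc[[l]]$b2, params[[paste0("enc", l, "_c2")]])
    grads[[paste0("enc", l, "_c2")]] <- list(W = g2$dW, b = g2$db)
    g1 <- block_bwd(g2$dx, cache$enc[[l]]$b1, params[[paste0("enc", l, "_c1")]],
                    need_dx = l > 1L)   # input gradients are never consumed
    grads[[paste0("enc", l, "_c1")]] <- list(W = g1$dW, b = g1$db)
    dcur <- g1$dx
  }
  grads
}

# ---- training loop ---------------------------------------------------------

# Train a U-net with the NPCC loss and Adam, selecting the epoch with the
# best validation loss. `x`, `y` are (H,W,N,C) tensors (targets C = 1).
train_network <- function(x, y, x_val, y_val, spec, cfg) {
  stopifnot(inherits(spec, "unet_spec"), inherits(cfg, "train_config"))
  params <- unet_init(spec)
  state <- adam_init(params)
  n <- dim(x)[3L]
  n_batches <- ceiling(n / cfg$batch_size)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, params = params, epoch = 0L)
  order_seed <- cfg$seed + 7919L
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_local_seed(order_seed + ep, sample.int(n))
    ep_loss <- 0
    for (b in seq_len(n_batches)) {
      idx <- ord[((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size, n)]
      xb <- x[, , idx, , drop = FALSE]
      yb <- y[, , idx, , drop = FALSE]
      fw <- unet_forward(params, spec, xb)
      lg <- npcc_with_grad(fw$out, yb)
      ep_loss <- ep_loss + lg$loss * length(idx)
      grads <- unet_backward(params, spec, fw$cache, lg$grad)
      upd <- adam_step(params, grads, state, cfg$learning_rate)
      params <- upd$params; state <- upd$state
    }
    vl <- network_loss(params, spec, x_val, y_val, cfg$batch_size)
    history <- rbind(history,
                     data.frame(epoch = ep, train_loss = ep_loss / n,
                                val_loss = vl))
    if (vl < best$loss) best <- list(loss = vl, params = params, epoch = ep)
  }
  structure(list(params = best$params, spec = spec, config = cfg,
                 history = history, best_epoch = best$epoch,
                 best_val_loss = best$loss),
            class = "ls_network")
}

# Batched loss evaluation without storing caches.
network_loss <- function(params, spec, x, y, batch_size = 25L) {
  n <- dim(x)[3L]
  total <- 0
  for (b in seq_len(ceiling(n / batch_size))) {
    idx <- ((b - 1L) * batch_size + 1L):min(b * batch_size, n)
    out <- unet_forward(params, spec, x[, , idx, , drop = FALSE],
                        keep_cache = FALSE)$out
    total <- total + npcc_with_grad(out, y[, , idx, , drop = FALSE])$loss * length(idx)
  }
  total / n
}

# Batched inference on a (H,W,N,C) tensor; returns (H,W,N,1).
network_predict <- function(net, x, batch_size = 25L) {
  stopifnot(inherits(net, "ls_network"))
  n <- dim(x)[3L]
  out <- array(0, dim = c(dim(x)[1L], dim(x)[2L], n, 1L))
  for (b in seq_len(ceiling(n / batch_size))) {
    idx <- ((b - 1L) * batch_size + 1L):min(b * batch_size, n)
    out[, , idx, 1L] <- unet_forward(net$params, net$spec,
                                     x[, , idx, , drop = FALSE],
                                     keep_cache = FALSE)$out
  }
  out
}
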