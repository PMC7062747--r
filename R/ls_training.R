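# The learning-to-synthesize (LS) scheme: three residual U-nets trained in
# two steps. DNN-L maps the system input (raw intensity or approximant) to
# the unfiltered phase and is faithful at low frequencies; DNN-H maps the
# same unfiltered input to spectrally high-pass-filtered targets and keeps
# the upper band alive; DNN-S is trained afterwards, with L and H frozen, to
# synthesize the two partial reconstructions into a full-band estimate. The
# high-band map is additionally routed intact to DNN-S's final convolution
# so the synthesis cannot destroy it. The three networks are never merged
# into one trainable graph.

ls_input_field <- function(cfg) {
  switch(cfg$scheme, approximant = "fhat", end_to_end = "g")
}

load_xy <- function(manifest, split, cfg, target_field = "f") {
  xi_field <- ls_input_field(cfg)
  dat <- load_split(manifest, split, fields = unique(c(xi_field, target_field)))
  list(x = as_tensor4(dat[[xi_field]]),
       y = as_tensor4(dat[[target_field]]),
       ids = dat$ids)
}

#' Train DNN-L: the low-band-faithful network
#'
#' Minimizes the NPCC loss between the network output and the unfiltered
#' ground-truth phase over the training split; the returned weights are
#' those of the epoch with the best validation loss. The input is the raw
#' measurement (`scheme = "end_to_end"`) or the single-iteration
#' approximant (`scheme = "approximant"`).
#'
#' @param manifest A `dataset_manifest` from [make_dataset()].
#' @param unet A [unet_spec()] with `input_channels = 1`.
#' @param cfg A [train_config()].
#' @return An `ls_network` (weights, spec, config, per-epoch loss history).
#' @export
train_dnn_l <- function(manifest, unet, cfg) {
  tr <- load_xy(manifest, "train", cfg)
  va <- load_xy(manifest, "validation", cfg)
  if (dim(tr$x)[3L] == 0L || dim(va$x)[3L] == 0L)
    stop("empty train or validation split", call. = FALSE)
  net <- train_network(tr$x, tr$y, va$x, va$y, unet, cfg)
  net$role <- "dnn_l"
  net
}

#' Train DNN-H: the high-band network
#'
#' Identical protocol to [train_dnn_l()] except that the targets are the
#' spectrally filtered phases `fp` stored in the manifest; the inputs remain
#' unfiltered. The manifest's filter exponent must equal `cfg$q`.
#'
#' @inheritParams train_dnn_l
#' @return An `ls_network`.
#' @export
train_dnn_h <- function(manifest, unet, cfg) {
  mq <- manifest$filter$q
  if (!isTRUE(all.equal(as.numeric(mq), as.numeric(cfg$q))))
    stop(sprintf("manifest was filtered at q = %s but cfg$q = %s", mq, cfg$q),
         call. = FALSE)
  tr <- load_xy(manifest, "train", cfg, target_field = "fp")
  va <- load_xy(manifest, "validation", cfg, target_field = "fp")
  if (dim(tr$x)[3L] == 0L || dim(va$x)[3L] == 0L)
    stop("empty train or validation split", call. = FALSE)
  net <- train_network(tr$x, tr$y, va$x, va$y, unet, cfg)
  net$role <- "dnn_h"
  net
}

#' Train DNN-S: the synthesizer network
#'
#' With DNN-L and DNN-H frozen, their outputs on the training and validation
#' splits are precomputed and presented to DNN-S as a two-channel input
#' (low-band map, high-band map). The high-band channel is additionally
#' bypassed around the network body and concatenated unmodified at the
#' final convolution. Targets are the unfiltered ground-truth phases. With
#' `calibrate_inputs = TRUE` each band map is first histogram-matched
#' against its own training-target statistics; the default feeds the raw
#' network outputs, whose arbitrary NPCC scale the synthesizer absorbs
#' during training.
#'
#' @param manifest A `dataset_manifest`.
#' @param model_l,model_h Trained `ls_network`s from [train_dnn_l()] /
#'   [train_dnn_h()].
#' @param unet A [unet_spec()]; its `input_channels` is forced to 2 and, by
#'   default, channel 2 (the high-band map) is the bypass channel.
#' @param cfg A [train_config()].
#' @param calibrate_inputs Histogram-match the band maps to their training
#'   targets before synthesis (default FALSE).
#' @return An `ls_network` (with the band-input calibration references in
#'   `$input_calibration` when enabled).
#' @export
train_dnn_s <- function(manifest, model_l, model_h, unet, cfg,
                        calibrate_inputs = FALSE) {
  stopifnot(inherits(model_l, "ls_network"), inherits(model_h, "ls_network"))
  if (!identical(model_l$role, "dnn_l") || !identical(model_h$role, "dnn_h"))
    stop("`model_l` / `model_h` must be trained DNN-L / DNN-H networks",
         call. = FALSE)
  unet$input_channels <- 2L
  if (is.null(unet$bypass_channel)) unet$bypass_channel <- 2L
  tr <- load_xy(manifest, "train", cfg)
  va <- load_xy(manifest, "validation", cfg)
  calib <- NULL
  if (isTRUE(calibrate_inputs)) {
    tr_targets <- load_split(manifest, "train", fields = c("f", "fp"))
    calib <- list(lf = phase_reference(tr_targets$f, n_quantiles = 512L),
                  hf = phase_reference(tr_targets$fp, n_quantiles = 512L))
  }
  s_input <- function(x) s_band_input(model_l, model_h, x, calib)
  net <- train_network(s_input(tr$x), tr$y, s_input(va$x), va$y, unet, cfg)
  net$role <- "dnn_s"
  net$input_calibration <- calib
  net
}

# Calibrated two-channel synthesizer input from the frozen band networks.
s_band_input <- function(model_l, model_h, x, calib) {
  lf <- network_predict(model_l, x)
  hf <- network_predict(model_h, x)
  if (!is.null(calib)) {
    for (i in seq_len(dim(lf)[3L])) {
      lf[, , i, 1L] <- calibrate_phase(matrix(lf[, , i, 1L], dim(lf)[1L]),
                                       calib$lf)
      hf[, , i, 1L] <- calibrate_phase(matrix(hf[, , i, 1L], dim(hf)[1L]),
                                       calib$hf)
    }
  }
  concat_c(lf, hf)
}

#' Assemble a trained LS bundle
#'
#' @param model_l,model_h,model_s Trained networks with roles
#'   `dnn_l`, `dnn_h`, `dnn_s`.
#' @param q Filter exponent the high band was trained at.
#' @param scheme `"approximant"` or `"end_to_end"`.
#' @return An object of class `ls_bundle`.
#' @export
ls_bundle <- function(model_l, model_h, model_s, q, scheme) {
  stopifnot(identical(model_l$role, "dnn_l"),
            identical(model_h$role, "dnn_h"),
            identical(model_s$role, "dnn_s"))
  structure(list(model_l = model_l, model_h = model_h, model_s = model_s,
                 q = q, scheme = scheme),
            class = "ls_bundle")
}

#' Reconstruct phase with a trained LS bundle
#'
#' Runs the test-stage wiring: the input is passed to DNN-L and DNN-H in
#' parallel, and their outputs (with the high-band bypass) are synthesized
#' by DNN-S. Deterministic at inference.
#'
#' @param object An `ls_bundle`.
#' @param xi A matrix (or list of matrices) matching the bundle's scheme:
#'   raw intensity for `end_to_end`, approximant for `approximant`.
#' @param ... Unused.
#' @return A phase matrix (or list of matrices if `xi` was a list).
#' @export
predict.ls_bundle <- function(object, xi, ...) {
  single <- is.matrix(xi)
  x <- as_tensor4(if (single) list(xi) else xi)
  s_in <- s_band_input(object$model_l, object$model_h, x,
                       object$model_s$input_calibration)
  out <- network_predict(object$model_s, s_in)
  res <- tensor_to_list(out)
  if (single) res[[1L]] else res
}

# Per-band component outputs (used by the evaluation harness). The low- and
# high-band maps are reported raw (as produced by their networks); the
# synthesizer consumes their calibrated versions.
ls_component_outputs <- function(bundle, xi_list) {
  x <- as_tensor4(xi_list)
  lf <- network_predict(bundle$model_l, x)
  hf <- network_predict(bundle$model_h, x)
  s_in <- s_band_input(bundle$model_l, bundle$model_h, x,
                       bundle$model_s$input_calibration)
  sf <- network_predict(bundle$model_s, s_in)
  list(dnn_l = tensor_to_list(lf), dnn_h = tensor_to_list(hf),
       dnn_s = tensor_to_list(sf))
}

#' Calibrate a reconstruction against reference phase statistics
#'
#' The NPCC loss is blind to affine transformations of its arguments, so a
#' trained network reconstructs phase only up to scale and offset. This
#' monotone histogram-matching step maps the reconstruction's empirical CDF
#' onto a reference CDF (typically the pooled ground-truth phase values of
#' the training split), restoring quantitative phase. An affine distortion
#' `alpha * f + beta` (`alpha > 0`) of an image distributed like the
#' reference is undone exactly up to quantile-interpolation error.
#'
#' @param reconstruction A phase matrix.
#' @param reference_histogram A numeric vector of reference phase samples
#'   (e.g. pooled training ground truth), or a `reference_histogram` object
#'   from [phase_reference()].
#' @return A calibrated phase matrix with values inside the reference range.
#' @export
calibrate_phase <- function(reconstruction, reference_histogram) {
  assert_image(reconstruction, "reconstruction")
  ref <- if (inherits(reference_histogram, "phase_reference"))
    reference_histogram$quantiles else as.numeric(reference_histogram)
  if (length(ref) < 2L) stop("reference histogram too small", call. = FALSE)
  v <- as.vector(reconstruction)
  if (stats::sd(v) == 0)
    stop("constant reconstruction: CDF is degenerate", call. = FALSE)
  probs <- (rank(v, ties.method = "average") - 0.5) / length(v)
  out <- stats::quantile(ref, probs, names = FALSE, type = 7L)
  matrix(out, nrow(reconstruction), ncol(reconstruction))
}

#' Summarize reference phase statistics for calibration
#'
#' Pools the pixel values of a set of ground-truth phase maps into a fixed
#' number of quantiles, the compact reference used by [calibrate_phase()].
#'
#' @param phases A list of phase matrices (training ground truth).
#' @param n_quantiles Number of stored quantiles.
#' @return An object of class `phase_reference`.
#' @export
phase_reference <- function(phases, n_quantiles = 2048L) {
  if (is.matrix(phases)) phases <- list(phases)
  v <- unlist(lapply(phases, as.vector), use.names = FALSE)
  qs <- stats::quantile(v, probs = seq(0, 1, length.out = n_quantiles),
                        names = FALSE, type = 7L)
  structure(list(quantiles = qs, n_pixels = length(v)),
            class = "phase_reference")
}

#' Save / load a trained LS bundle
#'
#' The bundle is written as a directory: one weight file per network (flat
#' text, one line per parameter block) plus a YAML manifest of the specs,
#' training configs and loss histories.
#'
#' @param bundle An `ls_bundle`.
#' @param dir Target directory.
#' @return `save_bundle` returns `dir` invisibly; `load_bundle` returns the
#'   `ls_bundle`.
#' @export
save_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ls_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(q = bundle$q, scheme = bundle$scheme)
  for (nm in c("model_l", "model_h", "model_s")) {
    net <- bundle[[nm]]
    con <- file(file.path(dir, paste0(nm, "_weights.txt")), "w")
    for (pn in names(net$params)) {
      p <- net$params[[pn]]
      writeLines(paste(pn, "W", p$k, p$c_in, p$c_out,
                       paste(sprintf("%.17g", p$W), collapse = " ")), con)
      writeLines(paste(pn, "b", p$k, p$c_in, p$c_out,
                       paste(sprintf("%.17g", p$b), collapse = " ")), con)
    }
    close(con)
    meta[[nm]] <- list(spec = unclass(net$spec), config = unclass(net$config),
                       role = net$role, best_epoch = net$best_epoch,
                       best_val_loss = net$best_val_loss,
                       history = as.list(net$history))
    if (!is.null(net$input_calibration)) {
      meta[[nm]]$input_calibration <- lapply(net$input_calibration,
                                             function(r) unclass(r))
    }
  }
  yaml::write_yaml(meta, file.path(dir, "bundle.yaml"))
  invisible(dir)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "bundle.yaml"))
  read_net <- function(nm) {
    m <- meta[[nm]]
    spec <- do.call(unet_spec,
                    m$spec[intersect(names(m$spec), names(formals(unet_spec)))])
    cfg <- do.call(train_config,
                   m$config[intersect(names(m$config), names(formals(train_config)))])
    lines <- readLines(file.path(dir, paste0(nm, "_weights.txt")))
    params <- list()
    for (ln in lines) {
      parts <- strsplit(ln, " ", fixed = TRUE)[[1L]]
      pn <- parts[1L]; slot <- parts[2L]
      k <- as.integer(parts[3L]); ci <- as.integer(parts[4L])
      co <- as.integer(parts[5L])
      vals <- as.numeric(parts[-(1:5)])
      if (is.null(params[[pn]]))
        params[[pn]] <- list(W = NULL, b = NULL, k = k, c_in = ci, c_out = co)
      if (slot == "W") params[[pn]]$W <- matrix(vals, k * k * ci, co)
      else params[[pn]]$b <- vals
    }
    net <- structure(list(params = params, spec = spec, config = cfg,
                          history = as.data.frame(m$history),
                          best_epoch = m$best_epoch,
                          best_val_loss = m$best_val_loss,
                          role = m$role),
                     class = "ls_network")
    if (!is.null(m$input_calibration)) {
      net$input_calibration <- lapply(m$input_calibration, function(r) {
        structure(list(quantiles = as.numeric(r$quantiles),
                       n_pixels = r$n_pixels),
                  class = "phase_reference")
      })
    }
    net
  }
  ls_bundle(read_net("model_l"), read_net("model_h"), read_net("model_s"),
            q = meta$q, scheme = meta$scheme)
}
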