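# Quantitative evaluation: Pearson correlation, PSNR, SSIM, test-split
# metric tables for each LS component, and averaged-PSD spectral
# comparisons between estimators and ground truth.

#' Pearson correlation coefficient of two images
#'
#' Mean-removed normalized cross-correlation: 1 for identical (or
#' positively affinely related) images, 0 for uncorrelated ones.
#'
#' @param a,b Numeric matrices of equal shape.
#' @return A number in `[-1, 1]`.
#' @export
pcc <- function(a, b) {
  assert_image(a, "a"); assert_image(b, "b")
  if (!all(dim(a) == dim(b))) stop("shape mismatch", call. = FALSE)
  am <- a - mean(a); bm <- b - mean(b)
  sa <- sqrt(sum(am^2)); sb <- sqrt(sum(bm^2))
  if (sa == 0 || sb == 0)
    stop("PCC undefined for a spatially constant image", call. = FALSE)
  sum(am * bm) / (sa * sb)
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 log10(data_range^2 / MSE)`; returns `Inf` when the images are
#' identical.
#'
#' @param a,b Numeric matrices of equal shape.
#' @param data_range Peak-to-peak signal range (> 0), e.g. the ground-truth
#'   phase range of the dataset.
#' @return PSNR in dB.
#' @export
psnr <- function(a, b, data_range) {
  assert_image(a, "a"); assert_image(b, "b")
  if (!all(dim(a) == dim(b))) stop("shape mismatch", call. = FALSE)
  stopifnot(data_range > 0)
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

# separable valid-region Gaussian filtering operator: rows i..i+k-1
gaussian_band <- function(n, k = 11L, sigma = 1.5) {
  g <- exp(-((seq_len(k) - (k + 1) / 2)^2) / (2 * sigma^2))
  g <- g / sum(g)
  m <- matrix(0, n - k + 1L, n)
  for (i in seq_len(n - k + 1L)) m[i, i:(i + k - 1L)] <- g
  m
}

#' Structural similarity index of two images
#'
#' Mean local SSIM with the standard 11-pixel Gaussian window
#' (sigma = 1.5) and stabilizers `C1 = (0.01 r)^2`, `C2 = (0.03 r)^2`,
#' computed over the region where the window fits entirely inside the
#' image. Equals 1 iff the images are identical.
#'
#' @param a,b Numeric matrices of equal shape, at least 11 x 11.
#' @param data_range Signal range r (> 0).
#' @param window Window side length (odd).
#' @param sigma Gaussian window standard deviation in pixels.
#' @return A number in `[-1, 1]`.
#' @export
ssim <- function(a, b, data_range, window = 11L, sigma = 1.5) {
  assert_image(a, "a"); assert_image(b, "b")
  if (!all(dim(a) == dim(b))) stop("shape mismatch", call. = FALSE)
  stopifnot(data_range > 0)
  if (nrow(a) < window || ncol(a) < window)
    stop("image smaller than the SSIM window", call. = FALSE)
  mr <- gaussian_band(nrow(a), window, sigma)
  mc <- gaussian_band(ncol(a), window, sigma)
  smooth <- function(x) mr %*% x %*% t(mc)
  mu1 <- smooth(a); mu2 <- smooth(b)
  s11 <- smooth(a * a) - mu1^2
  s22 <- smooth(b * b) - mu2^2
  s12 <- smooth(a * b) - mu1 * mu2
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  num <- (2 * mu1 * mu2 + c1) * (2 * s12 + c2)
  den <- (mu1^2 + mu2^2 + c1) * (s11 + s22 + c2)
  mean(num / den)
}

#' Evaluate a trained LS bundle on the test split
#'
#' Reconstructs every test image with each estimator (the raw approximant,
#' DNN-L, DNN-S, and optionally a capacity-control network), calibrates
#' each reconstruction against the training-split phase histogram, and
#' tabulates PCC, PSNR and SSIM per image and as mean +/- sd per estimator.
#' DNN-H is excluded from the table: its targets are filtered, so a
#' ground-truth comparison is not meaningful. PSNR and SSIM use the
#' dataset-wide ground-truth phase range as `data_range` so rows are
#' comparable.
#'
#' @param bundle An `ls_bundle`.
#' @param manifest A `dataset_manifest` (test split must be disjoint from
#'   train/validation; verified).
#' @param extra_models Optional named list of additional single-input
#'   `ls_network`s to evaluate (e.g. `list(dnn_l3 = net)`).
#' @param calibrate Apply [calibrate_phase()] before computing metrics
#'   (default TRUE).
#' @return A `metrics_record`: list with `per_image` and `summary` data
#'   frames, `n_images`, `flux_p`, `q`.
#' @export
evaluate_bundle <- function(bundle, manifest, extra_models = list(),
                            calibrate = TRUE) {
  stopifnot(inherits(bundle, "ls_bundle"),
            inherits(manifest, "dataset_manifest"))
  ids_of <- function(s) vapply(Filter(function(r) r$split == s,
                                      manifest$records), `[[`, "", "id")
  test_ids <- ids_of("test")
  if (length(intersect(test_ids, c(ids_of("train"), ids_of("validation")))) > 0L)
    stop("protocol error: test ids overlap train/validation", call. = FALSE)
  cfg <- bundle$model_l$config
  te <- load_split(manifest, "test",
                   fields = unique(c(ls_input_field(cfg), "f")))
  tr <- load_split(manifest, "train", fields = "f")
  ref <- phase_reference(tr$f)
  xi <- te[[ls_input_field(cfg)]]
  truth <- te$f
  comp <- ls_component_outputs(bundle, xi)
  estimates <- list(approximant = te_fhat_or_input(te, manifest, cfg),
                    dnn_l = comp$dnn_l, dnn_s = comp$dnn_s)
  for (nm in names(extra_models)) {
    estimates[[nm]] <- tensor_to_list(network_predict(extra_models[[nm]],
                                                      as_tensor4(xi)))
  }
  dr <- manifest$ensemble$phase_max - manifest$ensemble$phase_min
  rows <- list()
  for (est in names(estimates)) {
    maps <- estimates[[est]]
    for (i in seq_along(truth)) {
      m <- maps[[i]]
      if (calibrate && stats::sd(as.vector(m)) > 0)
        m <- calibrate_phase(m, ref)
      rows[[length(rows) + 1L]] <- data.frame(
        id = te$ids[i], estimator = est,
        pcc = pcc(m, truth[[i]]),
        psnr = psnr(m, truth[[i]], dr),
        ssim = ssim(m, truth[[i]], dr))
    }
  }
  per_image <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per_image, per_image$estimator),
    function(d) data.frame(estimator = d$estimator[1L],
                           mean_pcc = mean(d$pcc), sd_pcc = stats::sd(d$pcc),
                           mean_psnr = mean(d$psnr), sd_psnr = stats::sd(d$psnr),
                           mean_ssim = mean(d$ssim), sd_ssim = stats::sd(d$ssim))))
  summ <- summ[match(names(estimates), summ$estimator), ]
  rownames(summ) <- NULL
  structure(list(per_image = per_image, summary = summ,
                 n_images = length(truth),
                 flux_p = manifest$noise$photons_p, q = bundle$q),
            class = "metrics_record")
}

# the approximant row: for the approximant scheme it is the network input
# itself; for end-to-end it is recomputed from the stored measurement.
te_fhat_or_input <- function(te, manifest, cfg) {
  if (ls_input_field(cfg) == "fhat") return(te$fhat)
  dat <- load_split(manifest, "test", fields = "fhat")
  dat$fhat
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf("<metrics_record> n = %d test images, p = %g photons/pixel, q = %g\n",
              x$n_images, x$flux_p, x$q))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s PCC %.3f +/- %.3f   PSNR %6.3f +/- %.3f dB   SSIM %.3f +/- %.3f\n",
                s$estimator[i], s$mean_pcc[i], s$sd_pcc[i],
                s$mean_psnr[i], s$sd_psnr[i], s$mean_ssim[i], s$sd_ssim[i]))
  }
  invisible(x)
}

#' Write a metrics summary as CSV
#'
#' @param record A `metrics_record`.
#' @param path Output CSV path.
#' @export
write_metrics_csv <- function(record, path) {
  stopifnot(inherits(record, "metrics_record"))
  utils::write.csv(record$summary, path, row.names = FALSE)
  invisible(path)
}

#' Spectral comparison of estimators against ground truth
#'
#' Computes the averaged-PSD cross-section of each estimator's
#' reconstructions and of the ground truth, all normalized to the
#' ground-truth peak, so band depletion (low band for the high network,
#' high band for the low network) shows up directly as a profile deficit.
#'
#' @param estimates Named list; each element a list of reconstruction
#'   matrices (one per test image).
#' @param ground_truth List of ground-truth matrices.
#' @param cut `"diagonal"` or `"radial"`.
#' @return Named list of `psd_profile`s; element `"ground_truth"` first.
#' @export
spectral_comparison <- function(estimates, ground_truth,
                                cut = c("diagonal", "radial")) {
  cut <- match.arg(cut)
  gt_raw <- psd_profile(ground_truth, cut = cut, normalize = FALSE)
  peak <- max(gt_raw$power)
  rescale <- function(p) { p$power <- p$power / peak; p }
  out <- list(ground_truth = rescale(gt_raw))
  for (nm in names(estimates)) {
    out[[nm]] <- rescale(psd_profile(estimates[[nm]], cut = cut,
                                     normalize = FALSE))
  }
  out
}

# band-integrated power of a profile over [fmin, fmax] (cycles/pixel)
band_power <- function(profile, fmin, fmax) {
  keep <- profile$freqs >= fmin & profile$freqs <= fmax
  sum(profile$power[keep])
}
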