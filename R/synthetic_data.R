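# Seeded ensembles of phase objects with power-law spectra, and assembly of
# full simulated datasets (phase, noiseless/noisy intensity, approximant,
# filtered target) with train/validation/test splits and a replayable
# manifest.

#' Generate a seeded ensemble of power-law phase objects
#'
#' Each object is spectrum-shaped Gaussian noise: a white real Gaussian
#' field is Fourier transformed (which guarantees Hermitian symmetry), its
#' coefficients are weighted by `S^(1/2) = (nx^2+ny^2)^(-a/2)` with the DC
#' term zeroed, the result is inverse-transformed, and the image is affinely
#' rescaled to `[phase_min, phase_max]` radians. The ensemble-average radial
#' PSD then follows `(nx^2+ny^2)^(-a)`; `a = 1` emulates the
#' inverse-quadratic spectrum of natural images.
#'
#' @param spec An [object_ensemble_spec()].
#' @return A list of `n_objects` phase matrices (radians).
#' @export
generate_objects <- function(spec) {
  if (!inherits(spec, "object_ensemble_spec"))
    stop("`spec` must be an object_ensemble_spec", call. = FALSE)
  n <- spec$grid_n
  nu <- grid_freqs(n)
  nu2 <- outer(nu^2, nu^2, `+`)
  shape <- nu2^(-spec$psd_exponent_a / 2)
  shape[1L, 1L] <- 0
  with_local_seed(spec$seed, {
    lapply(seq_len(spec$n_objects), function(i) {
      w <- matrix(stats::rnorm(n * n), n, n)
      fld <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n^2
      rng <- range(fld)
      if (rng[2L] == rng[1L]) {          # degenerate flat draw; map to midpoint
        matrix((spec$phase_min + spec$phase_max) / 2, n, n)
      } else {
        spec$phase_min + (fld - rng[1L]) / (rng[2L] - rng[1L]) *
          (spec$phase_max - spec$phase_min)
      }
    })
  })
}

# Largest-remainder split of n items into the given ratios; the train
# bucket absorbs any rounding residue left after remainder allocation.
split_sizes <- function(n, ratios = c(train = 9500, validation = 450, test = 500)) {
  ideal <- n * ratios / sum(ratios)
  base <- floor(ideal)
  left <- n - sum(base)
  if (left > 0) {
    order_rem <- order(ideal - base, decreasing = TRUE)
    base[order_rem[seq_len(left)]] <- base[order_rem[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(base), names(ratios))
}

#' Build a full simulated dataset on disk
#'
#' For every generated object writes the ground-truth phase `f`, the
#' noiseless intensity `g0`, the noisy measurement `g`, the single-iteration
#' approximant `fhat` computed from `g`, and the spectrally filtered target
#' `fp`; splits the records into train/validation/test by largest-remainder
#' rounding of `split_ratios`; and writes a YAML manifest recording every
#' parameter so the dataset can be replayed bit-exactly.
#'
#' Per-object noise seeds are derived deterministically from `noise$seed`
#' (seed + object index), so regenerating with the same manifest parameters
#' reproduces every array.
#'
#' @param spec An [object_ensemble_spec()].
#' @param config An [optical_config()] (its `grid_n` must match `spec`).
#' @param noise A [noise_spec()].
#' @param filter A [spectral_filter()].
#' @param out_dir Output directory (created if missing).
#' @param split_ratios Three positive numbers (train, validation, test);
#'   default 9500:450:500.
#' @return A `dataset_manifest` (invisibly the same list that is written to
#'   `manifest.yaml`).
#' @export
make_dataset <- function(spec, config, noise, filter, out_dir,
                         split_ratios = c(train = 9500, validation = 450, test = 500)) {
  stopifnot(inherits(spec, "object_ensemble_spec"),
            inherits(config, "optical_config"),
            inherits(noise, "noise_spec"),
            inherits(filter, "spectral_filter"))
  if (spec$grid_n != config$grid_n)
    stop("spec$grid_n and config$grid_n disagree", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create out_dir", call. = FALSE)
  objects <- generate_objects(spec)
  n <- spec$n_objects
  sizes <- split_sizes(n, split_ratios)
  split_of <- rep(names(sizes), times = sizes)
  ids <- sprintf("obj%05d", seq_len(n))
  records <- vector("list", n)
  for (i in seq_len(n)) {
    f <- objects[[i]]
    g0 <- forward_intensity(f, config)
    noise_i <- noise_spec(noise$photons_p, noise$gaussian_sigma,
                          noise$seed + i)
    g <- apply_noise(g0, noise_i)
    fhat <- approximant(g, config)
    fp <- apply_filter(f, filter)
    paths <- lapply(c(f = "f", g0 = "g0", g = "g", fhat = "fhat", fp = "fp"),
                    function(tag) file.path(out_dir, sprintf("%s_%s.tsv", ids[i], tag)))
    write_phase_array(f, paths$f)
    write_phase_array(g0, paths$g0)
    write_phase_array(g, paths$g)
    write_phase_array(fhat, paths$fhat)
    write_phase_array(fp, paths$fp)
    records[[i]] <- c(list(id = ids[i], split = split_of[i]),
                      lapply(paths, basename))
  }
  manifest <- list(
    schema_version = 1L,
    created = "synthetic",
    n_objects = n,
    split_sizes = as.list(sizes),
    ensemble = unclass(spec),
    optical = unclass(config)[c("wavelength", "defocus_z", "pixel_pitch",
                                "grid_n", "pad_factor")],
    aperture_na_cycles = config$aperture_na_cycles,
    noise = unclass(noise),
    filter = unclass(filter),
    records = records)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  structure(c(manifest, list(dir = out_dir)), class = "dataset_manifest")
}

#' Load a dataset manifest written by [make_dataset()]
#'
#' @param dir Dataset directory containing `manifest.yaml`.
#' @return A `dataset_manifest`.
#' @export
load_manifest <- function(dir) {
  path <- file.path(dir, "manifest.yaml")
  if (!file.exists(path)) stop("no manifest.yaml in ", dir, call. = FALSE)
  m <- yaml::read_yaml(path)
  structure(c(m, list(dir = dir)), class = "dataset_manifest")
}

#' Load the arrays of one split of a dataset
#'
#' @param manifest A `dataset_manifest`.
#' @param split One of `"train"`, `"validation"`, `"test"`.
#' @param fields Which arrays to load per record (subset of
#'   `c("f", "g0", "g", "fhat", "fp")`).
#' @return A list with `ids` and one list of matrices per requested field.
#' @export
load_split <- function(manifest, split = c("train", "validation", "test"),
                       fields = c("f", "g", "fhat", "fp")) {
  split <- match.arg(split)
  stopifnot(inherits(manifest, "dataset_manifest"))
  recs <- Filter(function(r) r$split == split, manifest$records)
  out <- list(ids = vapply(recs, `[[`, "", "id"))
  for (fld in fields) {
    out[[fld]] <- lapply(recs, function(r)
      read_phase_array(file.path(manifest$dir, r[[fld]])))
  }
  out
}
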