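# Plumbing for the on-disk formats: lossless text arrays for phase maps and
# intensity frames, 16-bit TIFF/PNG export-import for intensity counts, and
# a flat key-value configuration file.

#' Read and write floating-point arrays as plain text
#'
#' Arrays are stored as tab-separated text, one matrix row per line, full
#' double precision (17 significant digits), so a write/read round trip is
#' lossless.
#'
#' @param x A numeric matrix.
#' @param path File path.
#' @return `read_phase_array` returns a numeric matrix;
#'   `write_phase_array` returns `path` invisibly.
#' @export
write_phase_array <- function(x, path) {
  assert_image(x, "x")
  # %.17g guarantees the shortest-or-full representation that round-trips
  # doubles exactly
  lines <- vapply(seq_len(nrow(x)), function(i)
    paste(sprintf("%.17g", x[i, ]), collapse = "\t"), character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_phase_array
#' @export
read_phase_array <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  unname(as.matrix(data.table::fread(path, sep = "\t", header = FALSE)))
}

#' Write / read an intensity frame as a grayscale image
#'
#' Counts are scaled by a recorded gain so the image maximum maps to full
#' scale; the gain is returned (and must be supplied to recover counts).
#' TIFF export is 16-bit (the primary lossy-but-tight format); PNG export
#' is 8-bit. The format is chosen from the file extension.
#'
#' @param g Nonnegative intensity matrix (expected photon counts).
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @return `write_intensity_image` returns the gain (counts per unit of
#'   stored intensity), invisibly; `read_intensity_image` returns a counts
#'   matrix.
#' @export
write_intensity_image <- function(g, path) {
  assert_image(g, "g", nonneg = TRUE)
  gain <- max(g)
  img <- if (gain > 0) g / gain else g
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    png::writePNG(img, path)
  } else stop("unsupported image extension: ", ext, call. = FALSE)
  invisible(gain)
}

#' @rdname write_intensity_image
#' @param gain Counts per unit stored intensity (from the writer).
#' @export
read_intensity_image <- function(path, gain = 1) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else if (ext == "png") png::readPNG(path)
         else stop("unsupported image extension: ", ext, call. = FALSE)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img * gain
}

#' Read and write the flat key-value run configuration
#'
#' A plain YAML mapping with the scalar keys `wavelength_m`, `z_m`,
#' `pixel_pitch_m`, `grid_n`, `pad_factor`, `aperture_cycles_per_m`,
#' `photons_p`, `gaussian_sigma`, `q`, `seed` (missing keys fall back to the
#' package defaults). Returns the three config objects.
#'
#' @param path Path of the configuration file.
#' @return A list with elements `optical`, `noise`, `filter`, `seed`.
#' @export
read_run_config <- function(path) {
  kv <- yaml::read_yaml(path)
  pick <- function(key, default) if (!is.null(kv[[key]])) kv[[key]] else default
  optical <- optical_config(
    wavelength = pick("wavelength_m", 632.8e-9),
    defocus_z = pick("z_m", 0.4),
    pixel_pitch = pick("pixel_pitch_m", 36e-6),
    grid_n = pick("grid_n", 256L),
    aperture_na_cycles = kv[["aperture_cycles_per_m"]],
    pad_factor = pick("pad_factor", 1L))
  noise <- noise_spec(photons_p = pick("photons_p", 1),
                      gaussian_sigma = pick("gaussian_sigma", 0),
                      seed = pick("seed", 1L))
  filter <- spectral_filter(q = pick("q", 0.5))
  list(optical = optical, noise = noise, filter = filter,
       seed = as.integer(pick("seed", 1L)))
}

#' @rdname read_run_config
#' @param optical,noise,filter Config objects to serialize.
#' @param seed Master seed to record.
#' @export
write_run_config <- function(path, optical, noise, filter, seed = 1L) {
  kv <- list(wavelength_m = optical$wavelength, z_m = optical$defocus_z,
             pixel_pitch_m = optical$pixel_pitch, grid_n = optical$grid_n,
             pad_factor = optical$pad_factor,
             aperture_cycles_per_m = optical$aperture_na_cycles,
             photons_p = noise$photons_p,
             gaussian_sigma = noise$gaussian_sigma,
             q = filter$q, seed = as.integer(seed))
  yaml::write_yaml(kv[!vapply(kv, is.null, TRUE)], path)
  invisible(path)
}
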