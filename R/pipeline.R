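# Orchestration: a resumable pipeline running fixtures -> train -> predict
# -> evaluate in one output directory, with every artifact stamped by the
# configuration hash and master seed. The command-line front end in
# inst/cli/lsphase is a thin wrapper over these functions.

config_hash <- function(...) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(lapply(list(...), unclass), tmp)
  unname(tools::md5sum(tmp))
}

pipeline_log <- function(run_dir, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
  message(line)
  cat(line, "\n", file = file.path(run_dir, "run.log"), append = TRUE)
}

#' Run the simulation / training / evaluation pipeline
#'
#' Executes the requested stages in order inside `out_dir`:
#' \describe{
#'   \item{fixtures}{generate the synthetic dataset via [make_dataset()]
#'     (phase, noiseless and noisy intensity, approximant, filtered target,
#'     splits, manifest).}
#'   \item{train}{train DNN-L, DNN-H and DNN-S on the dataset and save the
#'     bundle.}
#'   \item{predict}{write the synthesized reconstruction of every test
#'     image.}
#'   \item{evaluate}{write the metric table (CSV) and the PSD comparison
#'     profiles (two-column text).}
#' }
#' A completed stage whose configuration hash is unchanged is skipped on
#' rerun; a missing upstream artifact raises an error naming the stage to
#' run first.
#'
#' @param out_dir Run directory (created if needed).
#' @param stages Character vector, ordered subset of
#'   `c("fixtures", "train", "predict", "evaluate")`.
#' @param ensemble An [object_ensemble_spec()].
#' @param optical An [optical_config()].
#' @param noise A [noise_spec()].
#' @param filter A [spectral_filter()].
#' @param unet A [unet_spec()].
#' @param train_cfg A [train_config()].
#' @param seed Master seed; fans out to the ensemble, noise and training
#'   seeds (each offset deterministically) unless those specs already carry
#'   non-default seeds you want kept, in which case pass `seed = NULL`.
#' @return Invisibly, a list with the manifest, bundle (if trained) and
#'   metrics (if evaluated).
#' @export
run_pipeline <- function(out_dir,
                         stages = c("fixtures", "train", "predict", "evaluate"),
                         ensemble, optical = optical_config(grid_n = ensemble$grid_n),
                         noise = noise_spec(), filter = spectral_filter(),
                         unet = unet_spec(), train_cfg = train_config(),
                         seed = 1L) {
  known <- c("fixtures", "train", "predict", "evaluate")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "),
         call. = FALSE)
  stages <- known[known %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    ensemble$seed <- seed
    noise <- noise_spec(noise$photons_p, noise$gaussian_sigma, seed + 1000L)
    train_cfg$seed <- seed + 2000L
    unet$seed <- seed + 3000L
  }
  hash <- config_hash(ensemble, optical, noise, filter, unet, train_cfg, seed)
  writeLines(c(paste("config_hash:", hash), paste("master_seed:", seed)),
             file.path(out_dir, "run_info.txt"))
  data_dir <- file.path(out_dir, "dataset")
  bundle_dir <- file.path(out_dir, "bundle")
  result <- list()

  if ("fixtures" %in% stages) {
    stamp <- file.path(data_dir, "config_hash.txt")
    if (dir.exists(data_dir) && file.exists(stamp) &&
        identical(readLines(stamp)[1L], hash)) {
      pipeline_log(out_dir, "fixtures: up to date, skipping")
    } else {
      pipeline_log(out_dir, "fixtures: generating dataset")
      unlink(data_dir, recursive = TRUE)
      make_dataset(ensemble, optical, noise, filter, data_dir)
      writeLines(hash, stamp)
    }
  }
  if (any(c("train", "predict", "evaluate") %in% stages) &&
      !file.exists(file.path(data_dir, "manifest.yaml")))
    stop("no dataset found: run the 'fixtures' stage first", call. = FALSE)
  if (any(c("train", "predict", "evaluate") %in% stages))
    result$manifest <- load_manifest(data_dir)

  if ("train" %in% stages) {
    stamp <- file.path(bundle_dir, "config_hash.txt")
    if (dir.exists(bundle_dir) && file.exists(stamp) &&
        identical(readLines(stamp)[1L], hash)) {
      pipeline_log(out_dir, "train: up to date, skipping")
      result$bundle <- load_bundle(bundle_dir)
    } else {
      pipeline_log(out_dir, "train: DNN-L")
      cfg <- train_cfg; cfg$q <- filter$q
      net_l <- train_dnn_l(result$manifest, unet, cfg)
      pipeline_log(out_dir, "train: DNN-H")
      unet_h <- unet; unet_h$seed <- unet$seed + 1L
      unet_h$residual <- FALSE   # input does not approximate filtered targets
      net_h <- train_dnn_h(result$manifest, unet_h, cfg)
      pipeline_log(out_dir, "train: DNN-S")
      unet_s <- unet; unet_s$seed <- unet$seed + 2L
      net_s <- train_dnn_s(result$manifest, net_l, net_h, unet_s, cfg)
      result$bundle <- ls_bundle(net_l, net_h, net_s, q = filter$q,
                                 scheme = cfg$scheme)
      save_bundle(result$bundle, bundle_dir)
      writeLines(hash, stamp)
    }
  }
  if (any(c("predict", "evaluate") %in% stages) && is.null(result$bundle)) {
    if (!file.exists(file.path(bundle_dir, "bundle.yaml")))
      stop("no trained bundle found: run the 'train' stage first", call. = FALSE)
    result$bundle <- load_bundle(bundle_dir)
  }

  if ("predict" %in% stages) {
    pipeline_log(out_dir, "predict: reconstructing test split")
    cfg <- result$bundle$model_l$config
    te <- load_split(result$manifest, "test", fields = ls_input_field(cfg))
    recon <- predict(result$bundle, te[[ls_input_field(cfg)]])
    pred_dir <- file.path(out_dir, "predictions")
    dir.create(pred_dir, showWarnings = FALSE)
    for (i in seq_along(recon))
      write_phase_array(recon[[i]],
                        file.path(pred_dir, paste0(te$ids[i], "_fhat_ls.tsv")))
  }

  if ("evaluate" %in% stages) {
    pipeline_log(out_dir, "evaluate: metrics and PSD profiles")
    result$metrics <- evaluate_bundle(result$bundle, result$manifest)
    write_metrics_csv(result$metrics, file.path(out_dir, "metrics.csv"))
    cfg <- result$bundle$model_l$config
    te <- load_split(result$manifest, "test",
                     fields = unique(c(ls_input_field(cfg), "f", "fhat")))
    comp <- ls_component_outputs(result$bundle, te[[ls_input_field(cfg)]])
    prof <- spectral_comparison(
      list(approximant = te$fhat, dnn_l = comp$dnn_l,
           dnn_h = comp$dnn_h, dnn_s = comp$dnn_s),
      te$f)
    for (nm in names(prof))
      utils::write.table(
        data.frame(freq = prof[[nm]]$freqs, power = prof[[nm]]$power),
        file.path(out_dir, sprintf("psd_%s.tsv", nm)),
        sep = "\t", row.names = FALSE, quote = FALSE)
    print(result$metrics)
  }
  invisible(result)
}
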