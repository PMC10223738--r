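#' Default run configuration
#'
#' A fully serializable description of one pipeline run, with every
#' reference default pre-filled: wavelength 632.8 nm, 5 layers, 10 mm
#' spacing, 200 (detection) / 400 (classification) neurons per side, batch
#' 64, learning rates 0.005/0.001, 120 epochs, split 8:17:75, scan
#' threshold 0.5. Override any field via the `...` or a YAML file
#' ([read_run_config()]).
#'
#' @param task One of `"gen-data"`, `"detect-train"`, `"classify-train"`,
#'   `"scan"`, `"eval"`, `"crossval"`.
#' @param seed Master seed; all randomness in the run derives from it.
#' @param out_dir Output directory for artifacts.
#' @param ... Named overrides of the nested defaults (replaced wholesale).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(task = "detect-train", seed = 1L, out_dir = "odnn_out",
                       ...) {
  cfg <- list(
    task = task, seed = as.integer(seed), out_dir = out_dir,
    network = list(network_size = 200L, num_layers = 5L, dz = 10e-3,
                   input_size = 50L, pitch = 4e-6, wavelength = 632.8e-9,
                   modulation_mode = "phase", pad_factor = 2L,
                   readout_mode = "magnitude"),
    hyper = list(batch_size = 64L, learning_rate = NULL, epochs = 120L,
                 optimizer = "adam", train_bias = TRUE, alpha = 1),
    split = list(ratios = c(8, 17, 75)),
    scan = list(window = 50L, stride = 10L, threshold = 0.5,
                match_radius = 25),
    data = list(n_pos = 100L, n_neg = 100L),
    paths = list(dataset = NULL, checkpoint = NULL, slice_prefix = NULL),
    crossval = list(k = 10L)
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- .merge_cfg(cfg[[nm]], dots[[nm]])
  class(cfg) <- "run_config"
  cfg
}

.merge_cfg <- function(base, override) {
  if (is.list(base) && is.list(override)) {
    for (nm in names(override)) base[[nm]] <- .merge_cfg(base[[nm]], override[[nm]])
    base
  } else override
}

#' Read a run configuration from YAML
#'
#' Missing fields fall back to the [run_config()] defaults.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("task", "seed", "out_dir"))]
  rest <- y[setdiff(names(y), c("task", "seed", "out_dir"))]
  do.call(run_config, c(args, rest))
}

.cfg_network <- function(cfg, task) {
  nc <- cfg$network
  layout <- default_detector_layout(nc$network_size, nc$readout_mode)
  network_config(network_size = nc$network_size, num_layers = nc$num_layers,
                 dz = nc$dz, input_size = nc$input_size, pitch = nc$pitch,
                 wavelength = nc$wavelength, detector_layout = layout,
                 modulation_mode = nc$modulation_mode,
                 pad_factor = nc$pad_factor)
}

.cfg_hyper <- function(cfg) {
  h <- cfg$hyper
  hyperparams(batch_size = h$batch_size, learning_rate = h$learning_rate,
              epochs = h$epochs, seed = .child_seed(cfg$seed, "train"),
              optimizer = h$optimizer, train_bias = isTRUE(h$train_bias),
              alpha = h$alpha)
}

# Write the run manifest: effective config including every defaulted
# decision (readout mode, detector geometry, stride) and derived seeds.
.write_manifest <- function(cfg, extra = list()) {
  man <- list(schema = "odnn-manifest", schema_version = 1L,
              config = unclass(cfg),
              derived_seeds = list(train = .child_seed(cfg$seed, "train"),
                                   split = .child_seed(cfg$seed, "split"),
                                   data = .child_seed(cfg$seed, "data"),
                                   init = .child_seed(cfg$seed, "init")))
  man <- c(man, extra)
  jsonlite::write_json(man, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(man)
}

#' Execute a configured pipeline run
#'
#' Dispatches on `config$task`, writes every artifact (dataset directory,
#' checkpoint, per-epoch history CSV, metrics CSV, candidate maps) plus a
#' JSON manifest recording the effective configuration and derived seeds
#' under `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return A list of produced artifacts (task dependent), invisibly.
#' @export
run_task <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- switch(config$task,
    "gen-data" = .task_gen_data(config),
    "detect-train" = .task_train(config, "detection"),
    "classify-train" = .task_train(config, "classification"),
    "scan" = .task_scan(config),
    "eval" = .task_eval(config),
    "crossval" = .task_crossval(config),
    stop("unknown task: ", config$task))
  invisible(out)
}

.task_gen_data <- function(cfg) {
  task <- if (!is.null(cfg$data$task)) cfg$data$task else "detection"
  ds <- gen_dataset(cfg$data$n_pos, cfg$data$n_neg, .cfg_params(cfg), task,
                    seed = .child_seed(cfg$seed, "data"))
  dsdir <- file.path(cfg$out_dir, "dataset")
  write_dataset(ds, dsdir)
  .write_manifest(cfg, list(artifacts = list(dataset = dsdir)))
  list(dataset = ds, dir = dsdir)
}

.cfg_params <- function(cfg) {
  pp <- cfg$data$params
  if (is.null(pp)) patch_params() else do.call(patch_params, pp)
}

.load_or_gen <- function(cfg, task) {
  if (!is.null(cfg$paths$dataset)) read_dataset(cfg$paths$dataset)
  else gen_dataset(cfg$data$n_pos, cfg$data$n_neg, .cfg_params(cfg), task,
                   seed = .child_seed(cfg$seed, "data"))
}

.task_train <- function(cfg, task) {
  ds <- .load_or_gen(cfg, task)
  sp <- split_cases(unique(ds$case_ids), cfg$split$ratios,
                    seed = .child_seed(cfg$seed, "split"))
  pick <- function(ids) {
    idx <- which(ds$case_ids %in% ids)
    list(images = ds$images[idx], labels = ds$labels[idx])
  }
  net <- d2nn_network(.cfg_network(cfg, task),
                      seed = .child_seed(cfg$seed, "init"))
  fit <- train_d2nn(net, pick(sp$training), pick(sp$validation),
                    .cfg_hyper(cfg), task)
  ckpt <- file.path(cfg$out_dir, "checkpoint.rds")
  save_network(fit$network, ckpt)
  utils::write.csv(fit$history, file.path(cfg$out_dir, "history.csv"),
                   row.names = FALSE)
  te <- pick(sp$test)
  ev <- evaluate_patches(fit$network, te$images, fit$b[1], fit$b[2])
  met <- confusion_and_metrics(ev$pred, te$labels)
  write_metrics_csv(stats::setNames(list(met), paste0(task, " (test set)")),
                    file.path(cfg$out_dir, "metrics.csv"))
  .write_manifest(cfg, list(artifacts = list(checkpoint = ckpt),
                            learned_bias = as.list(fit$b),
                            test_cases = sp$test))
  list(fit = fit, metrics = met, split = sp)
}

.task_eval <- function(cfg) {
  net <- load_network(cfg$paths$checkpoint)
  ds <- .load_or_gen(cfg, "detection")
  ev <- evaluate_patches(net, ds$images)
  met <- confusion_and_metrics(ev$pred, ds$labels)
  write_metrics_csv(list(eval = met), file.path(cfg$out_dir, "metrics.csv"))
  .write_manifest(cfg)
  list(metrics = met, scores = ev)
}

.task_scan <- function(cfg) {
  net <- load_network(cfg$paths$checkpoint)
  if (!is.null(cfg$paths$slice_prefix)) {
    sl <- read_slice(cfg$paths$slice_prefix)
  } else {
    sl <- gen_slice(.cfg_params(cfg), seed = .child_seed(cfg$seed, "data"))
  }
  sc <- scan_config(cfg$scan$window, cfg$scan$stride, cfg$scan$threshold)
  cmap <- scan_slice(net, sl$image, sc)
  export_candidate_map(cmap, file.path(cfg$out_dir, "scan"))
  res <- evaluate_scan(cmap, sl$truth_centers, cfg$scan$match_radius)
  .write_manifest(cfg, list(scan_result = res))
  list(candidates = cmap, result = res)
}

.task_crossval <- function(cfg) {
  task <- if (!is.null(cfg$data$task)) cfg$data$task else "detection"
  ds <- .load_or_gen(cfg, task)
  folds <- kfold_cases(unique(ds$case_ids), cfg$crossval$k,
                       seed = .child_seed(cfg$seed, "split"))
  accs <- vapply(seq_along(folds), function(i) {
    te_idx <- which(ds$case_ids %in% folds[[i]])
    tr_idx <- setdiff(seq_along(ds$case_ids), te_idx)
    net <- d2nn_network(.cfg_network(cfg, task),
                        seed = .child_seed(cfg$seed, paste0("init", i)))
    fit <- train_d2nn(net,
                      list(images = ds$images[tr_idx], labels = ds$labels[tr_idx]),
                      list(images = list(), labels = integer(0)),
                      .cfg_hyper(cfg), task)
    ev <- evaluate_patches(fit$network, ds$images[te_idx], fit$b[1], fit$b[2])
    mean(ev$pred == ds$labels[te_idx])
  }, numeric(1))
  utils::write.csv(data.frame(fold = seq_along(accs), accuracy = accs),
                   file.path(cfg$out_dir, "crossval.csv"), row.names = FALSE)
  .write_manifest(cfg, list(fold_accuracies = accs, mean_accuracy = mean(accs)))
  list(fold_accuracies = accs, mean_accuracy = mean(accs))
}
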