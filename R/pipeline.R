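#' Assemble a pipeline run configuration
#'
#' One configuration object governs an end-to-end segmentation run:
#' normalize, predict the three channels, post-process, instance-segment,
#' mesh and analyze. It round-trips through YAML unchanged (models are
#' referenced by checkpoint path).
#'
#' @param input Path to the tomogram stack (TIFF/MRC), or a
#'   [tomogram_stack()] passed directly to [run_pipeline()].
#' @param models Named list (`cell`, `vacuole`, `droplet`) of trained
#'   [unet_build()] models or paths to `.rds` checkpoints.
#' @param out_dir Output directory for artifacts and the provenance log.
#' @param condition Condition label recorded in droplet records.
#' @param size In-plane size for preprocessing (power-of-two; 512 at full
#'   scale).
#' @param voxel_size_nm Voxel size override.
#' @param post Per-channel [post_options()] (or one for all).
#' @param smooth_iters Mesh smoothing iterations.
#' @param seed Seed recorded in the log (all pipeline stages after
#'   training are deterministic).
#' @return A list of class `run_config`.
#' @export
run_config <- function(input, models, out_dir = tempfile("liposeg_run"),
                       condition = "sample", size = 512,
                       voxel_size_nm = NULL,
                       post = list(cell = post_options(min_volume = 1000),
                                   vacuole = post_options(min_volume = 1000),
                                   droplet = post_options(min_volume = 50)),
                       smooth_iters = 10, seed = 1) {
  structure(list(input = input, models = models, out_dir = out_dir,
                 condition = condition, size = size,
                 voxel_size_nm = voxel_size_nm, post = post,
                 smooth_iters = smooth_iters, seed = seed),
            class = "run_config")
}

load_channel_model <- function(models, channel) {
  m <- models[[channel]]
  if (is.null(m))
    stop2("no model checkpoint configured for channel '", channel, "'")
  if (is.character(m)) {
    if (!file.exists(m))
      stop2("model checkpoint for channel '", channel, "' not found: ", m)
    m <- readRDS(m)
  }
  if (!inherits(m, "unet"))
    stop2("checkpoint for channel '", channel, "' is not a unet model")
  m
}

#' Run the full segmentation and analysis pipeline
#'
#' Executes normalize -> predict (cell, vacuole, droplet) -> post-process
#' -> instance segmentation -> mesh -> droplet analysis, writing one
#' line-delimited JSON provenance entry per stage. All stages after
#' training are deterministic, so rerunning a config reproduces the
#' outputs bitwise.
#'
#' @param config A [run_config()].
#' @return A list with the normalized stack, per-channel probability and
#'   label volumes, meshes, the droplet record table and the path of the
#'   provenance log.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "provenance.jsonl")
  if (file.exists(log_path)) file.remove(log_path)
  log_stage <- function(stage, ...) {
    entry <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                    seed = config$seed), list(...))
    cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE)
  }
  stack <- if (inherits(config$input, "tomogram_stack")) config$input
           else read_stack(config$input, voxel_size_nm = config$voxel_size_nm)
  log_stage("load", id = stack$id, dim = dim(stack$voxels))
  norm <- preprocess_stack(stack, size = config$size)
  log_stage("normalize", size = config$size)
  channels <- c("cell", "vacuole", "droplet")
  probs <- list()
  for (ch in channels) {
    model <- load_channel_model(config$models, ch)
    probs[[ch]] <- predict_stack(norm, model)
    log_stage("predict", channel = ch, params = unet_param_count(model))
  }
  pp <- postprocess_channels(probs, config$post)
  log_stage("postprocess", steps = nrow(pp$log))
  meshes <- list()
  for (ch in channels) {
    meshes[[ch]] <- labels_to_meshes(pp$labels[[ch]], norm$voxel_size_nm,
                                     smooth_iters = config$smooth_iters,
                                     channel = ch)
    log_stage("mesh", channel = ch, n = length(meshes[[ch]]))
  }
  records <- analyze_droplets(meshes$droplet, meshes$vacuole,
                              condition = config$condition)
  log_stage("analyze", n_droplets = nrow(records),
            n_consumed = sum(records$consumed, na.rm = TRUE))
  write_droplet_table(records, file.path(config$out_dir, "droplets.csv"))
  list(stack = norm, probs = probs, labels = pp$labels, meshes = meshes,
       records = records, log = log_path)
}

#' Read or write a pipeline configuration as YAML
#'
#' @param config A [run_config()] (models given as checkpoint paths).
#' @param path YAML file path.
#' @return `write_run_config` returns `path`; `read_run_config` the
#'   `run_config`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$post <- lapply(x$post, unclass)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$post <- lapply(x$post, function(p) do.call(post_options, p))
  do.call(run_config, x)
}
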