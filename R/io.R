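# Plain-text persistence: model checkpoints (JSON), manifests (CSV), round
# histories (JSON-lines + summary CSV), and YAML experiment configuration.

#' Save a model checkpoint
#'
#' Single-file JSON archive of the ordered name -> tensor mapping plus the
#' embedded configuration; full double precision, round-trips losslessly.
#'
#' @param model An `lsnet` object (or any list with `cfg` and `params`).
#' @param path Output file path.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(
    config = unclass(model$cfg),
    params = lapply(model$params, function(p)
      list(dim = dim(p) %||% length(p), data = as.vector(p))))
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE), path)
}

#' Load a model checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return An `lsnet` object.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  cfgl <- obj$config
  stages <- lapply(cfgl$stages, as.list)
  cfg <- lsnet_config(cfgl$stem_channels, stages, cfgl$num_classes,
                      cfgl$input_size, cfgl$activation, cfgl$normalization)
  params <- lapply(obj$params, function(e) {
    v <- as.numeric(e$data)
    if (length(e$dim) > 1) dim(v) <- e$dim
    v
  })
  structure(list(cfg = cfg, params = params), class = "lsnet")
}

#' Write a dataset manifest
#' @param manifest Data frame with `path`, `label`, `client_id`.
#' @param path Output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
}

#' Read a dataset manifest
#' @param path Manifest CSV with columns `path`, `label`, `client_id`.
#' @return Data frame.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("path", "label", "client_id") %in% names(df)))
  if (anyDuplicated(df$path)) stop("manifest paths must be unique")
  df
}

#' Write a round history
#'
#' Emits one JSON object per round to `<out>/rounds.jsonl`, a per-round
#' summary to `<out>/summary.csv`, and the per-round client weight trace to
#' `<out>/weights.csv`.
#'
#' @param history An `fl_history` from [run_federated()].
#' @param out Output directory (created if needed).
#' @export
write_round_history <- function(history, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  lines <- vapply(history$rounds, function(lg)
    as.character(jsonlite::toJSON(list(
      round = lg$round, participants = lg$participants,
      local_losses = lg$local_losses, weights = as.numeric(lg$weights),
      metrics = lg$metrics), digits = NA, auto_unbox = TRUE)),
    character(1))
  writeLines(lines, file.path(out, "rounds.jsonl"))
  utils::write.csv(summarize_history(history),
                   file.path(out, "summary.csv"), row.names = FALSE)
  wt <- do.call(rbind, lapply(history$rounds, function(lg)
    data.frame(round = lg$round,
               client_id = as.integer(sub("client", "", names(lg$weights))),
               weight = as.numeric(lg$weights))))
  utils::write.csv(wt, file.path(out, "weights.csv"), row.names = FALSE)
}

#' Load an experiment configuration from YAML
#'
#' Recognized top-level blocks: `model` (fields of [lsnet_config()], or
#' `preset: micro`), `federation` (fields of [fl_config()]), `weighting`
#' (fields of [weighting_config()]), and `data` (fields of
#' [synthetic_spec()] plus `partition` fields of [partition_spec()] and
#' `sensor_heterogeneity: true/false`).
#'
#' @param path YAML file path.
#' @return List with `model`, `federation`, `weighting`, `data` entries.
#' @export
load_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  out <- list()
  m <- y$model %||% list(preset = "micro")
  if (identical(m$preset, "micro")) {
    out$model <- lsnet_micro_config(
      num_classes = m$num_classes %||% (y$data$num_classes %||% 3L),
      input_size = m$input_size %||% (y$data$image_size %||% 32L))
  } else if (identical(m$preset, "table")) {
    out$model <- lsnet_table_config(num_classes = m$num_classes %||% 10L)
  } else {
    out$model <- lsnet_config(
      stem_channels = m$stem_channels, stages = m$stages,
      num_classes = m$num_classes,
      input_size = m$input_size %||% c(224L, 224L),
      activation = m$activation %||% "gelu",
      normalization = m$normalization %||% "layernorm")
  }
  f <- y$federation %||% list()
  out$federation <- do.call(fl_config, f)
  w <- y$weighting %||% list()
  out$weighting <- do.call(weighting_config, w)
  d <- y$data %||% list()
  part <- d$partition %||% list()
  out$data <- list(
    spec = synthetic_spec(
      num_classes = d$num_classes %||% 3L,
      image_size = d$image_size %||% 32L,
      n_total = d$n_total %||% 150L,
      imbalance = d$imbalance %||% "uniform",
      seed = d$seed %||% 1L),
    partition = partition_spec(
      num_clients = out$federation$num_clients,
      mode = part$mode %||% "iid",
      dirichlet_alpha = part$dirichlet_alpha %||% 0.5,
      seed = part$seed %||% (d$seed %||% 1L)),
    sensor_heterogeneity = isTRUE(d$sensor_heterogeneity))
  out
}
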