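## Flat YAML configuration files mirroring the model and training configs.
## Unknown keys error; absent keys keep the full-scale defaults.

#' Load a model + training configuration from a YAML file
#'
#' The file is a flat key/value mapping whose keys are the arguments of
#' [model_config()], [swin_config()] (prefixed `swin_`), and
#' [train_config()]. All defaults are the full-scale values.
#'
#' @param path YAML file path.
#' @param num_classes class count (required unless present in the file).
#' @return list with elements `model` and `train`.
#' @export
load_config <- function(path, num_classes = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  swin_keys <- names(formals(swin_config))
  model_keys <- setdiff(names(formals(model_config)), "swin")
  train_keys <- names(formals(train_config))
  swin_args <- list()
  model_args <- list()
  train_args <- list()
  for (key in names(raw)) {
    if (startsWith(key, "swin_") && substring(key, 6) %in% swin_keys) {
      swin_args[[substring(key, 6)]] <- raw[[key]]
    } else if (key %in% model_keys) {
      model_args[[key]] <- raw[[key]]
    } else if (key %in% train_keys) {
      train_args[[key]] <- raw[[key]]
    } else {
      stop(sprintf("unknown configuration key '%s' in %s", key, path),
           call. = FALSE)
    }
  }
  if (!is.null(num_classes)) model_args$num_classes <- num_classes
  model_args$swin <- do.call(swin_config, swin_args)
  list(model = do.call(model_config, model_args),
       train = do.call(train_config, train_args))
}
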