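# Run configuration: one nested list holding every stage's parameters, with
# defaults equal to the published values where one is printed and to the
# documented package choices otherwise. YAML round-trip for the command-line
# driver.

#' Default run configuration
#'
#' @param seed master seed; stages derive their own seeds from it.
#' @return nested list with blocks `preprocess`, `channels`, `unet`, `loss`,
#'   `train`, `threshold`, `postprocess`, `seed`.
#' @export
defaultConfig <- function(seed = 1L) {
  list(
    preprocess = list(claheClip = 2, claheTiles = c(8, 8), gamma = 1.2),
    channels = list(
      list(channel = 1, closeRadius = 11),
      list(channel = 2, l = 10.8, s = 1.9, nDirs = 8, closeRadius = 11),
      list(channel = 3, l = 5, s = 0.1, nDirs = 18, closeRadius = 11)
    ),
    unet = list(base = 64, side = 576, slope = 0.01),
    loss = list(lambda = 0.5, eps = 1e-7),
    train = list(epochs = 30, batchSize = 2, momentum = 0.9, weightDecay = 0,
                 valFraction = 0.1, augment = TRUE),
    threshold = list(b = -15, window = c(15, 15)),
    postprocess = list(minSize = 25),
    metrics = list(alpha = 2, beta = 2),
    seed = as.integer(seed)
  )
}

#' Read / write a run configuration as YAML
#' @param cfg nested configuration list.
#' @param path YAML file path.
#' @return `readConfig()`: configuration list merged over the defaults.
#' @export
writeConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  mergeConfig(defaultConfig(), user)
}

mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(user[[nm]]))) {
      base[[nm]] <- mergeConfig(base[[nm]], user[[nm]])
    } else base[[nm]] <- user[[nm]]
  }
  base
}

#' Save / load a trained model
#'
#' Serializes the model together with a digest of its architecture so a
#' checkpoint cannot silently be loaded into a different wiring.
#'
#' @param model a [UNetModel-class].
#' @param path file path (`.rds`).
#' @return `loadModel()`: the model.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(spec = model@spec, params = model@params,
               buffers = model@buffers, seed = model@seed,
               specHash = specHash(model@spec)), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  x <- readRDS(path)
  if (!identical(x$specHash, specHash(x$spec)))
    stop("checkpoint architecture digest mismatch: ", path)
  new("UNetModel", spec = x$spec, params = x$params, buffers = x$buffers,
      seed = x$seed)
}

specHash <- function(spec) {
  paste(c(spec$encoder, spec$decoder, spec$side), collapse = "-")
}
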