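# Model persistence: one self-describing JSON file with architecture,
# weights, scalers, permutation, seeds and history — sufficient to
# reproduce scores bit-for-bit.

#' Save a trained model to JSON
#'
#' @param model a `br_model`.
#' @param path output path (`.json`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "br_model"))
  pack_weights <- function(w) lapply(w$layers, function(l) {
    list(W = l$W, b = l$b)
  })
  obj <- list(
    format = "balanceAD/br_model/1",
    arch = list(sizes = model$arch$sizes,
                activations = model$arch$activations,
                use_bias = model$arch$use_bias),
    weights = pack_weights(model$weights),
    final_weights = pack_weights(model$final_weights),
    alpha = model$alpha, beta = model$beta, gamma = model$gamma,
    best_epoch = model$best_epoch, best_mse = model$best_mse,
    reason = model$reason,
    rows = model$rows, test_rows = model$test_rows,
    permutation = model$permutation,
    scaler = if (!is.null(model$scaler)) {
      list(columns = names(model$scaler$min),
           min = unname(model$scaler$min), max = unname(model$scaler$max),
           constant = unname(model$scaler$constant))
    },
    config = unclass(model$config),
    history = model$history
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Load a trained model saved by [save_model()]
#'
#' @param path JSON path.
#' @return a `br_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "balanceAD/br_model/1")) {
    stopf("not a balanceAD model file: %s", path)
  }
  arch <- mlp_architecture(obj$arch$sizes, obj$arch$activations,
                           obj$arch$use_bias)
  unpack <- function(ws) {
    layers <- vector("list", length(arch$sizes) - 1)
    for (l in seq_along(layers)) {
      # simplifyVector folds the layer list into a frame of list-columns
      Wl <- if (is.data.frame(ws)) ws$W[[l]] else ws[[l]]$W
      bl <- if (is.data.frame(ws)) ws$b[[l]] else ws[[l]]$b
      layers[[l]] <- list(W = matrix(as.numeric(Wl),
                                     arch$sizes[l], arch$sizes[l + 1]),
                          b = as.numeric(bl))
    }
    structure(list(layers = layers, arch = arch), class = "mlp_weights")
  }
  scaler <- if (!is.null(obj$scaler)) {
    nm <- as.character(unlist(obj$scaler$columns))
    structure(list(min = stats::setNames(unlist(obj$scaler$min), nm),
                   max = stats::setNames(unlist(obj$scaler$max), nm),
                   constant = stats::setNames(
                     as.logical(unlist(obj$scaler$constant)), nm)),
              class = "minmax_scaler")
  }
  cfg <- do.call(train_config, obj$config[setdiff(names(obj$config),
                                                  character())])
  structure(list(
    weights = unpack(obj$weights), final_weights = unpack(obj$final_weights),
    arch = arch, alpha = obj$alpha, beta = obj$beta, gamma = obj$gamma,
    best_epoch = obj$best_epoch, best_mse = obj$best_mse,
    history = as.data.frame(obj$history), rows = as.integer(obj$rows),
    test_rows = as.integer(obj$test_rows),
    permutation = as.integer(obj$permutation),
    scaler = scaler, config = cfg, reason = obj$reason
  ), class = "br_model")
}
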