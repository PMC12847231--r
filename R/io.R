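# Plain-text (JSON) checkpoints for trained compressors. Configurations and
# weight matrices round-trip exactly at full double precision.

.mlp_to_list <- function(mlp) {
  list(W = mlp$W, b = mlp$b, widths = mlp$widths,
       out_activation = mlp$out_activation)
}

.mlp_from_list <- function(x) {
  as_mat <- function(w) {
    if (is.matrix(w)) w else do.call(rbind, lapply(w, as.numeric))
  }
  list(W = lapply(x$W, as_mat),
       b = lapply(x$b, as.numeric),
       widths = as.integer(x$widths),
       out_activation = isTRUE(x$out_activation))
}

#' Save a trained compressor as a JSON checkpoint
#'
#' Serializes a fitted [fit_mdn_compressor()] or [fit_posterior_mean_net()]
#' model (or a bare `compressor_state`) with its architecture configuration
#' and all weights to a single JSON file at full double precision.
#'
#' @param object the model to save.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(object, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    .stopf("checkpoints require the jsonlite package")
  payload <- if (inherits(object, "epe_mdn")) {
    list(type = "epe_mdn",
         compressor_config = unclass(object$compressor_config),
         mdn_config = unclass(object$mdn_config),
         compressor_mlps = lapply(object$compressor$mlps, .mlp_to_list),
         head_mlps = lapply(object$head$mlps, .mlp_to_list),
         p = object$p, best_val = object$best_val, epochs = object$epochs)
  } else if (inherits(object, "posterior_mean_net")) {
    list(type = "posterior_mean_net",
         compressor_config = unclass(object$compressor_config),
         compressor_mlps = lapply(object$compressor$mlps, .mlp_to_list),
         p = object$p, best_val = object$best_val, epochs = object$epochs)
  } else if (inherits(object, "compressor_state")) {
    list(type = "compressor_state",
         compressor_config = unclass(object$config),
         compressor_mlps = lapply(object$mlps, .mlp_to_list))
  } else .stopf("cannot checkpoint objects of class %s", class(object)[1L])
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

.rebuild_compressor <- function(cfg_list, mlps_list) {
  cfg <- do.call(compressor_config, cfg_list[c(
    "kind", "input_dim", "hidden", "output_dim", "gin_epsilon",
    "gin_layers", "mlp_hidden", "feature_dim")])
  structure(list(config = cfg, mlps = lapply(mlps_list, .mlp_from_list)),
            class = "compressor_state")
}

#' Load a JSON checkpoint
#'
#' @param path file written by [save_checkpoint()].
#' @return The reconstructed model, with `predict()`/`simulate()` methods
#'   working as for the original fit (training history is not preserved).
#' @export
load_checkpoint <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    .stopf("checkpoints require the jsonlite package")
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  comp <- .rebuild_compressor(x$compressor_config, x$compressor_mlps)
  switch(x$type,
    compressor_state = comp,
    posterior_mean_net = structure(
      list(compressor = comp, history = NULL, best_val = x$best_val,
           epochs = x$epochs, p = x$p, compressor_config = comp$config),
      class = "posterior_mean_net"),
    epe_mdn = {
      mcfg <- mdn_config(x$mdn_config$family, x$mdn_config$k,
                         lo = x$mdn_config$lo, hi = x$mdn_config$hi,
                         hidden = x$mdn_config$hidden)
      head <- structure(
        list(config = mcfg,
             mlps = lapply(x$head_mlps, .mlp_from_list),
             p = x$p, q = comp$config$output_dim),
        class = "mdn_head_state")
      structure(list(compressor = comp, head = head, history = NULL,
                     best_val = x$best_val, epochs = x$epochs, p = x$p,
                     compressor_config = comp$config, mdn_config = mcfg),
                class = "epe_mdn")
    },
    .stopf("unknown checkpoint type %s", x$type))
}
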