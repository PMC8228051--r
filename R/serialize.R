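#' Save / load a DBN model as a JSON archive
#'
#' A single portable JSON file holding every layer's matrices with shape
#' metadata, the softmax parameters, and the model dimensions. The round
#' trip preserves all parameters to full double precision.
#'
#' @param model A `dbn_model`.
#' @param path File path (conventionally `.json`).
#' @export
save_dbn <- function(model, path) {
  stopifnot(inherits(model, "dbn_model"))
  enc <- function(m) list(dim = dim(m), data = as.vector(m))
  payload <- list(
    format = "vegdbn-dbn",
    version = 1L,
    feature_dim = model$feature_dim,
    n_classes = model$n_classes,
    depth = length(model$layers),
    layers = lapply(model$layers, function(l)
      list(W = enc(l$W), b = l$b, c = l$c)),
    softmax_W = enc(model$softmax_W),
    softmax_b = model$softmax_b)
  # I(17) = 17 significant digits, enough for an exact double round trip
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_dbn
#' @return `load_dbn` returns the reconstructed `dbn_model`.
#' @export
load_dbn <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (is.null(p$format) || p$format != "vegdbn-dbn")
    stop("not a vegdbn model archive", call. = FALSE)
  dec <- function(e) matrix(as.numeric(e$data), nrow = e$dim[1], ncol = e$dim[2])
  layers <- lapply(p$layers, function(l)
    structure(list(W = dec(l$W), b = as.numeric(l$b), c = as.numeric(l$c)),
              class = "rbm_params"))
  model <- dbn_model(layers, n_classes = p$n_classes)
  model$softmax_W <- dec(p$softmax_W)
  model$softmax_b <- as.numeric(p$softmax_b)
  model
}
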