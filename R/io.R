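# Model checkpoints as JSON: every array is stored with its dimensions so a
# checkpoint round-trips exactly (text-based, diffable, dependency-light).

ser_array <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.matrix(x) || is.array(x)) list(dim = dim(x), data = as.vector(x))
  else list(dim = NULL, data = as.vector(x))
}

deser_array <- function(s) {
  if (is.null(s)) return(NULL)
  x <- as.numeric(unlist(s$data))
  if (!is.null(s$dim) && length(s$dim)) {
    dm <- as.integer(unlist(s$dim))
    if (length(dm) == 2L) x <- matrix(x, dm[1], dm[2]) else dim(x) <- dm
  }
  x
}

ser_csscrbm <- function(p) {
  list(w = ser_array(p$w), b = ser_array(p$b), c = ser_array(p$c),
       log_a = ser_array(log(p$a)), sigma = p$sigma, pool = p$pool,
       pad = p$pad)
}

deser_csscrbm <- function(s) {
  csscrbm_params(deser_array(s$w), deser_array(s$b), deser_array(s$c),
                 exp(deser_array(s$log_a)), sigma = as.numeric(s$sigma),
                 pool = as.integer(s$pool), pad = as.integer(s$pad))
}

#' Save a model checkpoint as JSON
#' @param model a [seizcast_model()]
#' @param path output file
#' @export
save_model <- function(model, path) {
  obj <- list(
    cfg = model$cfg$layers, input_dim = model$input_dim,
    n_classes = model$n_classes, attention = model$attention,
    norm = model$norm, noise_scale = model$noise_scale,
    stack = lapply(model$stack, ser_csscrbm),
    attn = if (model$attention) lapply(model$attn, ser_array),
    head = lapply(model$head, ser_array))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a model checkpoint
#' @param path JSON checkpoint from [save_model()]
#' @export
load_model <- function(path) {
  s <- jsonlite::read_json(path)
  cfg <- stack_config(lapply(s$cfg, function(ly)
    list(K = as.integer(ly$K), k = as.integer(ly$k), pad = as.integer(ly$pad),
         pool = as.integer(ly$pool),
         lambda = if (is.null(ly$lambda)) NULL else as.numeric(ly$lambda))))
  model <- seizcast_model(cfg, input_dim = as.integer(unlist(s$input_dim)),
                          n_classes = as.integer(s$n_classes),
                          attention = isTRUE(s$attention),
                          norm = s$norm, noise_scale = s$noise_scale)
  model$stack <- lapply(s$stack, deser_csscrbm)
  if (model$attention) {
    model$attn <- lapply(s$attn, deser_array)
  }
  model$head <- lapply(s$head, deser_array)
  model
}

#' Save a pretrained layer stack as JSON
#' @export
save_stack <- function(stack, path) {
  jsonlite::write_json(lapply(stack, ser_csscrbm), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Load a pretrained layer stack
#' @export
load_stack <- function(path) {
  lapply(jsonlite::read_json(path), deser_csscrbm)
}
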