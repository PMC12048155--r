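# Portable checkpoints ----------------------------------------------------

#' Save a trained denoiser to a portable JSON checkpoint
#'
#' Writes a single JSON document holding a manifest (configurations, token
#' vocabulary hash, replacement distribution, loss trace) and every
#' parameter array with its dimensions, so checkpoints are plain text and
#' loadable anywhere.
#'
#' @param model An `egnn_denoiser`.
#' @param path Output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  encode_arrays <- function(p) {
    if (is.list(p)) {
      lapply(p, encode_arrays)
    } else {
      list(dim = if (is.null(dim(p))) length(p) else dim(p),
           data = as.numeric(p))
    }
  }
  payload <- list(
    manifest = list(
      format = "structvep-checkpoint-v1",
      egnn_config = unclass(model$egnn_config),
      graph_config = unclass(model$graph_config),
      provider_mode = model$provider$mode,
      provider_dim = model$provider$dim,
      vocab = as.character(model$vocab),
      vocab_hash = sum(utf8ToInt(paste(model$vocab, collapse = ""))),
      theta = model$theta,
      corpus_ids = model$corpus_ids,
      trace = as.list(model$trace)
    ),
    params = encode_arrays(unclass(model$params))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a denoiser checkpoint
#'
#' @param path Path written by [save_checkpoint()].
#' @return An `egnn_denoiser` (without a training configuration; ready for
#'   scoring).
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE,
                                 simplifyMatrix = FALSE)
  man <- payload$manifest
  if (!identical(man$format, "structvep-checkpoint-v1")) {
    stop("unrecognized checkpoint format")
  }
  vocab <- token_vocabulary()
  if (man$vocab_hash != sum(utf8ToInt(paste(vocab, collapse = "")))) {
    stop("checkpoint vocabulary does not match this package's vocabulary")
  }
  decode_arrays <- function(p) {
    if (is.list(p) && !is.null(p$dim) && !is.null(p$data)) {
      out <- as.numeric(p$data)
      if (length(p$dim) > 1) dim(out) <- p$dim
      out
    } else {
      lapply(p, decode_arrays)
    }
  }
  params <- decode_arrays(payload$params)
  class(params) <- "egnn_params"
  gc_args <- man$graph_config[c("k", "cutoff", "pe_dims")]
  ec <- man$egnn_config
  structure(
    list(params = params,
         egnn_config = egnn_config(layers = ec$layers, hidden = ec$hidden,
                                   input_dim = ec$input_dim,
                                   message_dim = ec$message_dim,
                                   edge_dim = ec$edge_dim,
                                   coord_norm = ec$coord_norm,
                                   residual = ec$residual),
         graph_config = do.call(graph_config, gc_args),
         provider = embedding_provider(man$provider_mode,
                                       dim = man$provider_dim,
                                       lookup = if (man$provider_mode == "table")
                                         function(id) stop("re-attach a lookup for table mode")),
         theta = man$theta,
         vocab = vocab,
         trace = tibble::as_tibble(man$trace),
         corpus_ids = man$corpus_ids),
    class = "egnn_denoiser"
  )
}
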