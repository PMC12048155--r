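# Self-supervised residue-recovery training ------------------------------

#' Training configuration
#'
#' @param lr Adam learning rate (default 1e-4; desk-scale runs typically use
#'   a larger value).
#' @param token_budget Maximum residues per batch (default 8192).
#' @param max_len Proteins longer than this are removed from the corpus
#'   (default 2000).
#' @param epochs Number of epochs.
#' @param seed Integer master seed for shuffling and per-epoch perturbation.
#' @param perturbation A [perturbation_spec()].
#' @param loss_on `"all"` computes the loss at every position (the objective
#'   sums over the whole sequence); `"perturbed"` restricts it to perturbed
#'   sites (experimentation flag).
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-4, token_budget = 8192, max_len = 2000,
                         epochs = 100, seed = 1,
                         perturbation = perturbation_spec(),
                         loss_on = c("all", "perturbed")) {
  if (lr <= 0) stop("lr must be positive")
  structure(list(lr = lr, token_budget = as.integer(token_budget),
                 max_len = as.integer(max_len), epochs = as.integer(epochs),
                 seed = as.integer(seed), perturbation = perturbation,
                 loss_on = match.arg(loss_on)),
            class = "train_config")
}

#' Summed softmax cross-entropy of recovered residues
#'
#' `loss = -sum_n sum_c V_{n,c} log softmax(Y)_{n,c}` over all positions,
#' with the per-token average also reported.
#'
#' @param Y `n x 33` logits.
#' @param targets `n x 33` one-hot wild-type matrix.
#' @return List with `value` (sum) and `per_token`.
#' @export
cross_entropy_loss <- function(Y, targets) {
  if (!all(dim(Y) == dim(targets))) stop("logits and targets shapes disagree")
  ok <- apply(targets, 1, function(r) sum(r == 1) == 1 && sum(r) == 1)
  if (!all(ok)) stop("targets must be one-hot rows")
  lp <- logits_to_logprobs(Y)
  value <- -sum(targets * lp)
  list(value = value, per_token = value / nrow(Y))
}

#' Filter a corpus by maximum length
#'
#' Removes proteins exceeding `max_len` residues (2000 by default),
#' preserving order.
#'
#' @param structures List of `protein_structure` objects.
#' @param max_len Maximum length kept.
#' @return Filtered list.
#' @export
filter_corpus <- function(structures, max_len = 2000) {
  keep <- vapply(structures, n_residues, integer(1)) <= max_len
  structures[keep]
}

#' Token-budget batching
#'
#' Shuffles the corpus with the given seed, then greedily fills batches so
#' that the total residue count per batch stays within the budget; every
#' protein appears exactly once. A single protein longer than the budget is
#' placed alone with a warning.
#'
#' @param corpus List of `protein_structure` objects (already
#'   length-filtered).
#' @param token_budget Maximum residues per batch (default 8192).
#' @param seed Shuffle seed.
#' @return List of integer index vectors into `corpus`.
#' @export
make_batches <- function(corpus, token_budget = 8192, seed = 1) {
  lens <- vapply(corpus, n_residues, integer(1))
  ord <- withr::with_seed(seed, sample(seq_along(corpus)))
  batches <- list()
  cur <- integer(0)
  cur_tokens <- 0L
  for (i in ord) {
    if (lens[i] > token_budget) {
      warning("protein '", corpus[[i]]$id, "' (", lens[i],
              " residues) exceeds the token budget; batched alone")
      if (length(cur)) batches <- c(batches, list(cur))
      batches <- c(batches, list(i))
      cur <- integer(0)
      cur_tokens <- 0L
      next
    }
    if (cur_tokens + lens[i] > token_budget && length(cur)) {
      batches <- c(batches, list(cur))
      cur <- integer(0)
      cur_tokens <- 0L
    }
    cur <- c(cur, i)
    cur_tokens <- cur_tokens + lens[i]
  }
  if (length(cur)) batches <- c(batches, list(cur))
  batches
}

#' Pre-train the denoising encoder on a structure corpus
#'
#' Every epoch each sequence is independently re-perturbed, node attributes
#' are re-encoded, the graph forward pass and 33-class readout are computed,
#' and the summed cross-entropy of the recovered residues against the
#' wild-type sequence is minimized with Adam (one step per token-budget
#' batch). Fully seeded: identical configurations give identical loss
#' traces.
#'
#' @param corpus List of `protein_structure` objects.
#' @param graph_conf A [graph_config()].
#' @param egnn_conf An [egnn_config()].
#' @param train_conf A [train_config()].
#' @param provider An [embedding_provider()] (default one-hot).
#' @param verbose Print the loss every `verbose` epochs (0 = quiet).
#' @return An `egnn_denoiser`: trained parameters, configurations, the
#'   replacement distribution used, and a per-epoch loss trace (tibble
#'   `epoch`, `loss` with mean per-token loss).
#' @export
train_denoiser <- function(corpus,
                           graph_conf = graph_config(k = 10),
                           egnn_conf = egnn_config(hidden = 64, input_dim = 33),
                           train_conf = train_config(),
                           provider = embedding_provider("one_hot", dim = 33),
                           verbose = 0) {
  corpus <- filter_corpus(corpus, train_conf$max_len)
  if (length(corpus) == 0) stop("corpus is empty after length filtering")
  if (egnn_conf$input_dim != provider$dim) {
    stop("egnn_config input_dim must equal the provider dim")
  }

  spec <- train_conf$perturbation
  if (isTRUE(attr(spec, "theta_default")) && spec$strategy == "multinomial") {
    # replacement distribution from corpus residue frequencies
    spec$theta <- corpus_theta(corpus)
  }

  graphs <- lapply(corpus, build_residue_graph, config = graph_conf)
  targets <- lapply(corpus, function(s) one_hot_encode(s$sequence))

  params <- egnn_init_params(egnn_conf, seed = train_conf$seed)
  theta_flat <- flatten_params(params)
  opt <- adam_init(length(theta_flat))

  trace <- numeric(train_conf$epochs)
  for (epoch in seq_len(train_conf$epochs)) {
    batch_seed <- train_conf$seed + 7919L * (epoch %% 100000L)
    batches <- make_batches(corpus, train_conf$token_budget, seed = batch_seed)
    epoch_loss <- 0
    epoch_tokens <- 0L
    for (b in seq_along(batches)) {
      idx <- batches[[b]]
      grad_flat <- numeric(length(theta_flat))
      for (i in idx) {
        pe_seed <- batch_seed + 31L * i + b
        enc <- perturb_and_encode(corpus[[i]], provider, spec, pe_seed)
        tg <- targets[[i]]
        if (train_conf$loss_on == "perturbed") {
          keep <- enc$pair$changed
          if (!any(keep)) next
          mask <- as.numeric(keep)
          tg <- tg * mask
        }
        lg <- egnn_loss_grads(params, graphs[[i]], enc$W, tg, egnn_conf)
        if (!is.finite(lg$loss)) {
          stop(sprintf("training diverged (non-finite loss) at epoch %d, protein '%s'",
                       epoch, corpus[[i]]$id))
        }
        epoch_loss <- epoch_loss + lg$loss
        epoch_tokens <- epoch_tokens + nrow(targets[[i]])
        grad_flat <- grad_flat + flatten_params(lg$grads)
      }
      st <- adam_step(theta_flat, grad_flat, opt, lr = train_conf$lr)
      theta_flat <- st$theta
      opt <- st$state
      params <- unflatten_params(theta_flat, params)
    }
    trace[epoch] <- epoch_loss / max(epoch_tokens, 1L)
    if (verbose > 0 && epoch %% verbose == 0) {
      message(sprintf("epoch %d: per-token loss %.4f", epoch, trace[epoch]))
    }
  }

  structure(
    list(params = params, egnn_config = egnn_conf, graph_config = graph_conf,
         train_config = train_conf, provider = provider, theta = spec$theta,
         vocab = token_vocabulary(),
         trace = tibble::tibble(epoch = seq_len(train_conf$epochs),
                                loss = trace),
         corpus_ids = vapply(corpus, `[[`, character(1), "id")),
    class = "egnn_denoiser"
  )
}

#' @export
print.egnn_denoiser <- function(x, ...) {
  cat("<egnn_denoiser> ", x$egnn_config$layers, " layers, hidden ",
      x$egnn_config$hidden, ", k = ", x$graph_config$k, "; trained ",
      nrow(x$trace), " epochs on ", length(x$corpus_ids),
      " protein(s); final per-token loss ",
      sprintf("%.4f", utils::tail(x$trace$loss, 1)), "\n", sep = "")
  invisible(x)
}

#' Per-site token log-probabilities for a wild-type protein
#'
#' Encodes the unperturbed sequence, runs the trained network on the
#' protein's residue graph, and returns row-normalized log-probabilities —
#' the reference-state forward pass that serves all mutants of the protein.
#'
#' @param model An `egnn_denoiser`.
#' @param structure A `protein_structure`.
#' @param graph Optional prebuilt `residue_graph` (rebuilt from the model's
#'   graph configuration otherwise).
#' @return `n x 33` matrix of log-probabilities.
#' @export
model_logprobs <- function(model, structure, graph = NULL) {
  if (is.null(graph)) graph <- build_residue_graph(structure, model$graph_config)
  W_V <- encode_nodes(model$provider, structure$sequence, structure$id)
  W_L <- egnn_forward(graph, model$params, model$egnn_config, W_V = W_V)
  logits_to_logprobs(readout_logits(W_L, model$params))
}

#' Argmax residue recovery rate
#'
#' Fraction of residues whose wild-type token is the argmax of the model's
#' 33-class readout on the unperturbed input.
#'
#' @param model An `egnn_denoiser`.
#' @param corpus A `protein_structure` or list of them.
#' @return Fraction between 0 and 1.
#' @export
recovery_rate <- function(model, corpus) {
  if (inherits(corpus, "protein_structure")) corpus <- list(corpus)
  hits <- 0L
  total <- 0L
  for (s in corpus) {
    lp <- model_logprobs(model, s)
    pred <- max.col(lp, ties.method = "first")
    truth <- token_indices(s$sequence)
    hits <- hits + sum(pred == truth)
    total <- total + length(truth)
  }
  hits / total
}
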