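# Residue perturbation strategies and node-attribute providers ----------

#' Perturbation specification
#'
#' Describes how training-time noise is injected to emulate random mutation.
#' Under the multinomial strategy each site is independently redrawn with
#' probability `p` from the replacement distribution `theta` over the 20
#' canonical residues (possibly redrawing itself); the BERT-style mask
#' strategy selects 15% of sites and applies the 80/10/10
#' mask/random/unchanged split; the Gaussian strategy adds white noise of
#' the given variance to embedding rows; the recoding strategies
#' (global average, sliding window) replace embedding rows of perturbed
#' sites with pooled rows.
#'
#' @param strategy One of `"multinomial"`, `"global_average"`,
#'   `"sliding_window"`, `"gaussian"`, `"mask"`.
#' @param p Per-site perturbation probability between 0 and 1 (default 0.15,
#'   mirroring the masking convention; the redraw may keep the residue).
#' @param theta Length-20 replacement distribution over
#'   [canonical_residues()]; defaults to uniform. During corpus training
#'   this is replaced by the residue frequencies observed in the corpus.
#' @param gaussian_variance Variance of the additive embedding noise
#'   (default 0.5).
#' @param window Odd window size for the sliding-window recoding (default 3).
#' @param mask_select Selection probability of the mask strategy (0.15).
#' @param mask_split Length-3 mask/random/unchanged split (0.8, 0.1, 0.1).
#' @return A `perturbation_spec` list.
#' @export
perturbation_spec <- function(strategy = c("multinomial", "global_average",
                                           "sliding_window", "gaussian", "mask"),
                              p = 0.15,
                              theta = NULL,
                              gaussian_variance = 0.5,
                              window = 3,
                              mask_select = 0.15,
                              mask_split = c(0.8, 0.1, 0.1)) {
  strategy <- match.arg(strategy)
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  theta_default <- is.null(theta)
  if (is.null(theta)) theta <- rep(1 / 20, 20)
  if (length(theta) != 20) stop("theta must have length 20")
  if (abs(sum(theta) - 1) > 1e-9) stop("theta must sum to 1")
  if (gaussian_variance < 0) stop("gaussian_variance must be nonnegative")
  if (window < 1 || window %% 2 == 0) stop("window must be a positive odd integer")
  if (abs(sum(mask_split) - 1) > 1e-9) stop("mask_split must sum to 1")
  structure(list(strategy = strategy, p = p, theta = theta,
                 gaussian_variance = gaussian_variance, window = as.integer(window),
                 mask_select = mask_select, mask_split = mask_split),
            theta_default = theta_default,
            class = "perturbation_spec")
}

new_sequence_pair <- function(v, v_tilde, changed) {
  stopifnot(length(v) == length(v_tilde), length(v) == length(changed))
  structure(list(v = v, v_tilde = v_tilde, changed = changed),
            class = "sequence_pair")
}

#' @export
print.sequence_pair <- function(x, ...) {
  cat("<sequence_pair> length ", length(x$v), ", ", sum(x$changed),
      " site(s) flagged\n", sep = "")
  invisible(x)
}

#' Multinomial residue replacement
#'
#' Independently per site, with probability `p` the residue is redrawn from
#' the replacement distribution `theta` (which may redraw the same residue),
#' otherwise it is kept. Unknown (`X`) sites are never perturbed. The
#' `changed` flags mark sites whose residue actually differs afterwards.
#'
#' @param sequence Character scalar or per-site character vector over the
#'   canonical alphabet.
#' @param spec A [perturbation_spec()] with strategy `"multinomial"`.
#' @param seed Integer seed; identical seeds give identical outputs.
#' @return A `sequence_pair` with fields `v`, `v_tilde`, `changed`.
#' @export
perturb_multinomial <- function(sequence, spec = perturbation_spec(), seed = 1) {
  if (spec$p < 0 || spec$p > 1) stop("p must lie in [0, 1]")
  v <- as_site_chars(sequence)
  withr::with_seed(seed, {
    n <- length(v)
    redraw <- stats::runif(n) < spec$p
    redraw[v == "X"] <- FALSE
    v_tilde <- v
    if (any(redraw)) {
      v_tilde[redraw] <- sample(canonical_residues(), sum(redraw),
                                replace = TRUE, prob = spec$theta)
    }
    new_sequence_pair(v, v_tilde, v != v_tilde)
  })
}

#' BERT-style masking perturbation
#'
#' Selects each site independently with probability `mask_select` (0.15);
#' among selected sites 80% are replaced by the `<mask>` token, 10% by a
#' random other residue, and 10% are left unchanged. The `changed` flags
#' record the selection (including the unchanged 10%).
#'
#' @inheritParams perturb_multinomial
#' @param spec A [perturbation_spec()] (strategy `"mask"`).
#' @return A `sequence_pair`; masked sites carry the literal `"<mask>"`
#'   symbol in `v_tilde`.
#' @export
bert_mask <- function(sequence, spec = perturbation_spec("mask"), seed = 1) {
  v <- as_site_chars(sequence)
  withr::with_seed(seed, {
    n <- length(v)
    selected <- stats::runif(n) < spec$mask_select
    u <- stats::runif(n)
    v_tilde <- v
    cum <- cumsum(spec$mask_split)
    to_mask <- selected & u < cum[1]
    to_random <- selected & u >= cum[1] & u < cum[2]
    v_tilde[to_mask] <- "<mask>"
    if (any(to_random)) {
      v_tilde[to_random] <- vapply(v[to_random], function(a) {
        sample(setdiff(canonical_residues(), a), 1)
      }, character(1))
    }
    new_sequence_pair(v, v_tilde, selected)
  })
}

#' Additive Gaussian noise on node embeddings
#'
#' Returns `W_V + eps` where the entries of `eps` are i.i.d. normal with
#' mean zero and variance `spec$gaussian_variance` (default 0.5).
#'
#' @param W_V An `n x d` node-attribute matrix.
#' @param spec A [perturbation_spec()] (strategy `"gaussian"`).
#' @param seed Integer seed.
#' @return An `n x d` matrix.
#' @export
gaussian_perturb <- function(W_V, spec = perturbation_spec("gaussian"), seed = 1) {
  if (spec$gaussian_variance < 0) stop("gaussian_variance must be nonnegative")
  if (spec$gaussian_variance == 0) return(W_V)
  withr::with_seed(seed, {
    W_V + matrix(stats::rnorm(length(W_V), sd = sqrt(spec$gaussian_variance)),
                 nrow = nrow(W_V))
  })
}

#' Recode embedding rows of perturbed sites
#'
#' `global_average` replaces each perturbed site's row with the mean of the
#' unperturbed rows sharing that site's (perturbed) residue identity within
#' the same protein; `sliding_window` replaces it with the mean of the rows
#' in a centred window along the sequence, truncated at the boundaries.
#'
#' @param W_V `n x d` node-attribute matrix aligned with `sequence`.
#' @param sequence Per-site symbols after perturbation (character vector or
#'   scalar string).
#' @param changed Logical flags marking perturbed sites.
#' @param strategy `"global_average"` or `"sliding_window"`.
#' @param window Odd window size (default 3).
#' @return An `n x d` matrix; unperturbed rows are bit-identical to input.
#' @export
embed_recode <- function(W_V, sequence, changed,
                         strategy = c("global_average", "sliding_window"),
                         window = 3) {
  strategy <- match.arg(strategy)
  v <- as_site_chars(sequence)
  n <- length(v)
  stopifnot(nrow(W_V) == n, length(changed) == n)
  out <- W_V
  idx <- which(changed)
  if (strategy == "global_average") {
    for (i in idx) {
      exemplars <- which(!changed & v == v[i])
      if (length(exemplars) == 0L) {
        warning("no unperturbed exemplar of residue '", v[i],
                "' at site ", i, "; row left untouched")
        next
      }
      out[i, ] <- colMeans(W_V[exemplars, , drop = FALSE])
    }
  } else {
    half <- (window - 1) / 2
    for (i in idx) {
      lo <- max(1, i - half)
      hi <- min(n, i + half)
      out[i, ] <- colMeans(W_V[lo:hi, , drop = FALSE])
    }
  }
  out
}

#' Node-attribute embedding provider
#'
#' Abstracts where per-residue node attributes come from: `"one_hot"`
#' encodes the (possibly perturbed) sequence over the 33-token vocabulary;
#' `"table"` looks up a precomputed per-protein numeric matrix (row order =
#' residue order), e.g. hidden representations exported from a frozen
#' protein language model.
#'
#' @param mode `"one_hot"` or `"table"`.
#' @param dim Node attribute width; 33 for one-hot, the table width
#'   otherwise.
#' @param lookup For table mode: a named list of matrices keyed by protein
#'   id, or a function `(id) -> matrix`.
#' @return An `embedding_provider`.
#' @export
embedding_provider <- function(mode = c("one_hot", "table"), dim = 33,
                               lookup = NULL) {
  mode <- match.arg(mode)
  if (dim <= 0) stop("dim must be positive")
  if (mode == "table" && is.null(lookup)) stop("table mode requires a lookup")
  structure(list(mode = mode, dim = as.integer(dim), lookup = lookup),
            class = "embedding_provider")
}

#' Encode a sequence into node attributes
#'
#' In one-hot mode perturbed sequences are simply re-one-hot-encoded
#' ("mutate-then-recode"); in table mode the stored matrix is fetched and
#' contract-checked against the sequence length.
#'
#' @param provider An [embedding_provider()].
#' @param sequence Per-site symbols (perturbed or not).
#' @param id Protein identifier (required for table mode).
#' @return An `n x dim` numeric matrix.
#' @export
encode_nodes <- function(provider, sequence, id = NULL) {
  chars <- as_site_chars(sequence)
  if (provider$mode == "one_hot") {
    return(one_hot_encode(chars))
  }
  m <- if (is.function(provider$lookup)) provider$lookup(id) else provider$lookup[[id]]
  if (is.null(m)) stop("no embedding table for protein '", id, "'")
  if (nrow(m) != length(chars)) {
    stop("embedding table for '", id, "' has ", nrow(m),
         " rows but the sequence has ", length(chars), " residues")
  }
  if (ncol(m) != provider$dim) {
    stop("embedding table width ", ncol(m), " does not match provider dim ",
         provider$dim)
  }
  m
}

#' Read a per-protein embedding table from a delimited text file
#'
#' @param path Path to a whitespace- or tab-delimited numeric matrix, one
#'   row per residue.
#' @return A numeric matrix.
#' @export
read_embedding_table <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}

#' Residue replacement distribution from a corpus
#'
#' Empirical frequencies of the 20 canonical residues over the wild-type
#' sequences of a corpus, used as the default replacement distribution
#' during training.
#'
#' @param corpus List of `protein_structure` objects (or character
#'   sequences).
#' @return Length-20 probability vector aligned with [canonical_residues()].
#' @export
corpus_theta <- function(corpus) {
  seqs <- vapply(corpus, function(s) {
    if (inherits(s, "protein_structure")) s$sequence else as.character(s)
  }, character(1))
  chars <- unlist(strsplit(seqs, ""))
  counts <- table(factor(chars, levels = canonical_residues()))
  total <- sum(counts)
  if (total == 0) return(rep(1 / 20, 20))
  as.numeric(counts) / total
}

# Dispatch one training-time perturbation of a protein according to spec.
# Returns list(W = node attributes, pair = sequence_pair or NULL).
perturb_and_encode <- function(structure, provider, spec, seed) {
  v <- as_site_chars(structure$sequence)
  switch(
    spec$strategy,
    multinomial = {
      pair <- perturb_multinomial(v, spec, seed)
      list(W = encode_nodes(provider, pair$v_tilde, structure$id), pair = pair)
    },
    mask = {
      pair <- bert_mask(v, spec, seed)
      list(W = encode_nodes(provider, pair$v_tilde, structure$id), pair = pair)
    },
    gaussian = {
      W0 <- encode_nodes(provider, v, structure$id)
      list(W = gaussian_perturb(W0, spec, seed),
           pair = new_sequence_pair(v, v, rep(FALSE, length(v))))
    },
    {
      # global_average / sliding_window: multinomial site selection, then
      # pooled-row recoding of the original embedding at perturbed sites.
      pair <- perturb_multinomial(v, spec, seed)
      W0 <- encode_nodes(provider, v, structure$id)
      W <- embed_recode(W0, pair$v_tilde, pair$changed,
                        strategy = spec$strategy, window = spec$window)
      list(W = W, pair = pair)
    }
  )
}
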