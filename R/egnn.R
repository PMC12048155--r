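# Equivariant graph network: configuration, parameters, forward ---------

#' EGNN configuration
#'
#' @param layers Number of message-passing layers (default 6).
#' @param hidden Hidden width h (default 512; the model grid uses 512, 768,
#'   1280; tests use small widths).
#' @param input_dim Node-attribute input width d (33 for one-hot mode).
#' @param message_dim Message width (defaults to `hidden`).
#' @param edge_dim Edge-attribute width (93 with default graph settings).
#' @param coord_norm `"n"` divides the coordinate update by the node count
#'   (as the update rule is written); `"indegree"` divides by each node's
#'   in-neighbourhood size instead (stability option).
#' @param residual Add residual connections on node features (default off).
#' @return An `egnn_config` list.
#' @export
egnn_config <- function(layers = 6, hidden = 512, input_dim = 33,
                        message_dim = NULL, edge_dim = 93,
                        coord_norm = c("n", "indegree"), residual = FALSE) {
  if (layers < 1) stop("layers must be >= 1")
  if (hidden <= 0) stop("hidden must be positive")
  if (is.null(message_dim)) message_dim <- hidden
  structure(list(layers = as.integer(layers), hidden = as.integer(hidden),
                 input_dim = as.integer(input_dim),
                 message_dim = as.integer(message_dim),
                 edge_dim = as.integer(edge_dim),
                 coord_norm = match.arg(coord_norm),
                 residual = isTRUE(residual)),
            class = "egnn_config")
}

xavier <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize EGNN parameters
#'
#' Per-layer two-layer perceptrons for the edge/message map, the scalar
#' coordinate gate (final layer down-scaled for stable coordinate updates)
#' and the node update, plus an input projection d -> h and the 33-class
#' readout.
#'
#' @param config An [egnn_config()].
#' @param seed Integer seed.
#' @param n_classes Readout width (33 tokens).
#' @param gate_scale Multiplier on the gate output layer init (default 1e-3).
#' @param readout_scale Multiplier on the readout init (default 1e-2, so an
#'   untrained model starts near the uniform-guess loss ln 33).
#' @return Nested list of parameter matrices/vectors (`egnn_params`).
#' @export
egnn_init_params <- function(config, seed = 1, n_classes = 33,
                             gate_scale = 1e-3, readout_scale = 1e-2) {
  h <- config$hidden
  m <- config$message_dim
  ein <- 2 * h + 1 + config$edge_dim
  withr::with_seed(seed, {
    params <- list(
      W_in = xavier(config$input_dim, h), b_in = numeric(h),
      layers = lapply(seq_len(config$layers), function(l) {
        list(
          We1 = xavier(ein, h), be1 = numeric(h),
          We2 = xavier(h, m), be2 = numeric(m),
          Wx1 = xavier(m, m), bx1 = numeric(m),
          Wx2 = xavier(m, 1) * gate_scale, bx2 = numeric(1),
          Wv1 = xavier(h + m, h), bv1 = numeric(h),
          Wv2 = xavier(h, h), bv2 = numeric(h)
        )
      }),
      W_out = xavier(h, n_classes) * readout_scale, b_out = numeric(n_classes)
    )
    class(params) <- "egnn_params"
    params
  })
}

# Fixed input standardization inside the message MLP: geometric inputs are
# Angstrom-scale (distances up to the 30 A cutoff, squared distances up to
# its square), so they are divided by fixed constants before meeting
# unit-scale weights. The raw edge attributes on the graph are untouched.
.D2_SCALE <- 1e-2   # squared CA-CA distances (A^2)
.EDGE_SCALE <- 0.1  # distance / local-frame blocks of the edge attributes (A)
.N_GEOM_COLS <- 37L # 25 inter-atomic distances + 12 local-frame coordinates

scaled_edge_attr <- function(W_E) {
  k <- min(.N_GEOM_COLS, ncol(W_E))
  W_E[, seq_len(k)] <- W_E[, seq_len(k)] * .EDGE_SCALE
  W_E
}

silu <- function(x) x / (1 + exp(-x))

silu_grad <- function(x) {
  s <- 1 / (1 + exp(-x))
  s * (1 + x * (1 - s))
}

linear <- function(x, w, b) sweep(x %*% w, 2, b, "+")

coord_coef <- function(graph, config) {
  if (config$coord_norm == "n") {
    rep(1 / graph$n, graph$n)
  } else {
    deg <- as.numeric(Matrix::rowSums(graph$inc_from))
    1 / pmax(deg, 1)
  }
}

# One layer forward. state: list(W = n x h, X = n x 3). Returns updated
# state plus the intermediate quantities needed by the backward pass.
egnn_layer_forward <- function(state, graph, lp, config, keep_cache = FALSE) {
  W <- state$W
  X <- state$X
  from <- graph$from
  to <- graph$to
  n <- graph$n

  diff <- X[from, , drop = FALSE] - X[to, , drop = FALSE]
  d2 <- rowSums(diff^2)
  W_E_s <- if (is.null(graph$W_E_scaled)) scaled_edge_attr(graph$W_E) else graph$W_E_scaled
  ein <- cbind(W[from, , drop = FALSE], W[to, , drop = FALSE],
               d2 * .D2_SCALE, W_E_s)
  z1 <- linear(ein, lp$We1, lp$be1)
  h1 <- silu(z1)
  z2 <- linear(h1, lp$We2, lp$be2)
  M <- silu(z2)
  q1 <- linear(M, lp$Wx1, lp$bx1)
  g1 <- silu(q1)
  gate <- linear(g1, lp$Wx2, lp$bx2) # |E| x 1, no final nonlinearity

  coef <- coord_coef(graph, config)
  upd <- diff * as.numeric(gate)
  X_new <- X + coef * as.matrix(graph$inc_from %*% upd)

  S <- as.matrix(graph$inc_from %*% M)
  vin <- cbind(W, S)
  u1 <- linear(vin, lp$Wv1, lp$bv1)
  r1 <- silu(u1)
  W_new <- linear(r1, lp$Wv2, lp$bv2)
  if (config$residual) W_new <- W_new + W

  out <- list(W = W_new, X = X_new)
  if (keep_cache) {
    out$cache <- list(W = W, X = X, diff = diff, ein = ein, z1 = z1, h1 = h1,
                      z2 = z2, M = M, q1 = q1, g1 = g1, gate = gate,
                      vin = vin, u1 = u1, r1 = r1, coef = coef)
  }
  out
}

#' Apply one EGNN layer
#'
#' Message computation `m_ij = phi_e(w_i, w_j, |x_i - x_j|^2, w_eij)` over
#' the directed edges, equivariant coordinate update
#' `x_i <- x_i + (1/n) sum_j (x_i - x_j) phi_x(m_ij)`, and node update
#' `w_i <- phi_v(w_i, sum_j m_ij)`. Edge attributes are read-only.
#'
#' @param state List with `W` (n x h node features) and `X` (n x 3
#'   coordinates).
#' @param graph A `residue_graph`.
#' @param layer_params One element of `params$layers` from
#'   [egnn_init_params()].
#' @param config An [egnn_config()].
#' @return Updated state list with `W` and `X`.
#' @export
egnn_layer <- function(state, graph, layer_params, config) {
  if (nrow(state$W) != graph$n) stop("state W is not aligned with the graph")
  out <- egnn_layer_forward(state, graph, layer_params, config)
  out[c("W", "X")]
}

#' Full EGNN forward pass
#'
#' Projects node attributes d -> h, applies the configured stack of layers,
#' and returns the final node features (updated coordinates are discarded;
#' only the features feed the readout).
#'
#' @param graph A `residue_graph` with `W_V` populated (see
#'   [set_node_attributes()]), or supply `W_V` directly.
#' @param params `egnn_params`.
#' @param config An [egnn_config()].
#' @param W_V Optional node-attribute matrix overriding `graph$W_V`.
#' @param keep_cache Retain per-layer intermediates (used by training).
#' @return `n x hidden` feature matrix; with `keep_cache = TRUE`, a list
#'   with `W`, `X` and `caches`.
#' @export
egnn_forward <- function(graph, params, config, W_V = NULL, keep_cache = FALSE) {
  if (is.null(W_V)) W_V <- graph$W_V
  if (is.null(W_V)) stop("node attributes W_V are unpopulated")
  if (ncol(W_V) != config$input_dim) {
    stop("W_V width ", ncol(W_V), " does not match config input_dim ",
         config$input_dim)
  }
  W <- linear(W_V, params$W_in, params$b_in)
  X <- graph$X
  caches <- if (keep_cache) vector("list", config$layers) else NULL
  for (l in seq_len(config$layers)) {
    out <- egnn_layer_forward(list(W = W, X = X), graph, params$layers[[l]],
                              config, keep_cache = keep_cache)
    W <- out$W
    X <- out$X
    if (keep_cache) caches[[l]] <- out$cache
  }
  if (keep_cache) list(W = W, X = X, caches = caches, W_V = W_V) else W
}

#' 33-class readout
#'
#' Linear map from final node features to unnormalized token scores; row
#' softmax of the result gives per-site token probabilities.
#'
#' @param W_L `n x hidden` final node features.
#' @param params `egnn_params` (uses `W_out`, `b_out`).
#' @return `n x 33` logits matrix.
#' @export
readout_logits <- function(W_L, params) {
  linear(W_L, params$W_out, params$b_out)
}

#' Row-wise log-softmax
#'
#' @param Y Logits matrix.
#' @return Matrix of log-probabilities; each row exponentiates and sums to 1.
#' @export
logits_to_logprobs <- function(Y) {
  mx <- apply(Y, 1, max)
  sh <- Y - mx
  sh - log(rowSums(exp(sh)))
}

n_params <- function(params) {
  sum(vapply(rapply(params, length, how = "unlist"), identity, numeric(1)))
}
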