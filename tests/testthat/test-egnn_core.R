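tiny_cfg <- function(layers = 2, hidden = 8) {
  egnn_config(layers = layers, hidden = hidden, input_dim = 33,
              message_dim = hidden)
}

test_that("a zero coordinate gate leaves coordinates unchanged", {
  g <- tiny_graph(8, k = 4, seed = 1)
  cfg <- tiny_cfg(1)
  p <- egnn_init_params(cfg, seed = 2)
  lp <- p$layers[[1]]
  lp$Wx2 <- lp$Wx2 * 0
  lp$bx2 <- lp$bx2 * 0
  W0 <- matrix(rnorm(8 * cfg$hidden), 8)
  st <- egnn_layer(list(W = W0, X = g$X), g, lp, cfg)
  expect_equal(st$X, g$X, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(st$W, W0)))
})

test_that("layers are roto-translation equivariant and permutation equivariant", {
  g <- tiny_graph(12, k = 5, seed = 3)
  cfg <- tiny_cfg(2)
  p <- egnn_init_params(cfg, seed = 4, gate_scale = 1, readout_scale = 1)
  W0 <- withr::with_seed(5, matrix(rnorm(12 * cfg$hidden), 12))
  run <- function(graph, W) {
    st <- list(W = W, X = graph$X)
    for (l in 1:2) st <- egnn_layer(st, graph, p$layers[[l]], cfg)
    st
  }
  out <- run(g, W0)
  motion <- rigid_motion(6)
  g_t <- g
  g_t$X <- sweep(g$X %*% t(motion$R), 2, motion$t, "+")
  out_t <- run(g_t, W0)
  expect_lt(max(abs(out$W - out_t$W)), 1e-5)
  expect_lt(max(abs(sweep(out$X %*% t(motion$R), 2, motion$t, "+") - out_t$X)), 1e-5)

  # permutation equivariance: relabel nodes consistently
  perm <- withr::with_seed(7, sample(12))
  inv <- order(perm)
  g_p <- g
  g_p$X <- g$X[perm, ]
  g_p$from <- inv[g$from]
  g_p$to <- inv[g$to]
  o <- order(g_p$from, g_p$to)
  g_p$from <- g_p$from[o]
  g_p$to <- g_p$to[o]
  g_p$W_E <- g$W_E[o, ]
  g_p$W_E_scaled <- g$W_E_scaled[o, ]
  g_p$inc_from <- Matrix::sparseMatrix(i = g_p$from, j = seq_along(g_p$from),
                                       x = 1, dims = c(12, length(g_p$from)))
  g_p$inc_to <- Matrix::sparseMatrix(i = g_p$to, j = seq_along(g_p$to),
                                     x = 1, dims = c(12, length(g_p$to)))
  out_p <- run(g_p, W0[perm, ])
  expect_lt(max(abs(out_p$W - out$W[perm, ])), 1e-9)
  expect_lt(max(abs(out_p$X - out$X[perm, ])), 1e-9)
})

test_that("the forward stack composes layers and keeps outputs finite", {
  g <- tiny_graph(15, k = 6, seed = 8)
  cfg1 <- tiny_cfg(1)
  p <- egnn_init_params(cfg1, seed = 9)
  W_V <- one_hot_encode(paste(rep("A", 15), collapse = ""))
  # L = 1 equals projection + one layer call
  manual <- egnn_layer(list(W = sweep(W_V %*% p$W_in, 2, p$b_in, "+"), X = g$X),
                       g, p$layers[[1]], cfg1)
  expect_equal(egnn_forward(g, p, cfg1, W_V = W_V), manual$W, tolerance = 1e-12)

  cfg6 <- tiny_cfg(6, hidden = 16)
  p6 <- egnn_init_params(cfg6, seed = 10)
  out <- egnn_forward(g, p6, cfg6, W_V = W_V)
  expect_equal(dim(out), c(15, 16))
  expect_true(all(is.finite(out)))
  expect_error(egnn_forward(g, p6, cfg6), "unpopulated")
  expect_error(egnn_forward(g, p6, cfg6, W_V = W_V[, 1:10]), "input_dim")
})

test_that("readout produces normalized 33-class distributions", {
  W_L <- matrix(rnorm(5 * 8), 5, 8)
  cfg <- tiny_cfg(1)
  p <- egnn_init_params(cfg, seed = 11)
  Y <- readout_logits(W_L, p)
  expect_equal(ncol(Y), 33)
  lp <- logits_to_logprobs(Y)
  expect_equal(rowSums(exp(lp)), rep(1, 5), tolerance = 1e-6)
  # zero readout weights give the uniform distribution
  p0 <- p
  p0$W_out <- p0$W_out * 0
  expect_equal(exp(logits_to_logprobs(readout_logits(W_L, p0))),
               matrix(1 / 33, 5, 33), tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  s <- make_helix_structure(5, jitter_sd = 0.3, seed = 12)
  g <- build_residue_graph(s, graph_config(k = 3))
  W_V <- one_hot_encode(s$sequence)
  tg <- W_V

  check_grads <- function(cfg, p, n_check = NULL, tol = 1e-4) {
    lg <- egnn_loss_grads(p, g, W_V, tg, cfg)
    th <- structvep:::flatten_params(p)
    gr <- structvep:::flatten_params(lg$grads)
    f <- function(v) {
      egnn_loss_grads(structvep:::unflatten_params(v, p), g, W_V, tg, cfg)$loss
    }
    idx <- if (is.null(n_check)) seq_along(th) else
      withr::with_seed(1, sample(length(th), n_check))
    num <- vapply(idx, function(i) {
      eps <- 1e-5
      tp <- th
      tp[i] <- tp[i] + eps
      up <- f(tp)
      tp[i] <- tp[i] - 2 * eps
      dn <- f(tp)
      (up - dn) / (2 * eps)
    }, numeric(1))
    rel <- abs(gr[idx] - num) / pmax(abs(gr[idx]) + abs(num), 1e-6)
    max(rel)
  }

  cfg1 <- egnn_config(layers = 1, hidden = 4, input_dim = 33, message_dim = 4)
  p1 <- egnn_init_params(cfg1, seed = 13, gate_scale = 1, readout_scale = 1)
  expect_lt(check_grads(cfg1, p1), 1e-4)

  # the coordinate path across layers: a 3-layer stack, random subset
  cfg3 <- egnn_config(layers = 3, hidden = 4, input_dim = 33, message_dim = 4)
  p3 <- egnn_init_params(cfg3, seed = 14, gate_scale = 1, readout_scale = 1)
  expect_lt(check_grads(cfg3, p3, n_check = 250), 1e-3)
})
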