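test_that("one-hot encoding over the 33-token vocabulary is exact", {
  vocab <- token_vocabulary()
  expect_length(vocab, 33)
  expect_equal(anyDuplicated(vocab), 0L)
  expect_true("<mask>" %in% vocab)

  m <- one_hot_encode("ACD")
  expect_equal(dim(m), c(3, 33))
  expect_equal(rowSums(m), rep(1, 3))
  expect_equal(apply(m, 1, function(r) sum(r == 1)), rep(1, 3))
  # non-canonical symbols absorb into the X token
  expect_equal(one_hot_encode("B")[1, ], one_hot_encode("X")[1, ])
  expect_equal(one_hot_encode("?")[1, ], one_hot_encode("X")[1, ])
  # the mask token round-trips through the character-vector path
  mm <- one_hot_encode(c("A", "<mask>", "G"))
  expect_equal(mm[2, match("<mask>", vocab)], 1)
})

test_that("multinomial perturbation honours p, theta and determinism", {
  spec0 <- perturbation_spec(p = 0)
  seq10 <- strsplit("ACDEFGHIKL", "")[[1]]
  expect_identical(perturb_multinomial(seq10, spec0, seed = 3)$v_tilde, seq10)

  theta_g <- c(rep(0, 7), 1, rep(0, 12)) # point mass on G
  spec1 <- perturbation_spec(p = 1, theta = theta_g)
  out <- perturb_multinomial(seq10, spec1, seed = 3)
  expect_true(all(out$v_tilde == "G"))

  long <- withr::with_seed(5, sample(canonical_residues(), 1e5, replace = TRUE))
  spec <- perturbation_spec(p = 0.3, theta = rep(1 / 20, 20))
  pair <- perturb_multinomial(long, spec, seed = 6)
  # closed form: a redrawn site keeps its residue with probability 1/20
  expect_true(abs(mean(pair$changed) - 0.3 * 19 / 20) < 0.01)
  expect_identical(pair, perturb_multinomial(long, spec, seed = 6))
  # unperturbed sites bit-identical, changed flags consistent
  expect_true(all(pair$v[!pair$changed] == pair$v_tilde[!pair$changed]))
  # X sites never perturbed
  px <- perturb_multinomial(rep("X", 100), perturbation_spec(p = 1), seed = 1)
  expect_true(all(px$v_tilde == "X"))
})

test_that("changed-site fraction matches the closed form on skewed inputs", {
  # sequences drawn from a non-uniform frequency, non-uniform theta
  freq <- (1:20) / sum(1:20)
  theta <- rev(freq)
  long <- withr::with_seed(8, sample(canonical_residues(), 2e5, replace = TRUE,
                                     prob = freq))
  p <- 0.4
  pair <- perturb_multinomial(long, perturbation_spec(p = p, theta = theta),
                              seed = 9)
  site_freq <- as.numeric(table(factor(long, levels = canonical_residues()))) /
    length(long)
  expected <- p * (1 - sum(site_freq * theta))
  expect_true(abs(mean(pair$changed) - expected) < 0.01)
})

test_that("BERT-style mask reproduces the 15% / 80-10-10 split", {
  long <- withr::with_seed(2, sample(canonical_residues(), 1e5, replace = TRUE))
  pair <- bert_mask(long, seed = 4)
  expect_true(abs(mean(pair$changed) - 0.15) < 0.01)
  sel <- which(pair$changed)
  frac_mask <- mean(pair$v_tilde[sel] == "<mask>")
  frac_same <- mean(pair$v_tilde[sel] == pair$v[sel])
  frac_rand <- mean(pair$v_tilde[sel] != "<mask>" & pair$v_tilde[sel] != pair$v[sel])
  expect_true(abs(frac_mask - 0.80) < 0.02)
  expect_true(abs(frac_rand - 0.10) < 0.02)
  expect_true(abs(frac_same - 0.10) < 0.02)
  # unselected sites untouched; same seed identical
  expect_true(all(pair$v[-sel] == pair$v_tilde[-sel]))
  expect_identical(pair, bert_mask(long, seed = 4))
})

test_that("gaussian perturbation has the configured variance", {
  W <- matrix(0, 1000, 1000)
  out <- gaussian_perturb(W, perturbation_spec("gaussian"), seed = 5)
  expect_true(abs(stats::var(as.numeric(out - W)) - 0.5) < 0.01)
  expect_identical(out, gaussian_perturb(W, perturbation_spec("gaussian"), seed = 5))
  expect_identical(gaussian_perturb(W, perturbation_spec("gaussian", gaussian_variance = 0)), W)
  expect_error(perturbation_spec("gaussian", gaussian_variance = -1), "nonnegative")
})

test_that("embedding recoding pools rows as specified", {
  n <- 10
  W <- matrix(as.numeric(seq_len(n * 4)), n, 4)
  v <- c("G", "A", "G", "A", "A", "G", "A", "A", "A", "A")
  changed <- rep(FALSE, n)
  changed[1] <- TRUE # perturbed-to-G site

  # all unperturbed glycine rows identical -> recoded row equals that row
  W_g <- W
  W_g[c(3, 6), ] <- matrix(rep(c(7, 7, 7, 7), 2), 2, 4, byrow = TRUE)
  out <- embed_recode(W_g, v, changed, "global_average")
  expect_equal(out[1, ], c(7, 7, 7, 7))
  expect_identical(out[-1, ], W_g[-1, ])

  # general case: mean of unperturbed same-identity rows
  out2 <- embed_recode(W, v, changed, "global_average")
  expect_equal(out2[1, ], colMeans(W[c(3, 6), ]))

  # no exemplar -> warn, row untouched
  v_solo <- c("W", rep("A", n - 1))
  expect_warning(out3 <- embed_recode(W, v_solo, changed, "global_average"),
                 "no unperturbed exemplar")
  expect_equal(out3[1, ], W[1, ])

  # sliding window: interior mean of {i-1, i, i+1}, boundary truncates
  ch <- rep(FALSE, n)
  ch[c(1, 5)] <- TRUE
  out4 <- embed_recode(W, v, ch, "sliding_window", window = 3)
  expect_equal(out4[5, ], colMeans(W[4:6, ]))
  expect_equal(out4[1, ], colMeans(W[1:2, ]))
  expect_identical(out4[c(2:4, 6:10), ], W[c(2:4, 6:10), ])
})

test_that("embedding providers enforce their table contracts", {
  s <- helix(6, seed = 3)
  one_hot <- embedding_provider("one_hot", dim = 33)
  expect_equal(dim(encode_nodes(one_hot, s$sequence, s$id)), c(6, 33))

  tbl <- matrix(rnorm(6 * 8), 6, 8)
  prov <- embedding_provider("table", dim = 8, lookup = setNames(list(tbl), s$id))
  expect_equal(encode_nodes(prov, s$sequence, s$id), tbl)
  expect_error(encode_nodes(prov, paste0(s$sequence, "A"), s$id), "rows")
  bad <- embedding_provider("table", dim = 9, lookup = setNames(list(tbl), s$id))
  expect_error(encode_nodes(bad, s$sequence, s$id), "width")
  expect_error(encode_nodes(prov, s$sequence, "unknown"), "no embedding table")

  # round-trip through the plain-text table reader
  tmp <- tempfile(fileext = ".tsv")
  write.table(tbl, tmp, row.names = FALSE, col.names = FALSE)
  expect_equal(unname(read_embedding_table(tmp)), unname(tbl), tolerance = 1e-12)
  unlink(tmp)
})

test_that("corpus residue frequencies define the default replacement distribution", {
  corpus <- make_corpus(fixture_spec(4, c(20, 40), seed = 2))
  th <- corpus_theta(corpus)
  expect_length(th, 20)
  expect_equal(sum(th), 1, tolerance = 1e-12)
  counts <- table(factor(unlist(strsplit(vapply(corpus, `[[`, character(1), "sequence"), "")),
                         levels = canonical_residues()))
  expect_equal(th, as.numeric(counts) / sum(counts))
})
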