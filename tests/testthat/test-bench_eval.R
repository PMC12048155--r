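toy_assay_table <- function() {
  # protein P1: 12 single mutants + 1 multi-site; protein P2: 9 mutants only
  wt1 <- "ACDEFGHIKLMN"
  p1 <- tibble::tibble(
    protein_id = "P1",
    mutant = c(sprintf("%s%dG", strsplit(wt1, "")[[1]][1:11], 1:11), "A1G:C2W", "E4W"),
    score = seq_len(13) / 10,
    ph = 7.0, temperature = 25
  )
  # drop duplicate-position G mutants that equal wild type (position 6 is G)
  p1 <- p1[p1$mutant != "G6G", ]
  p2 <- tibble::tibble(
    protein_id = "P2",
    mutant = sprintf("A%dV", 1:9),
    score = seq_len(9) / 10,
    ph = 8.0, temperature = 37
  )
  dplyr::bind_rows(p1, p2)
}

test_that("melting-temperature curation drops multi-site and small groups", {
  raw <- toy_assay_table()
  cur <- curate_assays(raw, mode = "dtm")
  # P2 has only 9 mutants -> dropped entirely
  expect_false(any(grepl("^P2", cur$assay)))
  # the multi-site record is removed before counting
  expect_false(any(grepl(":", cur$mutant)))
  expect_equal(unique(cur$assay), "P1-7.0")
  expect_equal(nrow(cur), 11) # 12 P1 records minus the multi-site one
  # exactly at the 10-mutant threshold the group survives
  cur9 <- curate_assays(raw[raw$protein_id == "P2", ], mode = "dtm")
  expect_equal(nrow(cur9), 0)
})

test_that("free-energy curation removes unalignable records and names assays", {
  raw <- toy_assay_table()
  refs <- c(P1 = "ACDEFGHIKLMN", P2 = paste(rep("A", 9), collapse = ""))
  # corrupt two wild-type letters so they cannot align
  raw$mutant[raw$protein_id == "P1"][c(2, 4)] <- c("W2G", "W4G")
  cur <- curate_assays(raw, mode = "ddg", reference_sequences = refs)
  expect_false(any(cur$mutant %in% c("W2G", "W4G")))
  # P1 keeps 13 - 2 mismatches - ... >= 10 records; multi-site records stay in
  # ddg mode when they align
  expect_true("A1G:C2W" %in% cur$mutant)
  expect_true(all(grepl("^P1-7.0-25$|^P2-8.0-37$", cur$assay)))
  # P2: 9 records < 10 -> dropped even though all align
  expect_false(any(cur$protein_id == "P2"))
})

test_that("curation is idempotent and errors on missing columns", {
  raw <- toy_assay_table()
  once <- curate_assays(raw, mode = "dtm")
  twice <- curate_assays(once, mode = "dtm")
  expect_equal(twice, once)
  expect_error(curate_assays(raw[, c("mutant", "score")], mode = "dtm"),
               "missing required column")
})

test_that("rank correlation matches the closed-form rank formula", {
  expect_equal(spearman_rho(1:4, 1:4), 1)
  expect_equal(spearman_rho(4:1, 1:4), -1)
  # independent oracle: 1 - 6 sum(d^2) / (n (n^2 - 1)) on untied data
  pred <- c(1, 2, 3, 4, 5)
  exper <- c(2, 1, 4, 3, 5)
  d <- rank(pred) - rank(exper)
  oracle <- 1 - 6 * sum(d^2) / (5 * (25 - 1))
  expect_equal(oracle, 0.8)
  expect_equal(spearman_rho(pred, exper), oracle, tolerance = 1e-12)
  # random untied cases agree with the formula
  withr::with_seed(4, for (i in 1:20) {
    a <- sample(20); b <- sample(20)
    expect_equal(spearman_rho(a, b),
                 1 - 6 * sum((rank(a) - rank(b))^2) / (20 * 399),
                 tolerance = 1e-12)
  })
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:3, 1:4), "lengths differ")
  expect_error(spearman_rho(1, 1), "at least 2")
})

test_that("evaluation aggregates per-assay correlations into the macro mean", {
  st1 <- planted_setup(n = 20, n_mutants = 15, seed = 11)
  st2 <- planted_setup(n = 25, n_mutants = 20, seed = 12)
  scored <- dplyr::bind_rows(
    score_variants(dplyr::mutate(st1$assay, assay = "A-7.0"), st1$logprobs,
                   wt_sequence = st1$structure$sequence),
    score_variants(dplyr::mutate(st2$assay, assay = "B-7.0"), st2$logprobs,
                   wt_sequence = st2$structure$sequence)
  )
  ev <- evaluate_assays(scored)
  expect_equal(nrow(ev$per_assay), 2)
  expect_equal(ev$macro_mean, mean(ev$per_assay$rho))
  expect_equal(ev$per_assay$rho, c(1, 1))
  expect_s3_class(tidy(ev), "tbl_df")
  expect_true(is.na(glance(ev)$bootstrap_sd))
  expect_s3_class(autoplot(ev), "ggplot")
})

test_that("bootstrap summary behaves as specified", {
  # constant correlations: mean c, sd 0 for any seed
  bs <- bootstrap_summary(rep(0.42, 8), seed = 3)
  expect_equal(bs$mean, 0.42, tolerance = 1e-12)
  expect_equal(bs$sd, 0)
  # frac = 1: every run identical, sd 0
  rho <- c(0.1, 0.5, 0.9, 0.3)
  bs1 <- bootstrap_summary(rho, frac = 1, seed = 4)
  expect_equal(bs1$sd, 0)
  expect_equal(bs1$mean, mean(rho), tolerance = 1e-12)
  # determinism
  expect_identical(bootstrap_summary(rho, seed = 5), bootstrap_summary(rho, seed = 5))
  expect_error(bootstrap_summary(rho, frac = 0), "frac")
  expect_error(bootstrap_summary(rho, frac = 1.5), "frac")
  expect_error(bootstrap_summary(0.5, seed = 1), "at least 2")
})

test_that("bootstrap mean converges to the macro mean with many runs", {
  rho <- withr::with_seed(6, runif(9, -0.2, 0.9))
  bs <- bootstrap_summary(rho, frac = 0.5, runs = 1e4, seed = 7)
  expect_lt(abs(bs$mean - mean(rho)), 0.01)
})

test_that("evaluation reports write CSV and JSON", {
  ev <- structure(list(per_assay = tibble::tibble(assay = c("A", "B"),
                                                  n_mutants = c(10L, 12L),
                                                  rho = c(0.5, 0.7)),
                       macro_mean = 0.6),
                  class = "vep_eval")
  ev <- add_bootstrap(ev, seed = 1)
  prefix <- tempfile()
  write_eval_report(ev, prefix)
  csv <- read.csv(paste0(prefix, ".csv"))
  expect_equal(csv$rho, c(0.5, 0.7))
  js <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(js$macro_mean, 0.6)
  expect_true(!is.null(js$bootstrap_sd))
  unlink(paste0(prefix, c(".csv", ".json")))
})
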