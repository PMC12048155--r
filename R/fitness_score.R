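# Zero-shot log-odds variant scoring -------------------------------------

#' Parse a mutation string
#'
#' Accepts deep-mutational-scanning convention strings like `"A24G"` or
#' multi-site `"A24G:T56W"` (1-based positions) and validates each stated
#' wild-type residue against the reference sequence.
#'
#' @param text Mutation string.
#' @param wt_sequence Wild-type sequence the positions refer to.
#' @return A `mutant`: tibble with columns `position`, `wt`, `mut` and the
#'   raw string as an attribute.
#' @export
parse_mutant <- function(text, wt_sequence) {
  wt_chars <- as_site_chars(wt_sequence)
  toks <- strsplit(text, ":", fixed = TRUE)[[1]]
  if (length(toks) == 0L || !all(grepl("^[A-Z][0-9]+[A-Z]$", toks))) {
    stop("malformed mutation string: '", text, "'")
  }
  position <- as.integer(sub("^[A-Z]([0-9]+)[A-Z]$", "\\1", toks))
  wt <- sub("^([A-Z])[0-9]+[A-Z]$", "\\1", toks)
  mut <- sub("^[A-Z][0-9]+([A-Z])$", "\\1", toks)
  if (anyDuplicated(position)) stop("duplicate positions in mutant '", text, "'")
  bad <- position < 1 | position > length(wt_chars)
  if (any(bad)) {
    stop("position ", position[which(bad)[1]], " outside sequence of length ",
         length(wt_chars))
  }
  mism <- wt != wt_chars[position]
  if (any(mism)) {
    p <- position[which(mism)[1]]
    stop(sprintf("wild-type mismatch at position %d: mutant says '%s', sequence has '%s'",
                 p, wt[which(mism)[1]], wt_chars[p]))
  }
  out <- tibble::tibble(position = position, wt = wt, mut = mut)
  attr(out, "raw") <- text
  class(out) <- c("mutant", class(out))
  out
}

#' Log-odds fitness score of a mutant
#'
#' Given the log-probability matrix of the wild-type forward pass (the
#' reference state shared by all mutants of a protein), the fitness score is
#' the sum over mutated sites of
#' `log p(mutant residue) - log p(wild-type residue)`.
#'
#' @param logprobs `n x 33` row-normalized log-probability matrix.
#' @param mutant A `mutant` from [parse_mutant()].
#' @return A `fitness_score`: list with `value` and `per_site` tibble.
#' @export
score_mutant <- function(logprobs, mutant) {
  if (any(mutant$position > nrow(logprobs))) {
    stop("mutant position exceeds the number of scored sites")
  }
  vocab <- token_vocabulary()
  mut_tok <- match(mutant$mut, vocab)
  wt_tok <- match(mutant$wt, vocab)
  contrib <- logprobs[cbind(mutant$position, mut_tok)] -
    logprobs[cbind(mutant$position, wt_tok)]
  structure(
    list(value = sum(contrib),
         per_site = tibble::tibble(position = mutant$position,
                                   wt = mutant$wt, mut = mutant$mut,
                                   log_odds = contrib)),
    class = "fitness_score"
  )
}

#' @export
print.fitness_score <- function(x, ...) {
  cat("<fitness_score> F = ", sprintf("%.4f", x$value), " over ",
      nrow(x$per_site), " site(s)\n", sep = "")
  invisible(x)
}

#' Average fitness scores across an ensemble of models
#'
#' Arithmetic mean of the log-odds scores (and of the per-site
#' contributions) of the same mutant under several model configurations.
#' Set `rank_average = TRUE` when combining whole score vectors elsewhere;
#' here scores of one mutant are averaged directly.
#'
#' @param scores Nonempty list of `fitness_score` objects for one mutant.
#' @return A `fitness_score`.
#' @export
ensemble_score <- function(scores) {
  if (length(scores) == 0L) stop("ensemble_score needs a nonempty list")
  per_site <- scores[[1]]$per_site
  contribs <- matrix(vapply(scores, function(s) s$per_site$log_odds,
                            numeric(nrow(per_site))),
                     nrow = nrow(per_site))
  per_site$log_odds <- rowMeans(contribs)
  structure(list(value = mean(vapply(scores, `[[`, numeric(1), "value")),
                 per_site = per_site),
            class = "fitness_score")
}

#' Score a table of variants against one or more models
#'
#' Data-frame-first scoring: takes an assay tibble with a `mutant` column,
#' runs one wild-type forward pass per model, and appends a `pred` column
#' with the (ensemble-averaged) log-odds fitness of each variant.
#'
#' @param data Tibble with a `mutant` column (DMS string convention).
#' @param models An `egnn_denoiser`, a list of them (ensemble), or a
#'   precomputed `n x 33` log-probability matrix (or list of matrices).
#' @param structure The wild-type `protein_structure` (required when
#'   `models` contains fitted models; for matrices only the sequence is
#'   needed).
#' @param wt_sequence Wild-type sequence; defaults to the structure's.
#' @param rank_average Combine ensemble members by averaging ranks instead
#'   of raw scores (default FALSE: mean of raw scores).
#' @return The input tibble with a `pred` column.
#' @export
score_variants <- function(data, models, structure = NULL, wt_sequence = NULL,
                           rank_average = FALSE) {
  if (!"mutant" %in% names(data)) stop("data must have a 'mutant' column")
  if (inherits(models, "egnn_denoiser") || is.matrix(models)) models <- list(models)
  if (is.null(wt_sequence)) {
    if (is.null(structure)) stop("supply a structure or a wt_sequence")
    wt_sequence <- structure$sequence
  }
  lp_list <- lapply(models, function(m) {
    if (is.matrix(m)) m else model_logprobs(m, structure)
  })
  mutants <- lapply(data$mutant, parse_mutant, wt_sequence = wt_sequence)
  member_scores <- vapply(lp_list, function(lp) {
    vapply(mutants, function(mu) score_mutant(lp, mu)$value, numeric(1))
  }, numeric(nrow(data)))
  member_scores <- matrix(member_scores, nrow = nrow(data))
  pred <- if (rank_average && ncol(member_scores) > 1) {
    rowMeans(apply(member_scores, 2, rank))
  } else {
    rowMeans(member_scores)
  }
  dplyr::mutate(data, pred = pred)
}
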