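# Benchmark curation and rank-correlation evaluation ---------------------

#' Curate raw mutation assay records into named assays
#'
#' Groups records by protein and experimental condition and applies the
#' thermostability benchmark filters: melting-temperature mode (`"dtm"`)
#' drops multi-site (continuous) mutants and names assays
#' `"<protein>-<pH>"`; folding-free-energy mode (`"ddg"`) drops records
#' whose stated wild-type residue cannot be aligned with the reference
#' sequence at the stated position and names assays
#' `"<protein>-<pH>-<temperature>"` (pH with one decimal, temperature as
#' integer Celsius). Groups retaining fewer than 10 mutants are dropped,
#' as are duplicate mutant strings within a group (first kept). Curation is
#' idempotent.
#'
#' @param data Tibble with columns `protein_id`, `mutant`, `score`, `ph`
#'   (and `temperature` for ddg mode).
#' @param mode `"dtm"` or `"ddg"`.
#' @param reference_sequences Named character vector or list mapping
#'   protein id to wild-type sequence (required for ddg mode).
#' @param min_mutants Minimum surviving mutants per assay (default 10).
#' @return Tibble of surviving records with an added `assay` name column.
#' @export
curate_assays <- function(data, mode = c("dtm", "ddg"),
                          reference_sequences = NULL, min_mutants = 10) {
  mode <- match.arg(mode)
  need <- c("protein_id", "mutant", "score", "ph")
  if (mode == "ddg") need <- c(need, "temperature")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- tibble::as_tibble(data)

  if (mode == "dtm") {
    out <- dplyr::filter(out, !grepl(":", .data$mutant, fixed = TRUE))
    out <- dplyr::mutate(out, assay = sprintf("%s-%.1f", .data$protein_id, .data$ph))
  } else {
    if (is.null(reference_sequences)) {
      stop("ddg mode requires reference_sequences")
    }
    aligned <- vapply(seq_len(nrow(out)), function(i) {
      ref <- reference_sequences[[out$protein_id[i]]]
      if (is.null(ref) || is.na(ref)) return(FALSE)
      ok <- TRUE
      for (tok in strsplit(out$mutant[i], ":", fixed = TRUE)[[1]]) {
        if (!grepl("^[A-Z][0-9]+[A-Z]$", tok)) return(FALSE)
        pos <- as.integer(sub("^[A-Z]([0-9]+)[A-Z]$", "\\1", tok))
        wt <- sub("^([A-Z]).*$", "\\1", tok)
        if (pos < 1 || pos > nchar(ref) || substr(ref, pos, pos) != wt) ok <- FALSE
      }
      ok
    }, logical(1))
    out <- out[aligned, , drop = FALSE]
    out <- dplyr::mutate(out, assay = sprintf("%s-%.1f-%d", .data$protein_id,
                                              .data$ph, as.integer(round(.data$temperature))))
  }

  out <- dplyr::distinct(out, .data$assay, .data$mutant, .keep_all = TRUE)
  out <- dplyr::group_by(out, .data$assay)
  out <- dplyr::filter(out, dplyr::n() >= min_mutants)
  out <- dplyr::ungroup(out)
  dplyr::relocate(out, "assay")
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; errors on degenerate input
#' (unequal or too-short vectors, or a constant side) rather than returning
#' NA.
#'
#' @param predicted,experimental Numeric vectors of equal length >= 2.
#' @return Correlation between -1 and 1.
#' @export
spearman_rho <- function(predicted, experimental) {
  if (length(predicted) != length(experimental)) {
    stop("predicted and experimental lengths differ")
  }
  if (length(predicted) < 2) stop("need at least 2 paired observations")
  if (stats::sd(predicted) == 0 || stats::sd(experimental) == 0) {
    stop("rank correlation undefined for a constant vector")
  }
  stats::cor(predicted, experimental, method = "spearman")
}

#' Per-assay rank correlation of predictions
#'
#' @param data Curated tibble with columns `assay`, `score` (experimental)
#'   and `pred` (model score).
#' @return A `vep_eval`: per-assay correlations and the unweighted macro
#'   mean, with [generics::tidy()] / [generics::glance()] methods.
#' @export
evaluate_assays <- function(data) {
  need <- c("assay", "score", "pred")
  if (!all(need %in% names(data))) {
    stop("data must have columns ", paste(need, collapse = ", "))
  }
  per_assay <- data |>
    dplyr::group_by(.data$assay) |>
    dplyr::summarise(n_mutants = dplyr::n(),
                     rho = spearman_rho(.data$pred, .data$score),
                     .groups = "drop")
  structure(list(per_assay = per_assay,
                 macro_mean = mean(per_assay$rho)),
            class = "vep_eval")
}

#' @export
print.vep_eval <- function(x, ...) {
  cat("<vep_eval> ", nrow(x$per_assay), " assay(s); macro-mean Spearman rho = ",
      sprintf("%.3f", x$macro_mean), "\n", sep = "")
  if (!is.null(x$bootstrap)) {
    cat("  bootstrap (frac ", x$bootstrap$frac, ", ", x$bootstrap$runs,
        " runs): mean ", sprintf("%.3f", x$bootstrap$mean), ", sd ",
        sprintf("%.3f", x$bootstrap$sd), "\n", sep = "")
  }
  invisible(x)
}

#' Bootstrap summary of assay-level correlations
#'
#' Per run, samples a fraction of the assays (without replacement by
#' default, matching the reported resampling of 50% of the samples over 10
#' independent runs) and averages their correlations; reports the mean and
#' standard deviation across runs. A per-mutant resampling mode and a
#' with-replacement mode are available behind flags.
#'
#' @param rho Numeric vector of per-assay correlations, or a `vep_eval`.
#' @param frac Fraction sampled per run, in (0, 1] (default 0.5).
#' @param runs Number of independent runs (default 10).
#' @param seed Integer seed.
#' @param replace Sample with replacement (default FALSE).
#' @param data Optional curated tibble with `assay`, `score`, `pred`
#'   columns; when supplied with `unit = "mutant"`, each run resamples
#'   mutants within every assay and recomputes the correlations.
#' @param unit `"assay"` (default) or `"mutant"`.
#' @return List with `mean`, `sd`, `frac`, `runs` and the per-run means.
#' @export
bootstrap_summary <- function(rho, frac = 0.5, runs = 10, seed = 1,
                              replace = FALSE, data = NULL,
                              unit = c("assay", "mutant")) {
  unit <- match.arg(unit)
  if (frac <= 0 || frac > 1) stop("frac must lie in (0, 1]")
  if (inherits(rho, "vep_eval")) rho <- rho$per_assay$rho
  run_means <- withr::with_seed(seed, {
    vapply(seq_len(runs), function(r) {
      if (unit == "assay") {
        if (length(rho) < 2) stop("need at least 2 assays to bootstrap")
        take <- ceiling(frac * length(rho))
        mean(sample(rho, take, replace = replace))
      } else {
        if (is.null(data)) stop("unit = 'mutant' requires the curated data")
        resampled <- data |>
          dplyr::group_by(.data$assay) |>
          dplyr::slice_sample(prop = frac, replace = replace) |>
          dplyr::summarise(rho = spearman_rho(.data$pred, .data$score),
                           .groups = "drop")
        mean(resampled$rho)
      }
    }, numeric(1))
  })
  list(mean = mean(run_means), sd = stats::sd(run_means), frac = frac,
       runs = runs, run_means = run_means)
}

#' Attach a bootstrap summary to an evaluation
#'
#' @param eval_result A `vep_eval`.
#' @inheritParams bootstrap_summary
#' @return The `vep_eval` with a `bootstrap` element.
#' @export
add_bootstrap <- function(eval_result, frac = 0.5, runs = 10, seed = 1,
                          replace = FALSE) {
  eval_result$bootstrap <- bootstrap_summary(eval_result$per_assay$rho,
                                             frac = frac, runs = runs,
                                             seed = seed, replace = replace)
  eval_result
}

#' Write an evaluation report as CSV and JSON
#'
#' @param eval_result A `vep_eval`.
#' @param prefix Output path prefix (`<prefix>.csv`, `<prefix>.json`).
#' @return The two paths, invisibly.
#' @export
write_eval_report <- function(eval_result, prefix) {
  csv <- paste0(prefix, ".csv")
  js <- paste0(prefix, ".json")
  utils::write.csv(eval_result$per_assay, csv, row.names = FALSE)
  payload <- list(macro_mean = eval_result$macro_mean)
  if (!is.null(eval_result$bootstrap)) {
    payload$bootstrap_mean <- eval_result$bootstrap$mean
    payload$bootstrap_sd <- eval_result$bootstrap$sd
  }
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
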