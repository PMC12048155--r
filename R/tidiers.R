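# broom-style tidiers and ggplot2 autoplot methods -----------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training trace of a denoiser
#'
#' @param x An `egnn_denoiser`.
#' @param ... Unused.
#' @return Tibble with columns `epoch`, `loss` (mean per-token loss).
#' @export
tidy.egnn_denoiser <- function(x, ...) x$trace

#' One-row summary of a trained denoiser
#'
#' @param x An `egnn_denoiser`.
#' @param ... Unused.
#' @return Tibble with layers, hidden width, k, parameter count, epochs and
#'   final per-token loss.
#' @export
glance.egnn_denoiser <- function(x, ...) {
  tibble::tibble(
    layers = x$egnn_config$layers,
    hidden = x$egnn_config$hidden,
    k = x$graph_config$k,
    n_parameters = n_params(x$params),
    epochs = nrow(x$trace),
    final_loss = utils::tail(x$trace$loss, 1)
  )
}

#' Loss-trace plot for a trained denoiser
#'
#' @param object An `egnn_denoiser`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.egnn_denoiser <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = log(33), linetype = "dashed") +
    ggplot2::labs(x = "epoch", y = "per-token cross-entropy",
                  caption = "dashed: uniform-guess level ln 33") +
    ggplot2::theme_minimal()
}

#' Tidy per-assay evaluation results
#'
#' @param x A `vep_eval`.
#' @param ... Unused.
#' @return Tibble with `assay`, `n_mutants`, `rho`.
#' @export
tidy.vep_eval <- function(x, ...) x$per_assay

#' One-row evaluation summary
#'
#' @param x A `vep_eval`.
#' @param ... Unused.
#' @return Tibble with assay count, macro-mean correlation, and bootstrap
#'   mean/sd when available.
#' @export
glance.vep_eval <- function(x, ...) {
  tibble::tibble(
    n_assays = nrow(x$per_assay),
    macro_mean = x$macro_mean,
    bootstrap_mean = if (is.null(x$bootstrap)) NA_real_ else x$bootstrap$mean,
    bootstrap_sd = if (is.null(x$bootstrap)) NA_real_ else x$bootstrap$sd
  )
}

#' Per-assay correlation plot
#'
#' @param object A `vep_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vep_eval <- function(object, ...) {
  df <- object$per_assay
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$assay, .data$rho),
                                   y = .data$rho)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$macro_mean, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Spearman rho",
                  caption = "dashed: macro mean") +
    ggplot2::theme_minimal()
}
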