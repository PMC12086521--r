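#' Plot a fold-difference sweep
#'
#' Fold difference against the swept threshold with the fitted
#' ordinary-least-squares line.
#'
#' @param object An `fd_sweep` (from [ddg_sweep()] or [rsa_sweep()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fd_sweep <- function(object, ...) {
  lab <- if (object$axis == "folding_ddg") {
    "folding ΔΔG threshold (kcal/mol)"
  } else {
    "RSA cutoff"
  }
  p <- ggplot2::ggplot(object$profile,
                       ggplot2::aes(x = .data$threshold, y = .data$fd)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = lab, y = "fold difference (case / control)")
  if (is.finite(object$slope)) {
    p <- p + ggplot2::geom_abline(slope = object$slope,
                                  intercept = object$intercept,
                                  linetype = "dashed")
  }
  p
}

#' Plot node-removal fractions across allele-frequency bins
#'
#' @param object A `binned_result` (from [af_fraction_profile()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.binned_result <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$bin, y = .data$fraction,
                               fill = .data$type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$fraction - .data$se,
                   ymax = .data$fraction + .data$se),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3) +
    ggplot2::labs(x = "allele-frequency bin", y = "fraction of variants")
}

#' Edgotype composition per cohort
#'
#' Stacked fractions of quasi-wildtype, edgetic, and quasi-null calls among
#' classified missense mutations, per cohort.
#'
#' @param calls Classified calls tibble (see [run_pipeline()]).
#' @return A ggplot object.
#' @export
plot_edgotype_fractions <- function(calls) {
  x <- calls |>
    filter(.data$class == "missense", !is.na(.data$label)) |>
    count(.data$cohort, .data$label) |>
    group_by(.data$cohort) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup() |>
    mutate(label = factor(.data$label, levels = c("quasi-wildtype",
                                                  "edgetic", "quasi-null")))
  ggplot2::ggplot(x, ggplot2::aes(x = .data$cohort, y = .data$fraction,
                                  fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of classified missense mutations",
                  fill = "edgotype")
}
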