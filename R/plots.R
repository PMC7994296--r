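# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a distance matrix
#'
#' @param object A `fcdyn_dm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fcdyn_dm <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$subject_a, .data$subject_b, fill = .data$distance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      title = sprintf("%s distance matrix", attr(object, "modality")),
      x = NULL, y = NULL, fill = "distance"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Observed vs predicted trait values
#'
#' @param object A `fcdyn_krr`.
#' @param ... Unused.
#' @return A ggplot of out-of-sample predictions against the
#'   (confound-adjusted) observed trait, coloured by fold.
#' @export
autoplot.fcdyn_krr <- function(object, ...) {
  ggplot2::ggplot(
    object$predictions,
    ggplot2::aes(.data$y_target, .data$y_hat, colour = factor(.data$fold))
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::labs(
      title = sprintf("cross-validated prediction (r2 = %.3f)", object$r2),
      x = "observed", y = "predicted", colour = "fold"
    ) +
    ggplot2::theme_minimal()
}

#' Explained variance per trait for a set of predictions
#'
#' @param object A `fcdyn_prediction_set`.
#' @param ... Unused.
#' @return A ggplot bar chart of per-trait explained variance, shaded by
#'   Bonferroni significance.
#' @export
autoplot.fcdyn_prediction_set <- function(object, ...) {
  df <- dplyr::mutate(object$summary,
    significant = .data$p_bonferroni < 0.05
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$trait, .data$r2, alpha = .data$significant)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35)) +
    ggplot2::labs(x = NULL, y = expression(r^2), alpha = "Bonferroni p < 0.05") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Representation-similarity tiles per behavioural group
#'
#' @param object A `fcdyn_similarity`.
#' @param ... Unused.
#' @return A ggplot with one tile panel per behavioural group.
#' @export
autoplot.fcdyn_similarity <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$rep_a, .data$rep_b, fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~group) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Free-energy trace of a variational fit
#'
#' @param model A group-level `fcdyn_hmm`.
#' @return A ggplot of the (non-increasing) free energy per iteration.
#' @export
plot_free_energy <- function(model) {
  df <- tibble::tibble(
    iteration = seq_along(model$free_energy),
    free_energy = model$free_energy
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$free_energy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(y = "variational free energy") +
    ggplot2::theme_minimal()
}
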