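# ggplot2 views of the main result types

#' Plot held-out predictions against experiment
#'
#' Scatter of predicted vs experimental binding free energy with the
#' identity line; the subtitle reports MAE and Pearson R.
#'
#' @param object A `dia_cv` from [loo_cv()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dia_cv <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$dg_exptl, y = .data$dg_pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(Delta * G[exptl] ~ "(kcal/mol)"),
      y = expression(Delta * G[pred] ~ "(kcal/mol)"),
      title = "Leave-one-out predictions",
      subtitle = sprintf("MAE %.2f kcal/mol, Pearson R %.2f",
                         object$mae, object$pearson_r))
}

#' Plot a per-residue interaction profile
#'
#' Mean van der Waals and electrostatic residue-ligand energies with
#' fluctuation ribbons, the raw material of the direct-interaction models.
#'
#' @param profile Tibble from [ensemble_interaction_profile()].
#' @return A ggplot object.
#' @export
plot_interaction_profile <- function(profile) {
  long <- tidyr::pivot_longer(
    profile,
    cols = c("mean_vdw", "mean_ele"),
    names_to = "term", values_to = "mean")
  long$fluct <- ifelse(long$term == "mean_vdw",
                       profile$fluct_vdw[match(long$residue_index,
                                               profile$residue_index)],
                       profile$fluct_ele[match(long$residue_index,
                                               profile$residue_index)])
  long$term <- ifelse(long$term == "mean_vdw", "vdW", "electrostatic")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$residue_index,
                                     y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$fluct,
                                      ymax = .data$mean + .data$fluct),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~term, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "protein residue",
                  y = "residue-ligand energy (kcal/mol)")
}

#' Plot docking success rates
#'
#' @param rates Tibble from [success_rates()].
#' @return A ggplot object.
#' @export
plot_success_rates <- function(rates) {
  ggplot2::ggplot(rates, ggplot2::aes(x = factor(.data$threshold),
                                      y = .data$success_rate)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "RMSD threshold (Å)", y = "success rate")
}
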