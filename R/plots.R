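#' Box plots of PRS-coefficient estimates across working models
#'
#' Visualizes the replicate distribution of the estimated PRS effect for
#' each working model, with the generative effect as a dashed reference
#' line — the standard way to read off stratification bias at a glance.
#'
#' @param object An `eprs_eval` tibble from [run_scenario()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eprs_eval <- function(object, ...) {
  truth <- attr(object, "truth")[["beta1"]]
  df <- dplyr::filter(object, .data$is_prs_term)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model_label, y = .data$estimate)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(yintercept = truth, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = NULL, y = expression(hat(beta)[1]),
                  title = "Estimated PRS effect by working model") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot

#' MSE of the PRS-coefficient estimator per model
#'
#' Bar plot of the Monte-Carlo MSE with +/- one MC standard error, per
#' working model; when the summary carries a `gamma` column (from
#' [gamma_sweep()]) MSE is drawn against gamma, one line per model.
#'
#' @param summary A tibble from [summarize_evaluation()] or [gamma_sweep()].
#' @return A ggplot object.
#' @export
plot_evaluation_mse <- function(summary) {
  if ("gamma" %in% names(summary)) {
    return(
      ggplot2::ggplot(summary,
                      ggplot2::aes(x = .data$gamma, y = .data$mse,
                                   colour = .data$model_label)) +
        ggplot2::geom_line() +
        ggplot2::geom_pointrange(
          ggplot2::aes(ymin = .data$mse - .data$mse_mc_se,
                       ymax = .data$mse + .data$mse_mc_se)) +
        ggplot2::labs(x = expression(gamma), y = "MSE", colour = NULL) +
        ggplot2::theme_minimal()
    )
  }
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$model_label, y = .data$mse)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mse - .data$mse_mc_se,
                   ymax = .data$mse + .data$mse_mc_se), width = 0.2) +
    ggplot2::labs(x = NULL, y = "MSE") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Distributions of PRS, ePRS and rPRS across a cohort
#'
#' Overlaid density plots of the three score metrics; the calibrated rPRS
#' should center at zero regardless of the cohort's ancestry composition
#' while PRS and ePRS carry the ancestry signal.
#'
#' @param profile A tibble from [prs_profile()].
#' @return A ggplot object.
#' @export
plot_prs_profile <- function(profile) {
  df <- tidyr::pivot_longer(
    dplyr::select(profile, "individual_id", "eprs_kind", "prs", "eprs", "rprs"),
    cols = c("prs", "eprs", "rprs"),
    names_to = "metric", values_to = "value")
  df$metric <- factor(df$metric, levels = c("prs", "eprs", "rprs"),
                      labels = c("PRS", "ePRS", "rPRS"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, fill = .data$metric)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::facet_wrap(~ .data$eprs_kind) +
    ggplot2::labs(x = NULL, y = "density", fill = NULL) +
    ggplot2::theme_minimal()
}
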