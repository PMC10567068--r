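#' Plot the per-bin model error profile
#'
#' Visualizes the output of [profile_bins()]: one RMSE curve per model over
#' the flexibility bins, the picture behind the thresholded selector (classic
#' wins at the rigid end, the flexible-acceptor model at the flexible end,
#' with flip-flop in between).
#'
#' @param profile A tibble from [profile_bins()].
#' @return A ggplot object.
#' @export
plot_bin_profile <- function(profile) {
  long <- tidyr::pivot_longer(
    profile,
    cols = c("rmse_gse", "rmse_absolv", "rmse_gse_phib"),
    names_to = "model", values_to = "rmse")
  long$model <- c(rmse_gse = "GSE(classic)", rmse_absolv = "ABSOLV(GRP)",
                  rmse_gse_phib = "GSE(Phi,B)")[long$model]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$phi_avg, y = .data$rmse,
                                     colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(Phi[avg] ~ "in bin"),
                  y = "RMSE (log units)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot fitted coefficient functions against per-bin estimates
#'
#' @param fit A `flex_acceptor_fit` from [train_flex_acceptor()] or
#'   [fit_c_functions()].
#' @return A ggplot object with one facet per coefficient.
#' @export
plot_coefficient_functions <- function(fit) {
  stopifnot(inherits(fit, "flex_acceptor_fit"))
  pts <- tidyr::pivot_longer(fit$bin_fits, cols = c("c0", "c1", "c2"),
                             names_to = "coefficient", values_to = "value")
  grid <- seq(min(fit$bin_fits$key_mean), max(fit$bin_fits$key_mean),
              length.out = 200)
  curves <- tidyr::pivot_longer(c_coefficients(grid, fit$params),
                                cols = c("c0", "c1", "c2"),
                                names_to = "coefficient", values_to = "value")
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$key_mean, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curves, ggplot2::aes(x = .data$x)) +
    ggplot2::facet_wrap(~coefficient, scales = "free_y") +
    ggplot2::labs(x = expression(Phi + B), y = "coefficient") +
    ggplot2::theme_minimal()
}

#' Observed-versus-predicted plot with the +/- 0.5 log band
#'
#' @param data Output of [predict_solubility()] carrying `logs0_obs`.
#' @param column Prediction column to plot (default the selected model).
#' @return A ggplot object.
#' @export
plot_obs_vs_pred <- function(data, column = "logs0_selected") {
  stopifnot(column %in% names(data), "logs0_obs" %in% names(data))
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[column]], y = .data$logs0_obs)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_abline(slope = 1, intercept = c(-0.5, 0.5),
                         linetype = 3, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = expression(predicted ~ log ~ S[0]),
                  y = expression(observed ~ log ~ S[0])) +
    ggplot2::theme_minimal()
}
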