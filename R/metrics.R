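#' Validation-type prediction metrics
#'
#' Computes the four standard metrics for a set of (observed, predicted)
#' log10 molar solubilities, all of the "validation type" (referenced to the
#' observations, not to a refitted line):
#' \itemize{
#'   \item `rmse`: root-mean-square error, `sqrt(mean((obs - pred)^2))`.
#'   \item `r2`: `1 - SS_res / SS_tot` about the observed mean. This can be
#'     negative when the model does worse than predicting the mean.
#'   \item `bias`: `mean(obs - pred)`; negative when solubility is
#'     overestimated.
#'   \item `mpp`: measure of prediction performance, the percentage of
#'     compounds predicted within +/- 0.5 log unit of observation
#'     (boundary inclusive).
#' }
#' Pairs with a missing value on either side are dropped and counted in
#' `n_missing`.
#'
#' @param obs,pred Numeric vectors of equal length (at least 2 usable pairs).
#' @return A one-row tibble: `n`, `n_missing`, `r2`, `rmse`, `bias`, `mpp`.
#' @examples
#' solubility_metrics(c(0, 1, 2), c(1, 1, 1))
#' @export
solubility_metrics <- function(obs, pred) {
  if (length(obs) != length(pred)) {
    stop("`obs` and `pred` must have equal length", call. = FALSE)
  }
  ok <- is.finite(obs) & is.finite(pred)
  n_missing <- sum(!ok)
  obs <- obs[ok]; pred <- pred[ok]
  n <- length(obs)
  if (n < 2) stop("metrics need at least 2 complete pairs", call. = FALSE)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) {
    stop("observed values have zero variance; r2 is undefined", call. = FALSE)
  }
  res <- obs - pred
  tibble::tibble(
    n = n,
    n_missing = n_missing,
    r2 = 1 - sum(res^2) / ss_tot,
    rmse = sqrt(mean(res^2)),
    bias = mean(res),
    mpp = 100 * mean(abs(res) <= 0.5)
  )
}

#' Metrics for every model column of a prediction table
#'
#' Convenience wrapper applying [solubility_metrics()] to each model column
#' produced by [predict_solubility()], against `logs0_obs`.
#'
#' @param data Output of [predict_solubility()] with a `logs0_obs` column.
#' @return A tibble with one row per model.
#' @export
model_metrics <- function(data) {
  stopifnot("logs0_obs" %in% names(data))
  cols <- c(gse_classic = "logs0_gse", absolv_grp = "logs0_absolv_grp",
            gse_phib = "logs0_gse_phib", consensus = "logs0_consensus",
            selected = "logs0_selected")
  cols <- cols[cols %in% names(data)]
  purrr::imap_dfr(cols, function(col, model) {
    dplyr::bind_cols(tibble::tibble(model = model),
                     solubility_metrics(data$logs0_obs, data[[col]]))
  })
}
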