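#' Flexibility-thresholded "exclusive-or" model selection
#'
#' The decision tree induced from per-bin error profiling of a large
#' intrinsic-solubility database: very rigid molecules (`Phi < 1.66`) are
#' best served by the classic equation, very flexible ones (`Phi > 10.83`)
#' by the flexible-acceptor model, and in the middle domain the winner
#' flip-flops between grouped ABSOLV and the flexible-acceptor model, looked
#' up per flexibility bin ("exclusive or" behaviour).
#'
#' @param phi Kier flexibility index (vectorized).
#' @param rule Decision table with half-open intervals `[phi_lower,
#'   phi_upper)` and a `model` column; default [default_decision_rule()].
#' @return Character vector of model names (`"gse_classic"`, `"absolv_grp"`,
#'   `"gse_phib"`). Missing `phi` falls back to `"gse_classic"` with a
#'   warning, so rigid small molecules without a computable Phi still get a
#'   prediction.
#' @examples
#' xor_select(c(1, 5, 31.2))
#' @export
xor_select <- function(phi, rule = default_decision_rule()) {
  stopifnot(all(c("phi_lower", "phi_upper", "model") %in% names(rule)))
  rule <- rule[order(rule$phi_lower), , drop = FALSE]
  if (any(is.na(phi))) {
    warning("missing Phi: defaulting to the classic equation for ",
            sum(is.na(phi)), " record(s)", call. = FALSE)
  }
  vapply(phi, function(p) {
    if (is.na(p)) return("gse_classic")
    if (p < 0) stop("Phi must be non-negative", call. = FALSE)
    hit <- which(p >= rule$phi_lower & p < rule$phi_upper)
    rule$model[hit[1]]
  }, character(1))
}

#' Published simplified model recommendation
#'
#' The headline recommendation: below `Phi = 11` take the consensus (mean of
#' grouped ABSOLV and the flexible-acceptor model); for more flexible
#' molecules take the flexible-acceptor model alone.
#'
#' @param phi Kier flexibility index (vectorized); `NA` selects the classic
#'   equation as in [xor_select()].
#' @return Character vector of model names.
#' @examples
#' recommended_select(c(6.7, 11, 20))
#' @export
recommended_select <- function(phi) {
  ifelse(is.na(phi), "gse_classic",
         ifelse(phi < 11, "consensus", "gse_phib"))
}

#' Closest prediction to an observed solubility
#'
#' Given one observed log S0 and a set of model predictions, returns the
#' model whose prediction is nearest the observation and the signed residual
#' `obs - pred` (positive residual = solubility underestimated). Ties are
#' broken in favour of the first-listed model.
#'
#' @param obs A single finite observed log10 molar solubility.
#' @param preds Named numeric vector (or named list) of model predictions;
#'   `NA` entries are ignored.
#' @return A one-row tibble: `model`, `pred`, `residual`.
#' @examples
#' closest_prediction(-8.71, c(absolv_grp = -8.54, gse_classic = -6.48))
#' @export
closest_prediction <- function(obs, preds) {
  if (length(obs) != 1L || is.na(obs) || !is.finite(obs)) {
    stop("`obs` must be a single finite value", call. = FALSE)
  }
  preds <- unlist(preds)
  if (is.null(names(preds)) || any(!nzchar(names(preds)))) {
    stop("`preds` must be named by model", call. = FALSE)
  }
  preds <- preds[!is.na(preds)]
  if (length(preds) == 0L) {
    stop("no finite predictions supplied to closest_prediction()", call. = FALSE)
  }
  k <- which.min(abs(obs - preds))   # which.min keeps the first on ties
  tibble::tibble(model = names(preds)[k], pred = unname(preds[k]),
                 residual = obs - unname(preds[k]))
}
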