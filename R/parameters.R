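CHARGE_GROUPS <- c("acid", "base", "zwitterion", "neutral", "big", "quaternary")

MODEL_NAMES <- c("gse_classic", "absolv_grp", "gse_phib", "consensus")

#' Classic General Solubility Equation constants
#'
#' `log S0 = 0.5 - 1.0 clogP - 0.01 (mp - 25)`, Yalkowsky's pre-trained
#' three-constant form.
#' @return A list with `c0`, `c1`, `c2`.
#' @export
gse_classic_params <- function() {
  list(c0 = 0.5, c1 = -1.0, c2 = -0.01)
}

#' Published grouped-ABSOLV coefficient table
#'
#' Coefficients of the seven-term Abraham solvation equation
#' `log S0 = a0 + a1 A + a2 B + a3 S_pi + a4 E + a5 V + a6 A*B`,
#' refit separately within six compound groups: the four net-charge classes
#' at pH 7.4 (acids, bases, zwitterions, neutrals) plus big molecules
#' (MW > 800 Da) and quaternary ammonium compounds.
#'
#' @return A tibble with columns `group`, `a0`..`a6`.
#' @export
absolv_group_table <- function() {
  tibble::tribble(
    ~group,        ~a0,   ~a1,   ~a2,   ~a3,   ~a4,   ~a5,   ~a6,
    "acid",       -0.30,  0.26,  1.07,  0.04, -0.91, -1.80,  0.43,
    "base",       -0.39, -0.61,  1.95,  0.25, -1.67, -1.37,  0.09,
    "zwitterion",  1.52, -1.44,  0.88, -0.23, -1.02, -1.08,  0.38,
    "neutral",    -0.45, -0.18,  1.73,  0.10, -1.48, -1.36,  0.26,
    "big",        -3.76,  0.72,  0.61, -0.03, -0.47, -0.38, -0.02,
    "quaternary",  0.53, -1.23,  0.74, -0.04, -0.62, -0.49,  0.09
  )
}

#' Published flexible-acceptor coefficient-function parameters
#'
#' The eight constants b0..b7 defining the three coefficient functions of the
#' flexible-acceptor solubility equation, with `x = Phi + B`:
#' \deqn{c_0(x) = b_0 + b_1 e^{-b_2 x}}
#' \deqn{c_1(x) = b_3 + b_4 (1 - e^{-b_5 x})}
#' \deqn{c_2(x) = b_6 + b_7 x}
#' Published values: `c0 = -4.456 + 6.049 exp(-0.0817 x)`,
#' `c1 = -1.326 + 1.058 (1 - exp(-0.1226 x))`, `c2 = -0.941 + 0.0389 x`.
#'
#' @return A named list `b0`..`b7`.
#' @export
flex_acceptor_params <- function() {
  list(b0 = -4.456, b1 = 6.049, b2 = 0.0817,
       b3 = -1.326, b4 = 1.058, b5 = 0.1226,
       b6 = -0.941, b7 = 0.0389)
}

#' Default flexibility-binned model-selection rule
#'
#' The decision table behind the "exclusive-or" selector: below Phi = 1.66
#' the classic equation wins; above Phi = 10.83 the flexible-acceptor model
#' wins; in between the winner alternates between the grouped-ABSOLV and the
#' flexible-acceptor model, bin by bin. Middle-domain interval edges are the
#' midpoints between consecutive published bin-average Phi values.
#'
#' @return A tibble with half-open intervals `[phi_lower, phi_upper)` and the
#'   winning `model`; the intervals partition `[0, Inf)`.
#' @export
default_decision_rule <- function() {
  centers <- c(2.0, 3.0, 4.0, 5.0, 6.0, 7.0, 7.4, 7.8, 8.3, 9.0, 9.9)
  winners <- c("absolv_grp", "absolv_grp", "gse_phib", "absolv_grp",
               "gse_phib", "gse_phib", "absolv_grp", "gse_phib",
               "absolv_grp", "gse_phib", "absolv_grp")
  mid <- (centers[-1] + centers[-length(centers)]) / 2
  lower <- c(1.66, mid)
  upper <- c(mid, 10.83)
  tibble::tibble(
    phi_lower = c(0, lower, 10.83),
    phi_upper = c(1.66, upper, Inf),
    model = c("gse_classic", winners, "gse_phib")
  )
}

#' Assemble the full parameter bundle
#'
#' Bundles every coefficient set the predictors and selector need: the classic
#' equation constants, the six-group ABSOLV table, the eight flexible-acceptor
#' constants, and the selection rule. The defaults are the published values.
#'
#' @param linear_gse,absolv,flex,decision_rule Optional overrides for the
#'   respective components.
#' @return A list of class `solubility_params`.
#' @export
default_parameter_bundle <- function(linear_gse = gse_classic_params(),
                                     absolv = absolv_group_table(),
                                     flex = flex_acceptor_params(),
                                     decision_rule = default_decision_rule()) {
  bundle <- structure(
    list(linear_gse = linear_gse, absolv = absolv, flex = flex,
         decision_rule = decision_rule,
         provenance = "builtin published coefficients"),
    class = "solubility_params")
  validate_parameter_bundle(bundle)
}

validate_parameter_bundle <- function(bundle) {
  if (!is.list(bundle$linear_gse) ||
      !all(c("c0", "c1", "c2") %in% names(bundle$linear_gse))) {
    stop("parameter bundle: `linear_gse` must supply c0, c1, c2", call. = FALSE)
  }
  ab <- bundle$absolv
  if (!is.data.frame(ab) || !all(c("group", paste0("a", 0:6)) %in% names(ab))) {
    stop("parameter bundle: `absolv` must be a table with group, a0..a6", call. = FALSE)
  }
  missing_groups <- setdiff(CHARGE_GROUPS, ab$group)
  if (length(missing_groups) > 0L) {
    stop("parameter bundle: `absolv` table is missing group(s): ",
         paste(missing_groups, collapse = ", "), call. = FALSE)
  }
  fx <- bundle$flex
  if (!all(paste0("b", 0:7) %in% names(fx))) {
    stop("parameter bundle: `flex` must supply b0..b7", call. = FALSE)
  }
  if (!(fx$b2 > 0 && fx$b5 > 0)) {
    stop("parameter bundle: decay rates b2 and b5 must be positive", call. = FALSE)
  }
  dr <- bundle$decision_rule
  if (!is.data.frame(dr) ||
      !all(c("phi_lower", "phi_upper", "model") %in% names(dr))) {
    stop("parameter bundle: `decision_rule` must have phi_lower, phi_upper, model",
         call. = FALSE)
  }
  dr <- dr[order(dr$phi_lower), , drop = FALSE]
  if (dr$phi_lower[1] != 0 || !is.infinite(dr$phi_upper[nrow(dr)]) ||
      any(abs(dr$phi_upper[-nrow(dr)] - dr$phi_lower[-1]) > 1e-12)) {
    stop("parameter bundle: decision rule intervals must partition [0, Inf)",
         call. = FALSE)
  }
  bundle$decision_rule <- dr
  bundle
}

#' @export
print.solubility_params <- function(x, ...) {
  cat("<solubility_params>\n")
  cat("  linear GSE: c0 =", x$linear_gse$c0, " c1 =", x$linear_gse$c1,
      " c2 =", x$linear_gse$c2, "\n")
  cat("  ABSOLV groups:", paste(x$absolv$group, collapse = ", "), "\n")
  cat(sprintf("  flexible-acceptor: c0(x) = %.4g + %.4g exp(-%.4g x)\n",
              x$flex$b0, x$flex$b1, x$flex$b2))
  cat("  decision rule:", nrow(x$decision_rule), "intervals\n")
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Read a parameter bundle from JSON (or the builtin defaults)
#'
#' @param path Path to a JSON file written by [save_parameter_bundle()], or
#'   the token `"builtin"` for the published defaults. Sections absent from
#'   the file fall back to the builtin values with a message.
#' @return A validated `solubility_params` bundle.
#' @export
load_parameter_bundle <- function(path = "builtin") {
  if (identical(path, "builtin")) return(default_parameter_bundle())
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("malformed parameter JSON '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  defaults <- default_parameter_bundle()
  take <- function(section) {
    if (is.null(raw[[section]])) {
      message("parameter bundle: section '", section, "' missing, using builtin")
      defaults[[section]]
    } else raw[[section]]
  }
  absolv <- take("absolv")
  if (!is.data.frame(absolv)) absolv <- tibble::as_tibble(absolv)
  dr <- take("decision_rule")
  if (!is.data.frame(dr)) dr <- tibble::as_tibble(dr)
  dr$phi_upper[is.na(dr$phi_upper) | dr$phi_upper == "Inf"] <- Inf
  dr$phi_upper <- as.numeric(dr$phi_upper)
  bundle <- structure(
    list(linear_gse = as.list(take("linear_gse")),
         absolv = tibble::as_tibble(absolv),
         flex = as.list(take("flex")),
         decision_rule = dr,
         provenance = if (!is.null(raw$provenance)) raw$provenance else path),
    class = "solubility_params")
  validate_parameter_bundle(bundle)
}

#' Write a parameter bundle to JSON
#'
#' @param bundle A `solubility_params` bundle.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_parameter_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "solubility_params"))
  out <- unclass(bundle)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
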