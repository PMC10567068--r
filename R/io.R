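# canonical column names and accepted aliases (all matched case-insensitively)
COLUMN_ALIASES <- list(
  id = c("id", "name", "compound", "drug"),
  smiles = c("smiles", "smi"),
  clogp = c("clogp", "logp", "clog_p"),
  mp_c = c("mp_c", "mp", "melting_point", "mpt"),
  is_liquid = c("is_liquid", "liquid"),
  abraham_a = c("abraham_a", "a"),
  abraham_b = c("abraham_b", "b"),
  abraham_s = c("abraham_s", "s", "s_pi", "spi"),
  abraham_e = c("abraham_e", "e"),
  abraham_v = c("abraham_v", "v"),
  charge_class = c("charge_class", "class", "group"),
  mw = c("mw", "molecular_weight"),
  phi = c("phi", "kier_phi", "flexibility"),
  logs0_obs = c("logs0_obs", "logs0", "log_s0", "logs0_observed")
)

#' Read a compound table from CSV
#'
#' Reads a comma-separated, UTF-8, header-required CSV of compound records
#' and normalizes the column names to the canonical set (`id`, `smiles`,
#' `clogp`, `mp_c`, `is_liquid`, `abraham_a`..`abraham_v`, `charge_class`,
#' `mw`, `phi`, `logs0_obs`). Matching is case-insensitive and a small alias
#' map is applied (e.g. `logP` -> `clogp`, `B` -> `abraham_b`). Empty cells
#' and `NA` are missing values.
#'
#' @param path CSV file path.
#' @return A tibble with canonical column names; unrecognized columns are
#'   kept as-is.
#' @export
read_compound_csv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  data <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"),
                          progress = FALSE)
  if (nrow(data) == 0L) stop("no data rows in ", path, call. = FALSE)
  nm <- names(data)
  canon <- nm
  for (target in names(COLUMN_ALIASES)) {
    hit <- which(tolower(nm) %in% COLUMN_ALIASES[[target]])
    if (length(hit) > 0L) canon[hit[1]] <- target
  }
  names(data) <- canon
  for (col in c("clogp", "mp_c", "abraham_a", "abraham_b", "abraham_s",
                "abraham_e", "abraham_v", "mw", "phi", "logs0_obs")) {
    if (col %in% names(data)) data[[col]] <- as.numeric(data[[col]])
  }
  if ("is_liquid" %in% names(data)) data$is_liquid <- as.logical(data$is_liquid)
  tibble::as_tibble(data)
}

#' Write a prediction table to CSV
#'
#' Writes the output of [predict_solubility()]. Prediction columns are
#' rounded to 2 decimals by default (the precision at which such predictions
#' are conventionally reported); `full_precision = TRUE` keeps all digits.
#'
#' @param data Prediction tibble.
#' @param path Output CSV path.
#' @param full_precision Keep full floating precision (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_prediction_csv <- function(data, path, full_precision = FALSE) {
  if (!full_precision) {
    pred_cols <- intersect(
      c("phi", "logs0_gse", "logs0_absolv_grp", "logs0_gse_phib",
        "logs0_consensus", "logs0_selected"), names(data))
    data <- dplyr::mutate(data, dplyr::across(dplyr::all_of(pred_cols),
                                              ~ round(.x, 2)))
  }
  readr::write_csv(data, path, na = "")
  invisible(path)
}
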