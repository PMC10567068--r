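#' Partition compound records into contiguous key bins
#'
#' Sorts records on the chosen key (`phi` or `phi + B`) and splits them into
#' `n_bins` contiguous groups. The default equal-count (quantile) strategy
#' matches the near-equal bin populations of the original training protocol
#' and stabilizes the per-bin regressions; equal-width bins over the key
#' range are available as an alternative.
#'
#' @param data A data frame with `phi` (and `abraham_b` when
#'   `key = "phi_plus_b"`) and `logs0_obs`.
#' @param key `"phi_plus_b"` (default, the training key) or `"phi"` (the
#'   profiling key).
#' @param n_bins Number of bins (>= 2); requires at least `3 * n_bins`
#'   usable records.
#' @param strategy `"equal_count"` or `"equal_width"`.
#' @return The usable records, sorted on the key, with columns `key_value`
#'   and integer `bin` appended.
#' @export
bin_by_key <- function(data, key = c("phi_plus_b", "phi"), n_bins = 20,
                       strategy = c("equal_count", "equal_width")) {
  key <- match.arg(key)
  strategy <- match.arg(strategy)
  if (n_bins < 2) stop("`n_bins` must be at least 2", call. = FALSE)
  data <- tibble::as_tibble(data)
  kv <- switch(key, phi = data$phi, phi_plus_b = data$phi + data$abraham_b)
  keep <- !is.na(kv) & !is.na(data$logs0_obs)
  data <- data[keep, , drop = FALSE]
  kv <- kv[keep]
  if (nrow(data) < 3 * n_bins) {
    stop("binning needs at least ", 3 * n_bins, " records with `", key,
         "` and `logs0_obs`; got ", nrow(data), call. = FALSE)
  }
  ord <- order(kv)
  data <- data[ord, , drop = FALSE]
  kv <- kv[ord]
  data$key_value <- kv
  if (strategy == "equal_count") {
    data$bin <- as.integer(ceiling(seq_along(kv) / (length(kv) / n_bins)))
  } else {
    edges <- seq(min(kv), max(kv), length.out = n_bins + 1)
    data$bin <- pmin(findInterval(kv, edges, rightmost.closed = TRUE), n_bins)
  }
  data
}

#' Per-bin linear solubility fit
#'
#' Ordinary least squares of `logs0_obs ~ clogp + I((mp - 25)/100)` within
#' one bin, the per-bin step of the two-step flexible-acceptor training.
#' The melting term uses the liquid convention of [gse_linear()].
#'
#' @param bin A data frame with `clogp`, `mp_c` (optionally `is_liquid`) and
#'   `logs0_obs`; at least 3 complete records.
#' @param label Optional bin label used in error messages.
#' @return Named numeric vector `c(c0, c1, c2)` on the `(mp - 25)/100` scale.
#' @export
fit_bin_gse <- function(bin, label = NULL) {
  bin <- tibble::as_tibble(bin)
  is_liquid <- if ("is_liquid" %in% names(bin)) bin$is_liquid else FALSE
  melt <- melting_term(bin$mp_c, rep_len(is_liquid, nrow(bin))) / 100
  ok <- !is.na(bin$clogp) & !is.na(melt) & !is.na(bin$logs0_obs)
  d <- data.frame(y = bin$logs0_obs[ok], clogp = bin$clogp[ok], melt = melt[ok])
  tag <- if (is.null(label)) "" else paste0(" (bin ", label, ")")
  if (nrow(d) < 3) {
    stop("per-bin fit needs >= 3 complete records", tag, call. = FALSE)
  }
  if (stats::sd(d$clogp) == 0 || stats::sd(d$melt) == 0) {
    stop("per-bin design is rank deficient: constant clogP or melting term", tag,
         call. = FALSE)
  }
  fit <- stats::lm(y ~ clogp + melt, data = d)
  co <- stats::coef(fit)
  c(c0 = unname(co[1]), c1 = unname(co["clogp"]), c2 = unname(co["melt"]))
}

#' Fit the three coefficient functions to per-bin coefficients
#'
#' Second step of the flexible-acceptor training: given per-bin coefficient
#' estimates at bin-mean key values `x`, fits
#' `c0(x) = b0 + b1 exp(-b2 x)`, `c1(x) = b3 + b4 (1 - exp(-b5 x))` and the
#' line `c2(x) = b6 + b7 x` by least squares. The three sub-problems share
#' no parameters, so they are fitted independently (their joint optimum
#' equals the per-curve optima). The two exponential fits use multi-start
#' nonlinear least squares over a documented grid of decay rates, with a
#' Nelder-Mead refinement fallback when `nls` fails to converge.
#'
#' @param bin_fits A data frame with columns `key_mean`, `c0`, `c1`, `c2`
#'   (>= 8 rows, one per bin).
#' @return An object of class `flex_acceptor_fit`: list with `params`
#'   (b0..b7), `diagnostics` (per-curve r-squared and RMSE), and `bin_fits`.
#' @export
fit_c_functions <- function(bin_fits) {
  bin_fits <- tibble::as_tibble(bin_fits)
  req <- c("key_mean", "c0", "c1", "c2")
  if (!all(req %in% names(bin_fits))) {
    stop("`bin_fits` needs columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  bin_fits <- dplyr::arrange(bin_fits, .data$key_mean)
  if (nrow(bin_fits) < 8) {
    stop("fitting 8 constants needs at least 8 bins; got ", nrow(bin_fits),
         call. = FALSE)
  }
  x <- bin_fits$key_mean

  f0 <- fit_exp_decay(x, bin_fits$c0, direction = "decay")
  f1 <- fit_exp_decay(x, bin_fits$c1, direction = "saturate")
  lin <- stats::lm(c2 ~ key_mean, data = bin_fits)
  b6 <- unname(stats::coef(lin)[1]); b7 <- unname(stats::coef(lin)[2])

  params <- list(b0 = f0$asym, b1 = f0$amp, b2 = f0$rate,
                 b3 = f1$asym, b4 = f1$amp, b5 = f1$rate,
                 b6 = b6, b7 = b7)
  pred <- c_coefficients(x, params)
  diag_row <- function(obs, fit) {
    ss_res <- sum((obs - fit)^2)
    ss_tot <- sum((obs - mean(obs))^2)
    c(r2 = 1 - ss_res / ss_tot, rmse = sqrt(ss_res / length(obs)))
  }
  diagnostics <- tibble::tibble(
    coefficient = c("c0", "c1", "c2"),
    r2 = c(diag_row(bin_fits$c0, pred$c0)["r2"],
           diag_row(bin_fits$c1, pred$c1)["r2"],
           diag_row(bin_fits$c2, pred$c2)["r2"]),
    rmse = c(diag_row(bin_fits$c0, pred$c0)["rmse"],
             diag_row(bin_fits$c1, pred$c1)["rmse"],
             diag_row(bin_fits$c2, pred$c2)["rmse"]),
    n_bins = nrow(bin_fits)
  )
  structure(list(params = params, diagnostics = diagnostics,
                 bin_fits = bin_fits),
            class = "flex_acceptor_fit")
}

# y = asym + amp * exp(-rate x)        (direction "decay")
# y = asym + amp * (1 - exp(-rate x))  (direction "saturate")
# multi-start on the decay rate; optim fallback keeps training robust when
# nls hits a singular gradient on noisy bin coefficients
fit_exp_decay <- function(x, y, direction = c("decay", "saturate"),
                          rates = c(0.02, 0.05, 0.1, 0.2, 0.5), tol = 1e-10) {
  direction <- match.arg(direction)
  form <- if (direction == "decay") {
    y ~ asym + amp * exp(-rate * x)
  } else {
    y ~ asym + amp * (1 - exp(-rate * x))
  }
  d <- data.frame(x = x, y = y)
  start_for <- function(rate) {
    if (direction == "decay") {
      asym <- y[which.max(x)]; amp <- y[which.min(x)] - asym
    } else {
      asym <- y[which.min(x)]; amp <- y[which.max(x)] - asym
    }
    list(asym = asym, amp = amp, rate = rate)
  }
  ssq <- function(p) {
    fit <- if (direction == "decay") p[1] + p[2] * exp(-p[3] * x)
           else p[1] + p[2] * (1 - exp(-p[3] * x))
    sum((y - fit)^2)
  }
  best <- NULL
  for (r in rates) {
    fit <- tryCatch(
      suppressWarnings(
        stats::nls(form, data = d, start = start_for(r),
                   control = stats::nls.control(maxiter = 500, tol = tol,
                                                minFactor = 1e-12,
                                                scaleOffset = 1, warnOnly = TRUE))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      p <- stats::coef(fit)[c("asym", "amp", "rate")]
      val <- ssq(p)
      if (is.null(best) || val < best$val) best <- list(p = p, val = val)
    }
  }
  for (r in rates) {   # refinement / fallback on the raw objective
    st <- start_for(r)
    op <- stats::optim(unlist(st), ssq, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = tol))
    if (is.null(best) || op$value < best$val) {
      best <- list(p = stats::setNames(op$par, c("asym", "amp", "rate")),
                   val = op$value)
    }
  }
  if (is.null(best)) {
    stop("coefficient-function fit failed to converge from any start", call. = FALSE)
  }
  if (best$p[["rate"]] < 0) {
    stop("coefficient-function fit converged to a negative decay rate (",
         signif(best$p[["rate"]], 4), "); the bin coefficients do not follow ",
         "the expected exponential form", call. = FALSE)
  }
  list(asym = unname(best$p["asym"]), amp = unname(best$p["amp"]),
       rate = unname(best$p["rate"]), ssq = best$val)
}

#' Two-step flexible-acceptor training
#'
#' Runs the full published protocol: sort on `Phi + B`, split into `n_bins`
#' near-equal bins, fit `(c0, c1, c2)` in each bin by least squares, then fit
#' the three coefficient functions to the per-bin estimates.
#'
#' @param data Compound records with `phi`, `abraham_b`, `clogp`, `mp_c` and
#'   `logs0_obs`.
#' @param n_bins Number of `Phi + B` bins (default 20, as published).
#' @param strategy Binning strategy, see [bin_by_key()].
#' @return A `flex_acceptor_fit`; its `bin_fits` component is the per-bin
#'   coefficient table (`bin`, `key_mean`, `n_entries`, `c0`, `c1`, `c2`).
#' @export
train_flex_acceptor <- function(data, n_bins = 20,
                                strategy = c("equal_count", "equal_width")) {
  strategy <- match.arg(strategy)
  binned <- bin_by_key(data, key = "phi_plus_b", n_bins = n_bins,
                       strategy = strategy)
  bin_fits <- binned |>
    dplyr::group_by(.data$bin) |>
    dplyr::group_modify(function(d, key) {
      co <- fit_bin_gse(d, label = key$bin)
      tibble::tibble(key_mean = mean(d$key_value), n_entries = nrow(d),
                     c0 = co["c0"], c1 = co["c1"], c2 = co["c2"])
    }) |>
    dplyr::ungroup()
  fit <- fit_c_functions(bin_fits)
  fit$bin_fits <- bin_fits
  fit
}

#' @export
print.flex_acceptor_fit <- function(x, ...) {
  p <- x$params
  cat("<flex_acceptor_fit> over", nrow(x$bin_fits), "bins\n")
  cat(sprintf("  c0(x) = %.4g + %.4g exp(-%.4g x)\n", p$b0, p$b1, p$b2))
  cat(sprintf("  c1(x) = %.4g + %.4g (1 - exp(-%.4g x))\n", p$b3, p$b4, p$b5))
  cat(sprintf("  c2(x) = %.4g + %.4g x\n", p$b6, p$b7))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_c_functions
#' @param x A `flex_acceptor_fit`.
#' @param ... Unused.
#' @export
tidy.flex_acceptor_fit <- function(x, ...) {
  tibble::tibble(term = paste0("b", 0:7),
                 estimate = unlist(x$params, use.names = FALSE),
                 coefficient = rep(c("c0", "c1", "c2"), c(3, 3, 2)))
}

#' @rdname fit_c_functions
#' @export
glance.flex_acceptor_fit <- function(x, ...) {
  tidyr::pivot_wider(x$diagnostics[, c("coefficient", "r2", "rmse")],
                     names_from = "coefficient",
                     values_from = c("r2", "rmse")) |>
    dplyr::mutate(n_bins = x$diagnostics$n_bins[1])
}

#' Fit the grouped ABSOLV table from data
#'
#' Least-squares fit of the seven-term Abraham form (intercept, A, B, S_pi,
#' E, V, A*B) within each charge/size group. Groups with fewer than
#' `min_records` complete records are reported unfit (`NA` coefficients).
#'
#' @param data Compound records with Abraham descriptors, `logs0_obs`, and
#'   either a `group` column or inputs for [classify_group()].
#' @param min_records Per-group size floor (default 8, one row per
#'   coefficient plus one).
#' @return An object of class `absolv_fit`: list with `table` (same shape as
#'   [absolv_group_table()]), and `diagnostics` (per-group n, r2, rmse).
#' @export
fit_absolv_groups <- function(data, min_records = 8) {
  data <- tibble::as_tibble(data)
  if (!"group" %in% names(data)) data <- classify_group(data)
  need <- c("abraham_a", "abraham_b", "abraham_s", "abraham_e", "abraham_v",
            "logs0_obs")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0L) {
    stop("fit_absolv_groups needs column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ok <- stats::complete.cases(data[, c(need, "group")])
  data <- data[ok, , drop = FALSE]
  rows <- purrr::map(CHARGE_GROUPS, function(gname) {
    d <- data[data$group == gname, , drop = FALSE]
    if (nrow(d) < min_records) {
      return(list(coefs = stats::setNames(rep(NA_real_, 7), paste0("a", 0:6)),
                  n = nrow(d), r2 = NA_real_, rmse = NA_real_))
    }
    fit <- stats::lm(
      logs0_obs ~ abraham_a + abraham_b + abraham_s + abraham_e + abraham_v +
        I(abraham_a * abraham_b), data = d)
    co <- stats::setNames(unname(stats::coef(fit)), paste0("a", 0:6))
    res <- stats::residuals(fit)
    ss_tot <- sum((d$logs0_obs - mean(d$logs0_obs))^2)
    list(coefs = co, n = nrow(d), r2 = 1 - sum(res^2) / ss_tot,
         rmse = sqrt(mean(res^2)))
  })
  if (all(vapply(rows, function(r) anyNA(r$coefs), logical(1)))) {
    stop("no group reached the ", min_records, "-record floor; cannot fit",
         call. = FALSE)
  }
  table <- dplyr::bind_cols(
    tibble::tibble(group = CHARGE_GROUPS),
    dplyr::bind_rows(purrr::map(rows, function(r) as.list(r$coefs))))
  diagnostics <- tibble::tibble(
    group = CHARGE_GROUPS,
    n = vapply(rows, function(r) r$n, numeric(1)),
    r2 = vapply(rows, function(r) r$r2, numeric(1)),
    rmse = vapply(rows, function(r) r$rmse, numeric(1)))
  structure(list(table = table, diagnostics = diagnostics),
            class = "absolv_fit")
}

#' @export
print.absolv_fit <- function(x, ...) {
  cat("<absolv_fit>\n")
  print(x$table)
  invisible(x)
}

#' @rdname fit_absolv_groups
#' @param x An `absolv_fit`.
#' @param ... Unused.
#' @export
tidy.absolv_fit <- function(x, ...) {
  tidyr::pivot_longer(x$table, cols = dplyr::starts_with("a"),
                      names_to = "term", values_to = "estimate")
}

#' @rdname fit_absolv_groups
#' @export
glance.absolv_fit <- function(x, ...) {
  x$diagnostics
}

#' Per-bin model error profile
#'
#' Sorts records on `Phi`, bins them, and computes each base model's RMSE in
#' each bin together with the winning (lowest-RMSE) model — the profiling
#' that motivates the flexibility-thresholded selector. Exact RMSE ties are
#' broken in the order flexible-acceptor, grouped ABSOLV, classic (favouring
#' the model recommended for flexible chemical space).
#'
#' @param data Compound records carrying the descriptors all three models
#'   need plus `logs0_obs`.
#' @param params A `solubility_params` bundle.
#' @param n_bins Number of `Phi` bins (the published profile used 19).
#' @param strategy Binning strategy, see [bin_by_key()].
#' @return A tibble (one row per bin): `bin`, `phi_avg`, `n_entries`,
#'   `rmse_gse`, `rmse_absolv`, `rmse_gse_phib`, `best_model`.
#' @export
profile_bins <- function(data, params = default_parameter_bundle(),
                         n_bins = 19, strategy = c("equal_count", "equal_width")) {
  strategy <- match.arg(strategy)
  preds <- predict_solubility(data, params = params, selector = "consensus")
  usable <- !is.na(preds$logs0_obs) & !is.na(preds$phi) &
    !is.na(preds$logs0_gse) & !is.na(preds$logs0_absolv_grp) &
    !is.na(preds$logs0_gse_phib)
  n_dropped <- sum(!usable)
  if (n_dropped > 0L) {
    message("profile_bins: dropping ", n_dropped,
            " record(s) lacking an observation or a model input")
  }
  preds <- preds[usable, , drop = FALSE]
  binned <- bin_by_key(preds, key = "phi", n_bins = n_bins, strategy = strategy)
  rmse <- function(e) sqrt(mean(e^2))
  tie_order <- c(gse_phib = 1L, absolv_grp = 2L, gse_classic = 3L)
  binned |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      phi_avg = mean(.data$phi),
      n_entries = dplyr::n(),
      rmse_gse = rmse(.data$logs0_obs - .data$logs0_gse),
      rmse_absolv = rmse(.data$logs0_obs - .data$logs0_absolv_grp),
      rmse_gse_phib = rmse(.data$logs0_obs - .data$logs0_gse_phib),
      .groups = "drop") |>
    dplyr::mutate(best_model = purrr::pmap_chr(
      list(.data$rmse_gse, .data$rmse_absolv, .data$rmse_gse_phib),
      function(g, a, p) {
        v <- c(gse_classic = g, absolv_grp = a, gse_phib = p)
        cand <- names(v)[v == min(v)]
        cand[order(tie_order[cand])][1]
      }))
}
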