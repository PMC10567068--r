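#' Linear General Solubility Equation
#'
#' Evaluates `log S0 = c0 + c1 clogP + c2 (mp - 25)` for each compound. The
#' melting term is clamped to zero for liquids and low-melting solids
#' (`mp <= 25` C, or `is_liquid = TRUE`), the standard convention: a liquid
#' solute pays no crystal-lattice penalty.
#'
#' @param clogp Octanol-water log partition coefficient.
#' @param mp_c Melting point in Celsius; may be `NA` for liquids if
#'   `is_liquid` is given.
#' @param params A list with `c0`, `c1`, `c2` (classic-scale `c2`, i.e. per
#'   degree); defaults to the classic constants `(0.5, -1.0, -0.01)`.
#' @param is_liquid Logical; `TRUE` zeroes the melting term.
#' @return log10 molar intrinsic solubility; `NA` where `clogp` is missing or
#'   `mp_c` is missing for a non-liquid.
#' @examples
#' gse_linear(clogp = 2, mp_c = 125)   # 0.5 - 2 - 1 = -2.5
#' @export
gse_linear <- function(clogp, mp_c, params = gse_classic_params(),
                       is_liquid = FALSE) {
  n <- max(length(clogp), length(mp_c))
  clogp <- rep_len(clogp, n); mp_c <- rep_len(mp_c, n)
  is_liquid <- rep_len(is_liquid %|0|% FALSE, n)
  melt <- melting_term(mp_c, is_liquid)
  ifelse(is.na(clogp), NA_real_,
         params$c0 + params$c1 * clogp + params$c2 * melt)
}

# (mp - 25) with the liquid convention; NA when mp missing and not a liquid
melting_term <- function(mp_c, is_liquid) {
  is_liquid[is.na(is_liquid)] <- FALSE
  out <- ifelse(is_liquid | (!is.na(mp_c) & mp_c <= 25), 0, mp_c - 25)
  out
}

`%|0|%` <- function(x, y) if (is.null(x)) y else x

#' Grouped Abraham solvation (ABSOLV) solubility prediction
#'
#' Evaluates `log S0 = a0 + a1 A + a2 B + a3 S_pi + a4 E + a5 V + a6 A*B`
#' with the coefficient row of the compound's group.
#'
#' @param A,B,S_pi,E,V Abraham solute descriptors: H-bond acidity and
#'   basicity sums, dipolarity/polarizability, excess molar refractivity
#'   ((cm^3/mol)/10) and McGowan volume ((cm^3/mol)/100).
#' @param group Character vector of group labels among
#'   `r paste(CHARGE_GROUPS, collapse = ", ")`.
#' @param table Coefficient table as from [absolv_group_table()].
#' @return log10 molar intrinsic solubility; `NA` where any descriptor or the
#'   group is missing.
#' @examples
#' absolv_grp(A = 1, B = 0, S_pi = 0, E = 0, V = 0, group = "acid")
#' @export
absolv_grp <- function(A, B, S_pi, E, V, group, table = absolv_group_table()) {
  n <- max(length(A), length(B), length(S_pi), length(E), length(V), length(group))
  A <- rep_len(A, n); B <- rep_len(B, n); S_pi <- rep_len(S_pi, n)
  E <- rep_len(E, n); V <- rep_len(V, n); group <- rep_len(group, n)
  bad <- !is.na(group) & !group %in% table$group
  if (any(bad)) {
    stop("unknown ABSOLV group(s): ", paste(unique(group[bad]), collapse = ", "),
         call. = FALSE)
  }
  row <- match(group, table$group)
  with(table[row, , drop = FALSE],
       a0 + a1 * A + a2 * B + a3 * S_pi + a4 * E + a5 * V + a6 * A * B)
}

#' Coefficient functions of the flexible-acceptor equation
#'
#' Evaluates the three coefficient functions at `x = Phi + B`:
#' `c0(x) = b0 + b1 exp(-b2 x)` (decreasing: flexible H-bond acceptors are
#' less soluble in the model lipid reference state), `c1(x) = b3 + b4 (1 -
#' exp(-b5 x))` (increasing towards 0: lipophilicity matters less for
#' flexible molecules), `c2(x) = b6 + b7 x` (near the classic crystal-lattice
#' coefficient; note `c2` multiplies `(mp - 25)/100`, not `(mp - 25)`).
#'
#' @param x Non-negative `Phi + B` values.
#' @param params Named list `b0`..`b7`; defaults to the published constants.
#' @return A tibble with columns `x`, `c0`, `c1`, `c2`.
#' @examples
#' c_coefficients(0)   # c0 = 1.593, c1 = -1.326, c2 = -0.941
#' @export
c_coefficients <- function(x, params = flex_acceptor_params()) {
  if (any(x < 0, na.rm = TRUE)) {
    stop("`x = Phi + B` must be non-negative", call. = FALSE)
  }
  tibble::tibble(
    x = x,
    c0 = params$b0 + params$b1 * exp(-params$b2 * x),
    c1 = params$b3 + params$b4 * (1 - exp(-params$b5 * x)),
    c2 = params$b6 + params$b7 * x
  )
}

#' Flexible-acceptor solubility prediction
#'
#' The flexible-acceptor generalization of the solubility equation:
#' `log S0 = c0(x) + c1(x) clogP + c2(x) (mp - 25)/100` with `x = Phi + B`,
#' where Phi is the Kier molecular flexibility index and B the Abraham
#' H-bond basicity. For rigid weak acceptors (`x` near 0) it approaches a
#' classic-like equation; for large flexible acceptors the lipophilicity
#' slope flattens to about -0.27 and the intercept drops to about -4.5.
#'
#' @param clogp,mp_c,is_liquid As in [gse_linear()].
#' @param phi Kier flexibility index.
#' @param B Abraham H-bond basicity sum.
#' @param params Named list `b0`..`b7` (see [flex_acceptor_params()]).
#' @return log10 molar intrinsic solubility; `NA` where any required input is
#'   missing.
#' @examples
#' gse_phi_b(clogp = 0, mp_c = 25, phi = 0, B = 0)  # c0(0) = 1.593
#' @export
gse_phi_b <- function(clogp, mp_c, phi, B, params = flex_acceptor_params(),
                      is_liquid = FALSE) {
  n <- max(length(clogp), length(mp_c), length(phi), length(B))
  clogp <- rep_len(clogp, n); mp_c <- rep_len(mp_c, n)
  phi <- rep_len(phi, n); B <- rep_len(B, n)
  is_liquid <- rep_len(is_liquid %|0|% FALSE, n)
  x <- phi + B
  cc <- c_coefficients(ifelse(is.na(x), 0, pmax(x, 0)), params)
  melt <- melting_term(mp_c, is_liquid)
  ifelse(is.na(x) | is.na(clogp), NA_real_,
         cc$c0 + cc$c1 * clogp + cc$c2 * melt / 100)
}

#' Consensus of the grouped-ABSOLV and flexible-acceptor predictions
#'
#' @param absolv,gsephib log10 molar predictions from the two models.
#' @return Their arithmetic mean; `NA` where either is missing.
#' @examples
#' consensus(-2.05, -2.97)  # -2.51
#' @export
consensus <- function(absolv, gsephib) {
  (absolv + gsephib) / 2
}

#' Classify compounds into the six ABSOLV fitting groups
#'
#' Order of precedence: a user-supplied `charge_class` always wins; else
#' molecular weight above 800 Da makes a compound `big`; else a permanently
#' charged nitrogen with no acidic group makes it `quaternary`; else the net
#' charge at pH 7.4 is estimated from substructures on the SMILES-derived
#' graph (carboxylic/sulfonic/phosphonic acids and tetrazoles count as
#' acidic; aliphatic amines, amidines and guanidines as basic; both present
#' makes a zwitterion; neither, a neutral).
#'
#' @param data A data frame with (any of) `charge_class`, `mw`, `smiles`.
#' @return `data` with the `group` column filled in.
#' @export
classify_group <- function(data) {
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  cls <- if ("charge_class" %in% names(data)) as.character(data$charge_class)
         else rep(NA_character_, n)
  bad <- !is.na(cls) & !cls %in% CHARGE_GROUPS
  if (any(bad)) {
    stop("unknown charge_class value(s): ",
         paste(unique(cls[bad]), collapse = ", "), call. = FALSE)
  }
  mw <- if ("mw" %in% names(data)) data$mw else rep(NA_real_, n)
  smiles <- if ("smiles" %in% names(data)) data$smiles else rep(NA_character_, n)
  out <- cls
  for (i in seq_len(n)) {
    if (!is.na(out[i])) next
    mwi <- mw[i]
    g <- if (!is.na(smiles[i]) && nzchar(smiles[i])) {
      parse_smiles(smiles[i])
    } else NULL
    if (is.na(mwi) && !is.null(g)) mwi <- molecular_weight(g)
    if (!is.na(mwi) && mwi > 800) { out[i] <- "big"; next }
    if (is.null(g)) {
      stop("record ", i, ": cannot classify, no charge_class and no usable SMILES/MW",
           call. = FALSE)
    }
    out[i] <- classify_graph(g)
  }
  data$group <- out
  data
}

# substructure heuristic for net charge at pH 7.4
classify_graph <- function(g) {
  el <- g$atoms$element; arom <- g$atoms$aromatic
  chg <- g$atoms$charge; nh <- g$atoms$n_h
  deg <- atom_degree(g)
  n <- nrow(g$atoms)
  nbrs <- vector("list", n); dbl <- vector("list", n)
  if (nrow(g$bonds) > 0L) {
    for (k in seq_len(nrow(g$bonds))) {
      f <- g$bonds$from[k]; t <- g$bonds$to[k]
      nbrs[[f]] <- c(nbrs[[f]], t); nbrs[[t]] <- c(nbrs[[t]], f)
      if (g$bonds$order[k] == 2) {
        dbl[[f]] <- c(dbl[[f]], t); dbl[[t]] <- c(dbl[[t]], f)
      }
    }
  }
  has_acid <- FALSE; has_base <- FALSE; has_perm_cation <- FALSE
  for (i in seq_len(n)) {
    if (el[i] %in% c("C", "S", "P") && !arom[i]) {
      # X(=O)(...)O[H] : carboxylic / sulfonic / phosphonic acid
      o_double <- any(el[dbl[[i]]] == "O")
      oh <- any(vapply(nbrs[[i]], function(j) {
        el[j] == "O" && deg[j] == 1L && nh[j] > 0L && chg[j] == 0L
      }, logical(1)))
      if (o_double && oh) has_acid <- TRUE
    }
    if (el[i] == "N" && arom[i] && nh[i] > 0L) {
      # aromatic NH in an all-azole ring with >= 3 ring N => tetrazole-like acid
      ring_n <- sum(el[nbrs[[i]]] == "N" & arom[nbrs[[i]]])
      if (ring_n >= 1L) {
        n_arom_n <- sum(el == "N" & arom)
        if (n_arom_n >= 4L) has_acid <- TRUE
      }
    }
    if (el[i] == "N" && chg[i] > 0L) {
      if (deg[i] + nh[i] >= 4L && length(dbl[[i]]) == 0L) has_perm_cation <- TRUE
    }
    if (el[i] == "N" && !arom[i] && chg[i] == 0L) {
      sp3_amine <- length(dbl[[i]]) == 0L &&
        !any(arom[nbrs[[i]]]) &&
        !any(vapply(nbrs[[i]], function(j) any(el[dbl[[j]]] %in% c("O", "S")), logical(1)))
      if (sp3_amine && all(el[nbrs[[i]]] == "C")) {
        # amidine / guanidine carbon neighbour also counts as basic
        has_base <- TRUE
      }
      amidine <- any(vapply(nbrs[[i]], function(j) {
        el[j] == "C" && any(el[dbl[[j]]] == "N")
      }, logical(1)))
      if (amidine) has_base <- TRUE
    }
  }
  if (has_perm_cation && !has_acid) return("quaternary")
  if (has_acid && has_base) return("zwitterion")
  if (has_acid) return("acid")
  if (has_base) return("base")
  "neutral"
}

#' Predict intrinsic solubility with every model
#'
#' The main tabular entry point: takes a compound table, fills in missing
#' `phi`, `mw` and `group` from SMILES where possible, evaluates the three
#' base models and the consensus, and applies the requested selector.
#'
#' @param data A data frame of compound records; recognised columns (all
#'   optional except what each model needs): `id`, `smiles`, `clogp`, `mp_c`,
#'   `is_liquid`, `abraham_a`, `abraham_b`, `abraham_s`, `abraham_e`,
#'   `abraham_v`, `charge_class`, `mw`, `phi`, `logs0_obs`.
#' @param params A `solubility_params` bundle (default: published values).
#' @param selector One of `"recommended"` (consensus below Phi = 11, else
#'   flexible-acceptor), `"xor"` (the binned decision tree), `"consensus"`,
#'   `"gse"`, `"absolv"`, `"gsephib"`.
#' @param alpha_modified Passed to [flexibility_index()] when Phi must be
#'   computed from SMILES.
#' @return The input tibble with appended columns `phi`, `group`,
#'   `logs0_gse`, `logs0_absolv_grp`, `logs0_gse_phib`, `logs0_consensus`,
#'   `selected_model`, `logs0_selected`.
#' @examples
#' predict_solubility(tibble::tibble(
#'   clogp = 2, mp_c = 120, phi = 3.2, abraham_a = 0.5, abraham_b = 1.2,
#'   abraham_s = 1.0, abraham_e = 0.8, abraham_v = 1.5, charge_class = "neutral"
#' ))
#' @export
predict_solubility <- function(data, params = default_parameter_bundle(),
                               selector = c("recommended", "xor", "consensus",
                                            "gse", "absolv", "gsephib"),
                               alpha_modified = TRUE) {
  selector <- match.arg(selector)
  stopifnot(inherits(params, "solubility_params"))
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  col <- function(name) if (name %in% names(data)) data[[name]] else rep(NA_real_, n)

  smiles <- if ("smiles" %in% names(data)) data$smiles else rep(NA_character_, n)
  phi <- col("phi")
  need_phi <- is.na(phi) & !is.na(smiles) & nzchar(smiles %|NA|% "")
  if (any(need_phi)) {
    phi[need_phi] <- suppressWarnings(
      flexibility_index(smiles[need_phi], alpha_modified = alpha_modified))
  }
  mw <- col("mw")
  need_mw <- is.na(mw) & !is.na(smiles) & nzchar(smiles %|NA|% "")
  if (any(need_mw)) {
    mw[need_mw] <- purrr::map_dbl(smiles[need_mw],
                                  function(s) molecular_weight(parse_smiles(s)))
  }
  data$phi <- phi
  data$mw <- mw

  grp <- tryCatch(classify_group(data)$group, error = function(e) {
    if ("group" %in% names(data)) data$group else rep(NA_character_, n)
  })
  data$group <- grp

  is_liquid <- if ("is_liquid" %in% names(data)) data$is_liquid else FALSE
  logs0_gse <- gse_linear(col("clogp"), col("mp_c"),
                          params = params$linear_gse, is_liquid = is_liquid)
  logs0_absolv <- rep(NA_real_, n)
  have_abs <- !is.na(grp) &
    !is.na(col("abraham_a")) & !is.na(col("abraham_b")) &
    !is.na(col("abraham_s")) & !is.na(col("abraham_e")) & !is.na(col("abraham_v"))
  if (any(have_abs)) {
    logs0_absolv[have_abs] <- absolv_grp(
      A = col("abraham_a")[have_abs], B = col("abraham_b")[have_abs],
      S_pi = col("abraham_s")[have_abs], E = col("abraham_e")[have_abs],
      V = col("abraham_v")[have_abs], group = grp[have_abs],
      table = params$absolv)
  }
  logs0_phib <- gse_phi_b(col("clogp"), col("mp_c"), phi, col("abraham_b"),
                          params = params$flex, is_liquid = is_liquid)
  logs0_cons <- consensus(logs0_absolv, logs0_phib)

  preds <- tibble::tibble(gse_classic = logs0_gse, absolv_grp = logs0_absolv,
                          gse_phib = logs0_phib, consensus = logs0_cons)
  sel_model <- switch(selector,
    recommended = recommended_select(phi),
    xor = xor_select(phi, rule = params$decision_rule),
    consensus = rep("consensus", n),
    gse = rep("gse_classic", n),
    absolv = rep("absolv_grp", n),
    gsephib = rep("gse_phib", n))
  sel_value <- vapply(seq_len(n), function(i) preds[[sel_model[i]]][i], numeric(1))

  data$logs0_gse <- logs0_gse
  data$logs0_absolv_grp <- logs0_absolv
  data$logs0_gse_phib <- logs0_phib
  data$logs0_consensus <- logs0_cons
  data$selected_model <- sel_model
  data$logs0_selected <- sel_value
  data
}

`%|NA|%` <- function(x, y) ifelse(is.na(x), y, x)
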