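#' Simulate a compound descriptor table
#'
#' Generates synthetic compound records with the marginal descriptor ranges
#' of a large curated intrinsic-solubility database, and observed log S0
#' values from a chosen generating model plus Gaussian noise. Every training
#' and evaluation stage of the package can thereby be exercised without any
#' external data.
#'
#' Descriptors are drawn independently and uniformly within their ranges by
#' default (defaults: Phi in 0.4-43, Abraham B in 0.4-12.9, clogP in -5.8 to
#' 8.7, melting point 25-350 C, A in 0-2, S_pi in 0.5-3.5, E in 0.5-4, V in
#' 0.5-3, all on the usual Abraham scales). Charge classes are assigned by a
#' multinomial with proportions matching the published group sizes
#' (1578/945/641/4246/93/39). All draws are made record-by-record from one
#' stream, so the first `n` records are identical for any larger `n` at the
#' same seed.
#'
#' Two optional departures from independent-uniform sampling:
#' `phi_levels` restricts Phi to an evenly spaced discrete set (a stratified
#' design used by parameter-recovery studies: with one level per training
#' bin, binning introduces no within-bin coefficient variation and zero-noise
#' recovery is exact); `correlate_mw` couples molecular weight to Phi through
#' a linear link plus jitter, emulating the database's "comet" structure in
#' which large molecules are flexible.
#'
#' @param n Number of records.
#' @param model Generating model: `"gse_classic"`, `"gse_phib"`, or
#'   `"absolv_grp"`.
#' @param params Generating parameters: a `c0/c1/c2` list for
#'   `"gse_classic"`, a `b0..b7` list for `"gse_phib"`, or a coefficient
#'   table for `"absolv_grp"` (defaults: the published values).
#' @param noise_sd Gaussian noise SD on log S0 (log10 units; default 0.5,
#'   about the RMSE the transparent models achieve on drug-like test sets).
#' @param seed Integer seed; same seed, same table.
#' @param ranges Named list overriding any default descriptor range
#'   `c(lo, hi)`: `phi`, `b`, `clogp`, `mp_c`, `a`, `s`, `e`, `v`.
#' @param phi_levels If not `NULL`, draw Phi from this many evenly spaced
#'   levels across the Phi range instead of continuously.
#' @param correlate_mw If `TRUE`, molecular weight follows
#'   `60 + 45 * phi + noise` instead of being left `NA`.
#' @param group_weights Multinomial charge-class proportions, named by group.
#' @return A tibble of compound records in the canonical column layout, with
#'   `logs0_true` (noise-free model value) alongside `logs0_obs`.
#' @examples
#' simulate_compounds(5, model = "gse_classic", noise_sd = 0, seed = 1)
#' @export
simulate_compounds <- function(n,
                               model = c("gse_phib", "gse_classic", "absolv_grp"),
                               params = NULL,
                               noise_sd = 0.5,
                               seed = 1L,
                               ranges = list(),
                               phi_levels = NULL,
                               correlate_mw = FALSE,
                               group_weights = c(acid = 1578, base = 945,
                                                 zwitterion = 641, neutral = 4246,
                                                 big = 93, quaternary = 39)) {
  model <- match.arg(model)
  stopifnot(n >= 1, noise_sd >= 0)
  defaults <- list(phi = c(0.4, 43), b = c(0.4, 12.9), clogp = c(-5.8, 8.7),
                   mp_c = c(25, 350), a = c(0, 2), s = c(0.5, 3.5),
                   e = c(0.5, 4), v = c(0.5, 3))
  bad <- setdiff(names(ranges), names(defaults))
  if (length(bad) > 0L) stop("unknown range name(s): ",
                             paste(bad, collapse = ", "), call. = FALSE)
  rg <- utils::modifyList(defaults, ranges)
  for (nm in names(rg)) {
    if (length(rg[[nm]]) != 2L || rg[[nm]][1] > rg[[nm]][2]) {
      stop("range `", nm, "` must be c(lo, hi) with lo <= hi", call. = FALSE)
    }
  }
  if (is.null(params)) {
    params <- switch(model, gse_classic = gse_classic_params(),
                     gse_phib = flex_acceptor_params(),
                     absolv_grp = absolv_group_table())
  }
  gw <- group_weights / sum(group_weights)
  if (!setequal(names(gw), CHARGE_GROUPS)) {
    stop("`group_weights` must be named by the six charge groups", call. = FALSE)
  }
  gw <- gw[CHARGE_GROUPS]

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  # 10 draws per record, row-major: the stream is stable under growing n
  u <- matrix(stats::runif(n * 10L), ncol = 10L, byrow = TRUE)
  z <- stats::qnorm(u[, 10L])
  scale_to <- function(col, r) r[1] + u[, col] * (r[2] - r[1])

  phi <- if (is.null(phi_levels)) {
    scale_to(1L, rg$phi)
  } else {
    levels <- seq(rg$phi[1], rg$phi[2], length.out = phi_levels)
    levels[pmin(floor(u[, 1L] * phi_levels) + 1L, phi_levels)]
  }
  b <- scale_to(2L, rg$b)
  clogp <- scale_to(3L, rg$clogp)
  mp_c <- scale_to(4L, rg$mp_c)
  a <- scale_to(5L, rg$a)
  s_pi <- scale_to(6L, rg$s)
  e <- scale_to(7L, rg$e)
  v <- scale_to(8L, rg$v)
  grp <- CHARGE_GROUPS[findInterval(u[, 9L], cumsum(gw), left.open = TRUE) + 1L]
  noise <- if (noise_sd > 0) noise_sd * z else rep(0, n)

  logs0_true <- switch(model,
    gse_classic = gse_linear(clogp, mp_c, params = params),
    gse_phib = gse_phi_b(clogp, mp_c, phi, b, params = params),
    absolv_grp = absolv_grp(a, b, s_pi, e, v, grp, table = params))

  mw <- if (correlate_mw) {
    60 + 45 * phi + 20 * stats::qnorm(pmin(pmax(u[, 9L], 1e-9), 1 - 1e-9))
  } else rep(NA_real_, n)

  tibble::tibble(
    id = sprintf("SIM%06d", seq_len(n)),
    smiles = NA_character_,
    clogp = clogp, mp_c = mp_c, is_liquid = FALSE,
    abraham_a = a, abraham_b = b, abraham_s = s_pi,
    abraham_e = e, abraham_v = v,
    charge_class = grp, mw = mw, phi = phi,
    logs0_true = logs0_true,
    logs0_obs = logs0_true + noise
  )
}
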