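# Hall-Kier alpha contributions by element and hybridization, relative to
# sp3 carbon (alpha = 0). Values follow the standard covalent-radius table
# used by the common descriptor toolkits.
HALL_KIER_ALPHA <- list(
  C  = c(sp = -0.22, sp2 = -0.13, sp3 = 0.00),
  N  = c(sp = -0.29, sp2 = -0.20, sp3 = -0.04),
  O  = c(sp = NA,    sp2 = -0.20, sp3 = -0.04),
  S  = c(sp = NA,    sp2 = 0.22,  sp3 = 0.35),
  P  = c(sp = NA,    sp2 = 0.30,  sp3 = 0.43),
  F  = c(sp = -0.07, sp2 = -0.07, sp3 = -0.07),
  Cl = c(sp = 0.29,  sp2 = 0.29,  sp3 = 0.29),
  Br = c(sp = 0.48,  sp2 = 0.48,  sp3 = 0.48),
  I  = c(sp = 0.73,  sp2 = 0.73,  sp3 = 0.73)
)

#' Sum of Hall-Kier alpha corrections over the heavy atoms
#'
#' The alpha correction adjusts the kappa shape indices for atoms whose
#' covalent radius differs from that of sp3 carbon (the reference, alpha = 0).
#' @param g A `mol_graph`.
#' @return The scalar sum of per-atom alpha contributions.
#' @export
hall_kier_alpha <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  hyb <- atom_hybridization(g)
  total <- 0
  for (i in seq_len(nrow(g$atoms))) {
    tab <- HALL_KIER_ALPHA[[g$atoms$element[i]]]
    if (is.null(tab)) next
    a <- tab[[hyb[i]]]
    if (!is.na(a)) total <- total + a
  }
  total
}

#' Count simple paths of one or two bonds in a molecular graph
#'
#' Path counts feed the kappa shape indices: a one-bond path is an edge, a
#' two-bond path is an unordered pair of distinct atoms joined through a
#' common neighbour. Bond orders and aromaticity are ignored: the skeleton
#' is treated as a simple graph.
#'
#' @param g A `mol_graph`.
#' @param length Path length in bonds, 1 or 2.
#' @return Integer path count.
#' @examples
#' count_paths(parse_smiles("CCCCC"), 2)  # 3 interior triples of n-pentane
#' @export
count_paths <- function(g, length) {
  stopifnot(inherits(g, "mol_graph"))
  if (!length %in% c(1L, 2L)) {
    stop("`length` must be 1 or 2, got ", length, call. = FALSE)
  }
  if (length == 1L) return(nrow(g$bonds))
  deg <- atom_degree(g)
  as.integer(sum(deg * (deg - 1L) / 2L))
}

#' Kier kappa shape indices and the molecular flexibility index
#'
#' First- and second-order kappa indices of a hydrogen-suppressed graph with
#' `A` heavy atoms and path counts `P1` (bonds) and `P2` (two-bond paths):
#' \deqn{^1\kappa = A (A-1)^2 / P_1^2, \qquad ^2\kappa = (A-1)(A-2)^2 / P_2^2}
#' With `alpha_modified = TRUE`, `A` is replaced by `A + alpha` (and each path
#' count by `P + alpha`), the Hall-Kier correction for covalent radius and
#' hybridization. The flexibility index is
#' \eqn{\Phi = {}^1\kappa \cdot {}^2\kappa / A}.
#'
#' `kappa2` (and hence `phi`) is undefined for molecules with fewer than
#' three heavy atoms and is returned as `NA`.
#'
#' @param g A `mol_graph`.
#' @param alpha_modified Apply the Hall-Kier alpha correction (default `TRUE`,
#'   matching the common descriptor toolkits; the unmodified variant has the
#'   closed forms used in the tests, e.g. a path graph of `A` atoms has
#'   `phi = A - 1`).
#' @return A one-row tibble: `kappa1`, `kappa2`, `nha`, `phi`.
#' @examples
#' kappa_indices(parse_smiles("C1CCCCC1"), alpha_modified = FALSE)
#' @export
kappa_indices <- function(g, alpha_modified = TRUE) {
  stopifnot(inherits(g, "mol_graph"))
  A <- heavy_atom_count(g)
  if (A < 1L) stop("molecular graph has no atoms", call. = FALSE)
  alpha <- if (alpha_modified) hall_kier_alpha(g) else 0
  p1 <- count_paths(g, 1L)
  p2 <- count_paths(g, 2L)
  k1 <- if (p1 + alpha > 0) {
    (A + alpha) * (A + alpha - 1)^2 / (p1 + alpha)^2
  } else NA_real_
  k2 <- if (A >= 3L && p2 + alpha > 0) {
    (A + alpha - 1) * (A + alpha - 2)^2 / (p2 + alpha)^2
  } else NA_real_
  phi <- if (!is.na(k1) && !is.na(k2)) k1 * k2 / A else NA_real_
  tibble::tibble(kappa1 = k1, kappa2 = k2, nha = A, phi = phi)
}

#' Kier molecular flexibility index from SMILES
#'
#' Computes \eqn{\Phi = {}^1\kappa\,{}^2\kappa / N_{HA}} for each SMILES
#' string. \eqn{\Phi} grows with chain length (an unbranched chain of `A`
#' atoms has \eqn{\Phi = A - 1} in the unmodified variant) and shrinks with
#' rings and branching; drug-like molecules span roughly 0.4 to 43.
#'
#' @param smiles Character vector of SMILES strings.
#' @param alpha_modified Apply the Hall-Kier alpha correction (default
#'   `TRUE`).
#' @return Numeric vector of flexibility indices; `NA` for molecules with
#'   fewer than 3 heavy atoms (with a warning).
#' @examples
#' flexibility_index(c("CCCCC", "C1CCCCC1"), alpha_modified = FALSE)
#' @export
flexibility_index <- function(smiles, alpha_modified = TRUE) {
  out <- purrr::map_dbl(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_real_)
    kappa_indices(parse_smiles(s), alpha_modified = alpha_modified)$phi
  })
  if (any(!is.na(smiles) & nzchar(smiles) & is.na(out))) {
    warning("flexibility index undefined for molecules with < 3 heavy atoms; NA returned",
            call. = FALSE)
  }
  out
}
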