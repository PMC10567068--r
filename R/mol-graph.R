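#' @keywords internal
ATOMIC_WEIGHTS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.086, P = 30.974, S = 32.067, Cl = 35.453, Br = 79.904, I = 126.904
)

# standard lowest valences used to assign implicit hydrogens to
# organic-subset atoms (multiple entries = hypervalent states)
DEFAULT_VALENCES <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_SUBSET <- c("b", "c", "n", "o", "p", "s")

#' Parse a SMILES string into a hydrogen-suppressed molecular graph
#'
#' Converts a SMILES string (Daylight dialect: organic subset, bracket atoms
#' with charge and explicit H counts, branches, ring closures including
#' `%nn`, aromatic lower-case atoms, bond symbols `- = # :` and the
#' directional bonds `/ \\` read as single) into a simple undirected graph
#' over the heavy atoms. Implicit hydrogens are counted, not represented as
#' nodes. Stereo descriptors and isotope labels are accepted and ignored;
#' they do not affect any topological index.
#'
#' @param smiles A single SMILES string.
#' @param largest_fragment If `TRUE` (default) and the SMILES encodes several
#'   disconnected fragments (e.g. a salt written with `.`), only the fragment
#'   with the most heavy atoms is kept: intrinsic solubility refers to the
#'   neutral parent compound.
#' @return An object of class `mol_graph`: a list with `atoms` (tibble:
#'   `element`, `aromatic`, `charge`, `n_h` implicit+explicit hydrogens) and
#'   `bonds` (tibble: `from`, `to`, `order`; aromatic bonds carry order 1.5).
#' @examples
#' g <- parse_smiles("CCO")
#' heavy_atom_count(g)
#' @export
parse_smiles <- function(smiles, largest_fragment = TRUE) {
  if (length(smiles) != 1L || is.na(smiles) || !nzchar(smiles)) {
    stop("`smiles` must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)

  element <- character()
  aromatic <- logical()
  charge <- integer()
  explicit_h <- integer()   # NA = assign by valence model
  bond_from <- integer(); bond_to <- integer(); bond_order <- numeric()

  prev <- NA_integer_
  pending <- NA_real_          # bond order queued before next atom/ring digit
  branch_stack <- integer()
  ring_open <- list()          # digit label -> list(atom, order)

  add_atom <- function(el, arom, chg, eh) {
    element[length(element) + 1L] <<- el
    aromatic[length(aromatic) + 1L] <<- arom
    charge[length(charge) + 1L] <<- chg
    explicit_h[length(explicit_h) + 1L] <<- eh
    idx <- length(element)
    if (!is.na(prev)) {
      ord <- pending
      if (is.na(ord)) ord <- if (arom && aromatic[prev]) 1.5 else 1
      bond_from[length(bond_from) + 1L] <<- prev
      bond_to[length(bond_to) + 1L] <<- idx
      bond_order[length(bond_order) + 1L] <<- ord
    }
    prev <<- idx
    pending <<- NA_real_
    idx
  }

  close_ring <- function(label) {
    if (is.na(prev)) stop("ring bond digit before any atom in '", smiles, "'", call. = FALSE)
    if (!is.null(ring_open[[label]])) {
      op <- ring_open[[label]]
      ord <- pending
      if (is.na(ord)) ord <- op$order
      if (is.na(ord)) ord <- if (aromatic[prev] && aromatic[op$atom]) 1.5 else 1
      bond_from[length(bond_from) + 1L] <<- op$atom
      bond_to[length(bond_to) + 1L] <<- prev
      bond_order[length(bond_order) + 1L] <<- ord
      ring_open[[label]] <<- NULL
    } else {
      ring_open[[label]] <<- list(atom = prev, order = pending)
    }
    pending <<- NA_real_
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket atom in '", smiles, "'", call. = FALSE)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^(\\d+)?([A-Za-z][a-z]?|\\*)(@{1,2}|@TH\\d|@AL\\d|@SP\\d)?(H\\d*)?([+-]+\\d*)?(:\\d+)?$",
        body))[[1]]
      if (length(m) == 0L) stop("cannot parse bracket atom [", body, "] in '", smiles, "'", call. = FALSE)
      sym <- m[3]
      arom <- sym %in% AROMATIC_SUBSET || sym %in% c("se", "as")
      el <- if (arom) {
        paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, nchar(sym)))
      } else sym
      hpart <- m[5]
      eh <- if (!nzchar(hpart)) 0L else if (hpart == "H") 1L else as.integer(sub("^H", "", hpart))
      cpart <- m[6]
      chg <- 0L
      if (nzchar(cpart)) {
        sign <- if (substr(cpart, 1, 1) == "+") 1L else -1L
        digits <- sub("^[+-]+", "", cpart)
        chg <- if (nzchar(digits)) sign * as.integer(digits) else sign * nchar(cpart)
      }
      add_atom(el, arom, chg, eh)
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1] %in% c("l", "r") &&
               paste0(ch, chars[i + 1]) %in% c("Cl", "Br")) {
      add_atom(paste0(ch, chars[i + 1]), FALSE, 0L, NA_integer_)
      i <- i + 2L
    } else if (ch %in% ORGANIC_SUBSET) {
      add_atom(ch, FALSE, 0L, NA_integer_)
      i <- i + 1L
    } else if (ch %in% AROMATIC_SUBSET) {
      add_atom(toupper(ch), TRUE, 0L, NA_integer_)
      i <- i + 1L
    } else if (ch == "-") { pending <- 1; i <- i + 1L
    } else if (ch == "=") { pending <- 2; i <- i + 1L
    } else if (ch == "#") { pending <- 3; i <- i + 1L
    } else if (ch == ":") { pending <- 1.5; i <- i + 1L
    } else if (ch %in% c("/", "\\")) { pending <- 1; i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) stop("branch opened before any atom in '", smiles, "'", call. = FALSE)
      branch_stack <- c(branch_stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(branch_stack) == 0L) stop("unbalanced ')' in '", smiles, "'", call. = FALSE)
      prev <- branch_stack[length(branch_stack)]
      branch_stack <- branch_stack[-length(branch_stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("truncated %nn ring label in '", smiles, "'", call. = FALSE)
      close_ring(paste0(chars[i + 1], chars[i + 2])); i <- i + 3L
    } else if (ch == ".") {
      prev <- NA_integer_; pending <- NA_real_; i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' in SMILES '", smiles, "'", call. = FALSE)
    }
  }
  if (length(branch_stack) > 0L) stop("unbalanced '(' in '", smiles, "'", call. = FALSE)
  if (length(ring_open) > 0L) stop("unclosed ring bond in '", smiles, "'", call. = FALSE)
  if (length(element) == 0L) stop("no atoms in SMILES '", smiles, "'", call. = FALSE)

  g <- new_mol_graph(element, aromatic, charge, explicit_h,
                     bond_from, bond_to, bond_order)
  if (largest_fragment) g <- keep_largest_fragment(g)
  g
}

new_mol_graph <- function(element, aromatic, charge, explicit_h,
                          from, to, order) {
  if (length(from) > 0L) {
    lo <- pmin(from, to); hi <- pmax(from, to)
    if (any(lo == hi)) stop("self-loop bond in molecular graph", call. = FALSE)
    key <- paste(lo, hi)
    if (anyDuplicated(key)) {
      keep <- !duplicated(key)
      lo <- lo[keep]; hi <- hi[keep]; order <- order[keep]
    }
    bonds <- tibble::tibble(from = lo, to = hi, order = order)
  } else {
    bonds <- tibble::tibble(from = integer(), to = integer(), order = numeric())
  }
  atoms <- tibble::tibble(element = element, aromatic = aromatic, charge = charge)
  atoms$n_h <- assign_hydrogens(atoms, bonds, explicit_h)
  structure(list(atoms = atoms, bonds = bonds), class = "mol_graph")
}

# Implicit hydrogen count by the standard SMILES valence model; bracket atoms
# carry an explicit count that is taken as-is. Aromatic C/N/B contribute one
# pi bond on top of their sigma degree; aromatic O/S donate a lone pair and
# get no increment. Aromatic atoms never promote to a hypervalent state.
assign_hydrogens <- function(atoms, bonds, explicit_h) {
  n <- nrow(atoms)
  bsum <- numeric(n)
  if (nrow(bonds) > 0L) {
    for (k in seq_len(nrow(bonds))) {
      o <- if (bonds$order[k] == 1.5) 1 else bonds$order[k]
      bsum[bonds$from[k]] <- bsum[bonds$from[k]] + o
      bsum[bonds$to[k]] <- bsum[bonds$to[k]] + o
    }
  }
  pi_arom <- atoms$aromatic & atoms$element %in% c("B", "C", "N", "P")
  bsum[pi_arom] <- bsum[pi_arom] + 1
  out <- integer(n)
  for (i in seq_len(n)) {
    if (!is.na(explicit_h[i])) { out[i] <- explicit_h[i]; next }
    vals <- DEFAULT_VALENCES[[atoms$element[i]]]
    if (is.null(vals)) { out[i] <- 0L; next }
    if (atoms$aromatic[i]) { out[i] <- max(0L, as.integer(vals[1] - bsum[i])); next }
    ok <- vals[vals >= bsum[i]]
    out[i] <- if (length(ok) == 0L) 0L else as.integer(ok[1] - bsum[i])
  }
  out
}

keep_largest_fragment <- function(g) {
  n <- nrow(g$atoms)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  if (nrow(g$bonds) > 0L) {
    for (k in seq_len(nrow(g$bonds))) {
      a <- find(g$bonds$from[k]); b <- find(g$bonds$to[k])
      if (a != b) comp[a] <- b
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  if (length(unique(root)) == 1L) return(g)
  best <- names(which.max(table(root)))
  keep <- which(root == as.integer(best))
  remap <- match(seq_len(n), keep)
  bonds <- g$bonds[g$bonds$from %in% keep & g$bonds$to %in% keep, , drop = FALSE]
  bonds$from <- remap[bonds$from]; bonds$to <- remap[bonds$to]
  structure(list(atoms = g$atoms[keep, , drop = FALSE], bonds = bonds),
            class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", nrow(x$atoms), " heavy atoms, ", nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

#' Heavy-atom count of a molecular graph
#' @param g A `mol_graph` from [parse_smiles()].
#' @return Integer number of non-hydrogen atoms.
#' @export
heavy_atom_count <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  nrow(g$atoms)
}

#' Molecular weight (Da) including implicit hydrogens
#' @inheritParams heavy_atom_count
#' @return Molecular weight in daltons (standard atomic weights).
#' @export
molecular_weight <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  w <- ATOMIC_WEIGHTS[g$atoms$element]
  if (anyNA(w)) {
    stop("no atomic weight for element(s): ",
         paste(unique(g$atoms$element[is.na(w)]), collapse = ", "), call. = FALSE)
  }
  sum(w) + sum(g$atoms$n_h) * ATOMIC_WEIGHTS[["H"]]
}

# per-atom sigma degree over heavy neighbours
atom_degree <- function(g) {
  n <- nrow(g$atoms)
  deg <- integer(n)
  if (nrow(g$bonds) > 0L) {
    t1 <- tabulate(g$bonds$from, n); t2 <- tabulate(g$bonds$to, n)
    deg <- t1 + t2
  }
  deg
}

# Hybridization perception mirroring the reference descriptor toolkit:
# aromatic -> sp2; C/N with a triple bond or cumulated doubles -> sp;
# any double bond -> sp2; singly-bonded N/O conjugated into an aromatic
# ring or onto a double-bonded C/N (aniline, phenol, ester, amide) -> sp2;
# hypervalent S/P (sulfoxide, sulfone, phosphate) remain sp3.
atom_hybridization <- function(g) {
  n <- nrow(g$atoms)
  el <- g$atoms$element
  arom <- g$atoms$aromatic
  deg <- atom_degree(g)
  n_double <- integer(n); n_triple <- integer(n)
  nbrs <- vector("list", n)
  if (nrow(g$bonds) > 0L) {
    for (k in seq_len(nrow(g$bonds))) {
      f <- g$bonds$from[k]; t <- g$bonds$to[k]; o <- g$bonds$order[k]
      nbrs[[f]] <- c(nbrs[[f]], t); nbrs[[t]] <- c(nbrs[[t]], f)
      if (o == 2) { n_double[f] <- n_double[f] + 1L; n_double[t] <- n_double[t] + 1L }
      if (o == 3) { n_triple[f] <- n_triple[f] + 1L; n_triple[t] <- n_triple[t] + 1L }
    }
  }
  out <- character(n)
  for (i in seq_len(n)) {
    e <- el[i]
    if (arom[i]) { out[i] <- "sp2"; next }
    if (e %in% c("C", "N")) {
      if (n_triple[i] > 0L || n_double[i] >= 2L) { out[i] <- "sp"; next }
      if (n_double[i] == 1L) { out[i] <- "sp2"; next }
      if (e == "N") {
        conj <- any(vapply(nbrs[[i]], function(j) {
          arom[j] || (el[j] %in% c("C", "N") && n_double[j] > 0L)
        }, logical(1)))
        out[i] <- if (isTRUE(conj)) "sp2" else "sp3"
      } else out[i] <- "sp3"
    } else if (e == "O") {
      if (n_double[i] > 0L) { out[i] <- "sp2"; next }
      conj <- any(vapply(nbrs[[i]], function(j) {
        arom[j] || (el[j] %in% c("C", "N") && n_double[j] > 0L)
      }, logical(1)))
      out[i] <- if (isTRUE(conj)) "sp2" else "sp3"
    } else if (e %in% c("S", "P")) {
      out[i] <- if (deg[i] == 1L && n_double[i] > 0L) "sp2" else "sp3"
    } else {
      out[i] <- "sp3"
    }
  }
  out
}
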