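# Brute-force and generator helpers shared across the test files.

# count 2-edge simple paths by enumerating all middle atoms and neighbour pairs
brute_force_paths2 <- function(adj) {
  n <- nrow(adj)
  total <- 0L
  for (j in seq_len(n)) {
    nb <- which(adj[j, ] == 1L)
    if (length(nb) >= 2L) total <- total + choose(length(nb), 2L)
  }
  as.integer(total)
}

# random connected simple graph: a random spanning tree plus extra edges
random_graph <- function(n, extra = 0L) {
  adj <- matrix(0L, n, n)
  for (i in 2:n) {
    j <- sample.int(i - 1L, 1L)
    adj[i, j] <- adj[j, i] <- 1L
  }
  free <- which(upper.tri(adj) & adj == 0L)
  if (extra > 0L && length(free) > 0L) {
    pick <- sample(free, min(extra, length(free)))
    adj[pick] <- 1L
    adj <- pmax(adj, t(adj))
  }
  adj
}

# mol_graph from an adjacency matrix of carbon atoms (test-only constructor)
graph_from_adjacency <- function(adj, element = "C") {
  n <- nrow(adj)
  smiles_bonds <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
  soluphi:::new_mol_graph(
    element = rep(element, n), aromatic = rep(FALSE, n),
    charge = rep(0L, n), explicit_h = rep(NA_integer_, n),
    from = smiles_bonds[, 1], to = smiles_bonds[, 2],
    order = rep(1, nrow(smiles_bonds)))
}

# random chemical tree (degree-capped) and two SMILES spellings of it
random_tree_smiles <- function(n_atoms, elements = c("C", "C", "C", "N", "O")) {
  caps <- c(C = 4L, N = 3L, O = 2L)
  repeat {
    el <- sample(elements, n_atoms, replace = TRUE)
    parent <- rep(NA_integer_, n_atoms)
    deg <- rep(0L, n_atoms)
    ok <- TRUE
    for (i in 2:n_atoms) {
      open <- seq_len(i - 1L)
      open <- open[deg[open] < caps[el[open]]]
      if (length(open) == 0L) { ok <- FALSE; break }
      p <- if (length(open) == 1L) open else sample(open, 1L)
      parent[i] <- p
      deg[i] <- deg[i] + 1L; deg[p] <- deg[p] + 1L
    }
    if (ok) break
  }
  children <- vector("list", n_atoms)
  for (i in 2:n_atoms) children[[parent[i]]] <- c(children[[parent[i]]], i)
  adj <- vector("list", n_atoms)
  for (i in 2:n_atoms) {
    adj[[i]] <- c(adj[[i]], parent[i])
    adj[[parent[i]]] <- c(adj[[parent[i]]], i)
  }
  write_from <- function(root) {
    seen <- rep(FALSE, n_atoms)
    rec <- function(i) {
      seen[i] <<- TRUE
      kids <- adj[[i]][!seen[adj[[i]]]]
      out <- el[i]
      for (k in kids) out <- paste0(out, "(", rec(k), ")")
      out
    }
    rec(root)
  }
  roots <- sample.int(n_atoms, 2L)
  c(write_from(roots[1]), write_from(roots[2]))
}

# table 5 of the outlier study: printed predictions used across test files
outlier_table <- function() {
  tibble::tribble(
    ~drug, ~phi, ~obs, ~cons_prev, ~cons_this, ~xor, ~gse_phib, ~absolv, ~gse, ~closest_residual,
    "folic_acid",     6.6,  -5.91, -3.88, -2.51, -4.07, -2.97, -2.05, -1.71, -1.84,
    "cisapride",      8.6,  -6.78, -4.21, -4.16, -2.97, -4.24, -4.07, -3.71, -2.54,
    "amiodarone",     9.2, -10.40, -7.86, -7.21, -4.38, -6.48, -7.93, -7.75, -2.47,
    "itraconazole",   9.6,  -8.71, -7.27, -7.12, -7.93, -5.69, -8.54, -6.48, -0.17,
    "rifabutin",     13.1,  -3.99, -6.81, -5.05, -8.54, -5.21, -4.89, -5.63,  0.90,
    "cyclosporine_a", 31.5, -5.03, -8.27, -4.49, -5.21, -4.38, -4.59, -4.03, -0.44
  )
}
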