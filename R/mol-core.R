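# Internal molecular-graph model.
#
# A molecule ("sq_mol") is a light list of parallel atom vectors plus a bond
# table. Aromaticity is a per-atom and per-bond flag fixed at parse time (one
# perception model for the whole run); hydrogens are implicit counts, never
# graph atoms.

ELEMENT_NUMBERS <- c(
  H = 1L, He = 2L, Li = 3L, Be = 4L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L,
  Na = 11L, Mg = 12L, Al = 13L, Si = 14L, P = 15L, S = 16L, Cl = 17L,
  K = 19L, Ca = 20L, Mn = 25L, Fe = 26L, Co = 27L, Ni = 28L, Cu = 29L,
  Zn = 30L, As = 33L, Se = 34L, Br = 35L, Ag = 47L, I = 53L, Pt = 78L,
  Au = 79L, Hg = 80L
)

# Default valences used for the implicit-hydrogen model. Multi-valent N/P/S
# take the smallest listed valence that accommodates the explicit bonds.
DEFAULT_VALENCES <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  F = 1L, Cl = 1L, Br = 1L, I = 1L
)

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

ELEMENT_WHITELIST <- c("H", "C", "N", "O", "F", "Br", "I", "Cl", "P", "S")

new_mol <- function(elem = character(), arom = logical(), charge = integer(),
                    hcount = integer(), hexp = logical(), stereo = character(),
                    iso = integer(), bonds = empty_bonds()) {
  structure(
    list(elem = elem, arom = arom, charge = charge, hcount = hcount,
         hexp = hexp, stereo = stereo, iso = iso, bonds = bonds),
    class = "sq_mol"
  )
}

empty_bonds <- function() {
  data.frame(i = integer(), j = integer(), order = integer(),
             arom = logical(), stereo = character(), stringsAsFactors = FALSE)
}

is_mol <- function(x) inherits(x, "sq_mol")

n_atoms <- function(mol) length(mol$elem)

n_bonds <- function(mol) nrow(mol$bonds)

#' @exportS3Method base::print
#' @noRd
print.sq_mol <- function(x, ...) {
  cat("<sq_mol> ", n_atoms(x), " atoms, ", n_bonds(x), " bonds: ",
      write_smiles(x), "\n", sep = "")
  invisible(x)
}

# Adjacency as a list of integer neighbour vectors.
mol_adjacency <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (k in seq_len(n)) adj[[k]] <- integer()
  if (n_bonds(mol)) {
    for (b in seq_len(n_bonds(mol))) {
      i <- mol$bonds$i[b]; j <- mol$bonds$j[b]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

# n x n matrix of bond row indices (0 where no bond).
mol_bond_lookup <- function(mol) {
  n <- n_atoms(mol)
  m <- matrix(0L, n, n)
  if (n_bonds(mol)) {
    idx <- seq_len(n_bonds(mol))
    m[cbind(mol$bonds$i, mol$bonds$j)] <- idx
    m[cbind(mol$bonds$j, mol$bonds$i)] <- idx
  }
  m
}

# Connected components as a list of atom-index vectors, in order of first atom.
mol_components <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0L) return(list())
  adj <- mol_adjacency(mol)
  seen <- logical(n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    stack <- s; comp <- integer()
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (seen[v]) next
      seen[v] <- TRUE
      comp <- c(comp, v)
      stack <- c(stack, adj[[v]][!seen[adj[[v]]]])
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# Logical vector over bonds: TRUE when the bond lies on a cycle (i.e. is not a
# bridge). Tarjan bridge-finding via iterative DFS.
mol_ring_bonds <- function(mol) {
  n <- n_atoms(mol)
  nb <- n_bonds(mol)
  if (nb == 0L) return(logical(0))
  adj_b <- vector("list", n)            # incident bond ids per atom
  for (k in seq_len(n)) adj_b[[k]] <- integer()
  for (b in seq_len(nb)) {
    i <- mol$bonds$i[b]; j <- mol$bonds$j[b]
    adj_b[[i]] <- c(adj_b[[i]], b)
    adj_b[[j]] <- c(adj_b[[j]], b)
  }
  other_end <- function(b, v) if (mol$bonds$i[b] == v) mol$bonds$j[b] else mol$bonds$i[b]

  disc <- integer(n); low <- integer(n); timer <- 0L
  is_bridge <- logical(nb)
  visited <- logical(n)

  for (root in seq_len(n)) {
    if (visited[root]) next
    # iterative DFS with explicit frames: (vertex, incoming bond, next nb idx)
    stack_v <- root; stack_pb <- 0L; stack_i <- 1L
    visited[root] <- TRUE; timer <- timer + 1L
    disc[root] <- low[root] <- timer
    while (length(stack_v)) {
      top <- length(stack_v)
      v <- stack_v[top]; pb <- stack_pb[top]; idx <- stack_i[top]
      nbrs <- adj_b[[v]]
      if (idx <= length(nbrs)) {
        stack_i[top] <- idx + 1L
        b <- nbrs[idx]
        if (b == pb) next
        w <- other_end(b, v)
        if (!visited[w]) {
          visited[w] <- TRUE; timer <- timer + 1L
          disc[w] <- low[w] <- timer
          stack_v <- c(stack_v, w); stack_pb <- c(stack_pb, b); stack_i <- c(stack_i, 1L)
        } else {
          low[v] <- min(low[v], disc[w])
        }
      } else {
        # retire frame
        stack_v <- stack_v[-top]; stack_pb <- stack_pb[-top]; stack_i <- stack_i[-top]
        if (pb != 0L) {
          u <- other_end(pb, v)
          low[u] <- min(low[u], low[v])
          if (low[v] > disc[u]) is_bridge[pb] <- TRUE
        }
      }
    }
  }
  !is_bridge
}

mol_ring_atoms <- function(mol) {
  rb <- mol_ring_bonds(mol)
  sort(unique(c(mol$bonds$i[rb], mol$bonds$j[rb])))
}

# Cyclomatic number (= SSSR ring count for a simple molecular graph).
mol_ring_count <- function(mol) {
  comps <- length(mol_components(mol))
  n_bonds(mol) - n_atoms(mol) + comps
}

# Sum of bond orders at each atom; aromatic bonds count 1.
mol_bond_sums <- function(mol) {
  n <- n_atoms(mol)
  bs <- numeric(n)
  if (n_bonds(mol)) {
    ord <- ifelse(mol$bonds$arom, 1, mol$bonds$order)
    for (b in seq_len(n_bonds(mol))) {
      bs[mol$bonds$i[b]] <- bs[mol$bonds$i[b]] + ord[b]
      bs[mol$bonds$j[b]] <- bs[mol$bonds$j[b]] + ord[b]
    }
  }
  bs
}

# Implicit hydrogen count for one atom under the package's valence model.
# Aromatic atoms use their lowest default valence and donate one bond to the
# delocalized system.
implicit_hydrogens <- function(elem, arom, bondsum, charge = 0L) {
  vals <- DEFAULT_VALENCES[[elem]]
  if (is.null(vals) || charge != 0L) return(0L)
  if (arom) return(max(0L, as.integer(vals[1] - bondsum - 1)))
  v <- vals[vals >= bondsum]
  if (!length(v)) return(0L)
  as.integer(v[1] - bondsum)
}

# Fill hcount for atoms whose H count was not written explicitly.
resolve_hydrogens <- function(mol) {
  bs <- mol_bond_sums(mol)
  for (k in seq_len(n_atoms(mol))) {
    if (!mol$hexp[k]) {
      if (mol$elem[k] %in% ORGANIC_SUBSET && mol$charge[k] == 0L) {
        mol$hcount[k] <- implicit_hydrogens(mol$elem[k], mol$arom[k], bs[k])
      } else {
        mol$hcount[k] <- 0L
      }
    }
  }
  mol
}

# Extract the subgraph on `atoms` (bond kept iff both ends kept), re-indexed,
# hydrogens re-derived as implicit.
mol_subgraph <- function(mol, atoms) {
  atoms <- sort(unique(atoms))
  map <- integer(n_atoms(mol)); map[atoms] <- seq_along(atoms)
  keep_b <- mol$bonds$i %in% atoms & mol$bonds$j %in% atoms
  bonds <- mol$bonds[keep_b, , drop = FALSE]
  bonds$i <- map[bonds$i]; bonds$j <- map[bonds$j]
  rownames(bonds) <- NULL
  out <- new_mol(
    elem = mol$elem[atoms], arom = mol$arom[atoms],
    charge = mol$charge[atoms], hcount = 0L * seq_along(atoms),
    hexp = rep(FALSE, length(atoms)), stereo = rep("", length(atoms)),
    iso = mol$iso[atoms], bonds = bonds
  )
  # atoms that lost an aromatic environment keep their flag only if they still
  # carry an aromatic bond
  if (length(out$arom)) {
    has_arom_bond <- rep(FALSE, n_atoms(out))
    if (n_bonds(out)) {
      ab <- out$bonds$arom
      has_arom_bond[unique(c(out$bonds$i[ab], out$bonds$j[ab]))] <- TRUE
    }
    out$arom <- out$arom & has_arom_bond
  }
  resolve_hydrogens(out)
}

mol_heavy_atoms <- function(mol) sum(mol$elem != "H")

# Rough molecular weight (monoisotopic-ish averages; used only for salt-strip
# tie-breaking).
ATOMIC_WEIGHTS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, P = 30.974, S = 32.06, Cl = 35.45, K = 39.098,
  Ca = 40.078, Zn = 65.38, Se = 78.971, Br = 79.904, I = 126.904,
  Li = 6.94, Fe = 55.845, Cu = 63.546, Mn = 54.938, Al = 26.982,
  Si = 28.085, As = 74.922, Ag = 107.868, Pt = 195.084, Au = 196.967,
  Hg = 200.592, He = 4.0026, Be = 9.0122, Co = 58.933, Ni = 58.693
)

mol_weight <- function(mol) {
  w <- ATOMIC_WEIGHTS[mol$elem]
  w[is.na(w)] <- 0
  sum(w) + sum(mol$hcount) * ATOMIC_WEIGHTS[["H"]]
}
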