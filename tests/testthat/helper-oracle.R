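# Independent brute-force oracles for substructure matching and MCS size.
# Deliberately naive: pattern atoms are placed in plain index order against
# every molecule atom (no frontier ordering, no adjacency-driven candidate
# generation), and the MCS oracle enumerates edge subsets of the smaller
# graph outright. Kept separate from the package's search code.

orc_mol <- function(smiles) scaffquery:::mol_from_smiles(smiles)

orc_graph <- function(mol) {
  list(num = scaffquery:::mol_atomic_numbers(mol),
       types = scaffquery:::mol_bond_types(mol),
       bonds = mol$bonds,
       lookup = scaffquery:::mol_bond_lookup(mol))
}

# pattern: list(atomic_num, bonds data.frame(i, j) with list-col allowed)
oracle_match <- function(pat, mol) {
  g <- orc_graph(if (is.character(mol)) orc_mol(mol) else mol)
  np <- length(pat$atomic_num)
  nm <- length(g$num)
  if (np > nm) return(FALSE)
  nb <- nrow(pat$bonds)
  try_place <- function(map) {
    k <- length(map) + 1L
    if (k > np) return(TRUE)
    for (v in seq_len(nm)) {
      if (v %in% map) next
      if (g$num[v] != pat$atomic_num[k]) next
      ok <- TRUE
      if (nb) for (b in seq_len(nb)) {
        i <- pat$bonds$i[b]; j <- pat$bonds$j[b]
        if (max(i, j) != k || min(i, j) >= k) next
        other <- map[min(i, j)]
        mb <- g$lookup[other, v]
        if (mb == 0L || !(g$types[mb] %in% pat$bonds$allowed[[b]])) {
          ok <- FALSE; break
        }
      }
      if (ok && try_place(c(map, v))) return(TRUE)
    }
    FALSE
  }
  try_place(integer())
}

oracle_match_smarts <- function(smarts, smiles) {
  oracle_match(parse_smarts(smarts), smiles)
}

# Exhaustive MCS size: every edge subset of the smaller graph that forms a
# connected subgraph is tested for embedding into the other graph.
oracle_mcs_size <- function(sa, sb) {
  a <- orc_mol(sa); b <- orc_mol(sb)
  if (scaffquery:::n_atoms(a) > scaffquery:::n_atoms(b)) { tmp <- a; a <- b; b <- tmp }
  ga <- orc_graph(a)
  na <- length(ga$num)
  nb <- nrow(ga$bonds)
  best <- 0L
  # single atoms first
  for (v in seq_len(na)) {
    if (any(orc_graph(b)$num == ga$num[v])) { best <- max(best, 1L); break }
  }
  if (nb) {
    subsets <- lapply(0:(2^nb - 1L), function(mask) which(bitwAnd(mask, 2^(seq_len(nb) - 1L)) > 0))
    sizes <- vapply(subsets, function(es) {
      if (!length(es)) return(0L)
      length(unique(c(ga$bonds$i[es], ga$bonds$j[es])))
    }, integer(1))
    ord <- order(-sizes)
    for (si in ord) {
      es <- subsets[[si]]
      natoms <- sizes[si]
      if (natoms <= best || !length(es)) next
      atoms <- sort(unique(c(ga$bonds$i[es], ga$bonds$j[es])))
      # connectivity of the edge subset
      comp <- atoms[1]; grew <- TRUE
      while (grew) {
        grew <- FALSE
        for (e in es) {
          i <- ga$bonds$i[e]; j <- ga$bonds$j[e]
          if (i %in% comp && !(j %in% comp)) { comp <- c(comp, j); grew <- TRUE }
          if (j %in% comp && !(i %in% comp)) { comp <- c(comp, i); grew <- TRUE }
        }
      }
      if (length(comp) != natoms) next
      idx <- match(atoms, atoms)
      remap <- integer(max(atoms)); remap[atoms] <- seq_along(atoms)
      pat <- list(
        atomic_num = ga$num[atoms],
        bonds = {
          bd <- data.frame(i = remap[ga$bonds$i[es]], j = remap[ga$bonds$j[es]])
          bd$allowed <- lapply(ga$types[es], identity)
          bd
        })
      if (oracle_match(pat, b)) best <- max(best, natoms)
    }
  }
  best
}
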