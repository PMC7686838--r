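# Maximum common connected substructure of two molecular graphs.
#
# Matching semantics (fixed for the whole pipeline): atoms match on element;
# bonds match when both are aromatic or both are non-aromatic of equal order.
# The common substructure is connected and need not be ring-complete; its size
# is counted in heavy atoms. Search is branch-and-bound over growing atom
# mappings; a per-pair time budget turns exhaustive search into best-found
# with an `approximate` flag (large inputs only).

mcs_graphs <- function(a, b, timeout = 5) {
  na <- n_atoms(a); nb_ <- n_atoms(b)
  if (na == 0L || nb_ == 0L) {
    return(list(size = 0L, atoms_a = integer(), atoms_b = integer(),
                bonds_a = integer(), approximate = FALSE))
  }
  num_a <- mol_atomic_numbers(a); num_b <- mol_atomic_numbers(b)
  type_a <- mol_bond_types(a); type_b <- mol_bond_types(b)
  adj_a <- mol_adjacency(a); adj_b <- mol_adjacency(b)
  look_a <- mol_bond_lookup(a); look_b <- mol_bond_lookup(b)

  best <- list(size = 0L, map_a = integer(), map_b = integer())
  t0 <- proc.time()[["elapsed"]]
  timed_out <- FALSE

  # Grow a mapping whose minimum a-atom is `seed`; only a-atoms >= seed may
  # join, and atoms in `excl` are barred for the whole branch. At each node,
  # one frontier atom u is either mapped to every compatible b-atom or
  # excluded - a complete, permutation-free decomposition.
  search <- function(map_a, map_b, seed, excl) {
    if (timed_out) return(invisible())
    if (proc.time()[["elapsed"]] - t0 > timeout) { timed_out <<- TRUE; return(invisible()) }
    size <- length(map_a)
    if (size > best$size) best <<- list(size = size, map_a = map_a, map_b = map_b)
    eligible <- setdiff(which(seq_len(na) >= seed), c(map_a, excl))
    if (size + min(length(eligible), nb_ - size) <= best$size) return(invisible())

    frontier <- setdiff(unique(unlist(adj_a[map_a])), c(map_a, excl))
    frontier <- frontier[frontier >= seed]
    if (!length(frontier)) return(invisible())
    u <- frontier[1L]
    for (v in setdiff(seq_len(nb_), map_b)) {
      if (num_b[v] != num_a[u]) next
      ok_edge <- FALSE
      for (k in seq_along(map_a)) {
        ba <- look_a[map_a[k], u]
        if (ba == 0L) next
        bb <- look_b[map_b[k], v]
        if (bb != 0L && type_a[ba] == type_b[bb]) { ok_edge <- TRUE; break }
      }
      if (!ok_edge) next
      search(c(map_a, u), c(map_b, v), seed, excl)
      if (timed_out) return(invisible())
    }
    search(map_a, map_b, seed, c(excl, u))
    invisible()
  }

  for (seed in seq_len(na)) {
    if (na - seed + 1L <= best$size) break
    for (v in seq_len(nb_)) {
      if (num_b[v] != num_a[seed]) next
      search(seed, v, seed, integer())
      if (timed_out) break
    }
    if (timed_out) break
  }

  if (best$size == 0L) {
    return(list(size = 0L, atoms_a = integer(), atoms_b = integer(),
                bonds_a = integer(), approximate = timed_out))
  }
  # pattern bonds: a-bonds within the mapped set whose image is compatible
  bonds_a <- integer()
  pos <- integer(na); pos[best$map_a] <- seq_along(best$map_a)
  for (bidx in seq_len(n_bonds(a))) {
    i <- a$bonds$i[bidx]; j <- a$bonds$j[bidx]
    if (pos[i] == 0L || pos[j] == 0L) next
    bb <- look_b[best$map_b[pos[i]], best$map_b[pos[j]]]
    if (bb != 0L && type_a[bidx] == type_b[bb]) bonds_a <- c(bonds_a, bidx)
  }
  list(size = best$size, atoms_a = best$map_a, atoms_b = best$map_b,
       bonds_a = bonds_a, approximate = timed_out)
}

# Build the common-substructure pattern (sq_pattern) from an mcs_graphs()
# result on molecule `a`.
mcs_pattern <- function(a, res) {
  atoms <- sort(res$atoms_a)
  if (!length(atoms)) return(NULL)
  idx <- integer(n_atoms(a)); idx[atoms] <- seq_along(atoms)
  types <- mol_bond_types(a)
  bi <- idx[a$bonds$i[res$bonds_a]]
  bj <- idx[a$bonds$j[res$bonds_a]]
  pat <- structure(
    list(atomic_num = mol_atomic_numbers(a)[atoms],
         arom = a$arom[atoms],
         bonds = data.frame(i = bi, j = bj)),
    class = "sq_pattern"
  )
  pat$bonds$allowed <- lapply(types[res$bonds_a], identity)
  pat
}

# A pattern reinterpreted as a plain graph so it can seed the next MCS fold.
pattern_to_mol <- function(pat) {
  nb <- nrow(pat$bonds)
  order <- integer(nb); arom <- logical(nb)
  for (k in seq_len(nb)) {
    al <- pat$bonds$allowed[[k]]
    t1 <- al[[1]]
    arom[k] <- t1 == "arom"
    order[k] <- switch(t1, single = 1L, arom = 1L, double = 2L, triple = 3L)
  }
  sym <- names(ELEMENT_NUMBERS)[match(pat$atomic_num, ELEMENT_NUMBERS)]
  m <- new_mol(
    elem = sym, arom = if (length(pat$arom)) ifelse(is.na(pat$arom), arom_from_bonds(pat, arom), pat$arom) else logical(),
    charge = integer(length(sym)), hcount = integer(length(sym)),
    hexp = rep(TRUE, length(sym)), stereo = rep("", length(sym)),
    iso = rep(NA_integer_, length(sym)),
    bonds = data.frame(i = pat$bonds$i, j = pat$bonds$j, order = order,
                       arom = arom, stereo = rep("", nb),
                       stringsAsFactors = FALSE)
  )
  m
}

arom_from_bonds <- function(pat, bond_arom) {
  n <- length(pat$atomic_num)
  fl <- logical(n)
  if (nrow(pat$bonds)) {
    ab <- bond_arom
    fl[unique(c(pat$bonds$i[ab], pat$bonds$j[ab]))] <- TRUE
  }
  fl
}

#' Maximum common substructure of two scaffolds
#'
#' Computes the largest connected substructure shared by two structures under
#' element and bond-aromaticity matching, returning its heavy-atom count and a
#' SMARTS pattern that matches both inputs.
#'
#' @param a,b SMILES strings or internal molecule objects.
#' @param timeout Per-pair search budget in seconds; on expiry the best
#'   pattern found so far is returned with `approximate = TRUE`.
#' @return A list with `size`, `smarts`, and `approximate`.
#' @export
mcs_common_atoms <- function(a, b, timeout = 5) {
  if (is.character(a)) a <- mol_from_smiles(a)
  if (is.character(b)) b <- mol_from_smiles(b)
  res <- mcs_graphs(a, b, timeout = timeout)
  pat <- mcs_pattern(a, res)
  list(size = res$size,
       smarts = if (is.null(pat)) NA_character_ else render_smarts(pat),
       approximate = res$approximate)
}

#' Scaffold distance from MCS size
#'
#' `d = 1 - m / (|a| + |b| - m)` (Tanimoto on atom counts) by default, or
#' `d = 1 - m / max(|a|, |b|)` with `formula = "max"`.
#'
#' @inheritParams mcs_common_atoms
#' @param formula `"tanimoto"` (default) or `"max"`.
#' @return Distance in `[0, 1]`.
#' @export
scaffold_distance <- function(a, b, formula = c("tanimoto", "max"), timeout = 5) {
  formula <- match.arg(formula)
  if (is.character(a)) a <- mol_from_smiles(a)
  if (is.character(b)) b <- mol_from_smiles(b)
  na <- mol_heavy_atoms(a); nb_ <- mol_heavy_atoms(b)
  if (na == 0L || nb_ == 0L) return(1)
  m <- mcs_graphs(a, b, timeout = timeout)$size
  if (formula == "tanimoto") 1 - m / (na + nb_ - m) else 1 - m / max(na, nb_)
}
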