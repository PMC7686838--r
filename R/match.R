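# Subgraph (monomorphism) matching engine used by SMARTS screening and by the
# query-verification pass. Pattern atoms are mapped injectively onto molecule
# atoms; every pattern bond must be realized by a compatible molecule bond
# (extra molecule bonds are allowed, per substructure-search semantics).
#
# The pattern side is an "sq_pattern": list(atomic_num, arom, bonds) where
# bonds has i, j and a list-column `allowed` of molecule bond types drawn from
# {"single", "double", "triple", "arom"}.

mol_bond_types <- function(mol) {
  if (!n_bonds(mol)) return(character())
  ifelse(mol$bonds$arom, "arom",
         c("single", "double", "triple")[mol$bonds$order])
}

mol_atomic_numbers <- function(mol) {
  unname(ELEMENT_NUMBERS[mol$elem])
}

# Order pattern atoms so every atom after the first has an already-placed
# neighbour (pattern assumed connected).
pattern_search_order <- function(pat) {
  n <- length(pat$atomic_num)
  if (n <= 1L) return(seq_len(n))
  adj <- vector("list", n)
  for (k in seq_len(nrow(pat$bonds))) {
    i <- pat$bonds$i[k]; j <- pat$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  ord <- 1L; placed <- logical(n); placed[1L] <- TRUE
  while (length(ord) < n) {
    nxt <- which(!placed & vapply(seq_len(n), function(v) {
      any(placed[adj[[v]]])
    }, logical(1)))
    if (!length(nxt)) {
      stop_sq("validation", "disconnected pattern passed to matcher")
    }
    ord <- c(ord, nxt[1L]); placed[nxt[1L]] <- TRUE
  }
  ord
}

# All (or the first) injective mappings of `pat` into `mol`.
# Returns a list of integer vectors, index = pattern atom, value = mol atom.
match_pattern <- function(pat, mol, first_only = TRUE, max_matches = 1000L) {
  np <- length(pat$atomic_num)
  nm <- n_atoms(mol)
  if (np == 0L || np > nm) return(list())

  mol_num <- mol_atomic_numbers(mol)
  mol_type <- mol_bond_types(mol)
  lookup <- mol_bond_lookup(mol)
  adjm <- mol_adjacency(mol)

  ord <- pattern_search_order(pat)
  # for each position in the order, the pattern bonds to already-placed atoms
  pos_of <- integer(np); pos_of[ord] <- seq_len(np)
  back_edges <- vector("list", np)
  if (nrow(pat$bonds)) {
    for (k in seq_len(nrow(pat$bonds))) {
      i <- pat$bonds$i[k]; j <- pat$bonds$j[k]
      late <- if (pos_of[i] > pos_of[j]) i else j
      early <- if (late == i) j else i
      back_edges[[pos_of[late]]] <-
        c(back_edges[[pos_of[late]]],
          list(list(other = early, allowed = pat$bonds$allowed[[k]])))
    }
  }

  results <- list()
  map <- integer(np)          # pattern atom -> mol atom
  used <- logical(nm)

  place <- function(step) {
    if (length(results) >= max_matches) return(TRUE)
    if (step > np) {
      results[[length(results) + 1L]] <<- map
      return(first_only)
    }
    pa <- ord[step]
    cands <- if (step == 1L) {
      which(mol_num == pat$atomic_num[pa])
    } else {
      # candidates adjacent (in mol) to the image of one placed neighbour
      be <- back_edges[[step]][[1L]]
      adjm[[map[be$other]]]
    }
    for (mv in cands) {
      if (used[mv] || mol_num[mv] != pat$atomic_num[pa]) next
      ok <- TRUE
      for (be in back_edges[[step]]) {
        b <- lookup[map[be$other], mv]
        if (b == 0L || !(mol_type[b] %in% be$allowed)) { ok <- FALSE; break }
      }
      if (!ok) next
      map[pa] <<- mv; used[mv] <<- TRUE
      done <- place(step + 1L)
      used[mv] <<- FALSE
      if (done) return(TRUE)
    }
    FALSE
  }
  place(1L)
  results
}
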