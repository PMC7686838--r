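# SMILES writer. Emits one fragment per connected component joined by '.';
# atoms use the organic subset where legal, brackets otherwise. A single bond
# between two aromatic atoms is written '-' so it cannot be mistaken for an
# aromatic ring bond.

write_smiles <- function(mol, strip_stereo = FALSE) {
  if (n_atoms(mol) == 0L) return("")
  if (strip_stereo) mol <- clear_stereo(mol)
  comps <- mol_components(mol)
  paste(vapply(comps, function(cp) write_fragment(mol, cp), character(1)),
        collapse = ".")
}

clear_stereo <- function(mol) {
  mol$stereo[] <- ""
  if (n_bonds(mol)) mol$bonds$stereo[] <- ""
  mol
}

write_fragment <- function(mol, atoms) {
  lookup <- mol_bond_lookup(mol)
  adj <- mol_adjacency(mol)
  bs <- mol_bond_sums(mol)

  start <- atoms[1]
  visited <- logical(n_atoms(mol))
  tree_child <- vector("list", n_atoms(mol))
  closures <- vector("list", n_atoms(mol))   # per atom: list of (digit, bond id)
  used_bond <- logical(n_bonds(mol))
  digit_next <- 1L

  # DFS to classify tree edges and ring-closure edges
  order_stack <- start
  visited[start] <- TRUE
  dfs <- function(v) {
    for (w in adj[[v]]) {
      b <- lookup[v, w]
      if (used_bond[b]) next
      if (!visited[w]) {
        used_bond[b] <<- TRUE
        visited[w] <<- TRUE
        tree_child[[v]] <<- c(tree_child[[v]], w)
        dfs(w)
      } else {
        used_bond[b] <<- TRUE
        d <- digit_next; digit_next <<- digit_next + 1L
        closures[[v]] <<- c(closures[[v]], list(list(digit = d, bond = b)))
        closures[[w]] <<- c(closures[[w]], list(list(digit = d, bond = b)))
      }
    }
  }
  dfs(start)

  bond_glyph <- function(b, parent, child) {
    bd <- mol$bonds[b, ]
    if (bd$arom) {
      if (mol$arom[parent] && mol$arom[child]) return("")
      return(":")
    }
    if (bd$order == 2L) return("=")
    if (bd$order == 3L) return("#")
    if (nzchar(bd$stereo)) return(bd$stereo)
    if (mol$arom[parent] && mol$arom[child]) return("-")
    ""
  }

  emit <- function(v) {
    out <- atom_token(mol, v, bs[v])
    for (cl in closures[[v]]) {
      b <- cl$bond
      u <- if (mol$bonds$i[b] == v) mol$bonds$j[b] else mol$bonds$i[b]
      g <- bond_glyph(b, v, u)
      dig <- if (cl$digit > 9L) sprintf("%%%02d", cl$digit) else as.character(cl$digit)
      out <- paste0(out, g, dig)
    }
    kids <- tree_child[[v]]
    if (length(kids)) {
      for (k in seq_along(kids)) {
        w <- kids[k]
        part <- paste0(bond_glyph(lookup[v, w], v, w), emit(w))
        out <- if (k < length(kids)) paste0(out, "(", part, ")")
               else paste0(out, part)
      }
    }
    out
  }
  emit(start)
}

atom_token <- function(mol, v, bondsum) {
  el <- mol$elem[v]
  sym <- if (mol$arom[v]) tolower(el) else el
  plain_ok <- el %in% ORGANIC_SUBSET && mol$charge[v] == 0L &&
    !nzchar(mol$stereo[v]) && is.na(mol$iso[v]) &&
    mol$hcount[v] == implicit_hydrogens(el, mol$arom[v], bondsum)
  if (plain_ok) return(sym)
  h <- mol$hcount[v]
  hpart <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
  ch <- mol$charge[v]
  cpart <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-"
           else sprintf("%+d", ch)
  ipart <- if (is.na(mol$iso[v])) "" else as.character(mol$iso[v])
  paste0("[", ipart, sym, mol$stereo[v], hpart, cpart, "]")
}
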