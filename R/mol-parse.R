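# SMILES reader for the subset the pipeline needs: organic-subset atoms,
# bracket atoms with isotope/stereo/H-count/charge, aromatic lowercase atoms,
# bonds - = # : / \, branches, ring closures (digit and %nn, reusable), and
# '.'-separated fragments.
#
# Aromaticity policy: lowercase letters mark aromatic atoms; an unwritten bond
# between two aromatic atoms is aromatic when it lies on a ring and single
# otherwise (biphenyl). Inputs normally pass through OpenBabel canonicalization
# first (see mol_from_smiles()), which fixes one perception model for the run.

parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    stop_sq("unparseable", "empty or non-string SMILES input")
  }
  s <- trimws(smiles)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)

  elem <- character(); arom <- logical(); charge <- integer()
  hcount <- integer(); hexp <- logical(); stereo <- character(); iso <- integer()
  bi <- integer(); bj <- integer(); border <- integer()
  barom <- logical(); bstereo <- character()

  prev <- NA_integer_
  pending <- ""                    # bond glyph awaiting next atom/ring closure
  branch_stack <- integer()
  ring_open <- list()              # digit -> list(atom, bond)

  add_atom <- function(el, ar, ch, hc, he, st, is) {
    elem <<- c(elem, el); arom <<- c(arom, ar); charge <<- c(charge, ch)
    hcount <<- c(hcount, hc); hexp <<- c(hexp, he); stereo <<- c(stereo, st)
    iso <<- c(iso, is)
    length(elem)
  }
  add_bond <- function(a, b, glyph) {
    if (a == b) stop_sq("unparseable", sprintf("self-bond in SMILES '%s'", s))
    bi <<- c(bi, a); bj <<- c(bj, b)
    if (glyph %in% c("/", "\\")) {
      border <<- c(border, 1L); barom <<- c(barom, FALSE); bstereo <<- c(bstereo, glyph)
    } else if (glyph == "=") {
      border <<- c(border, 2L); barom <<- c(barom, FALSE); bstereo <<- c(bstereo, "")
    } else if (glyph == "#") {
      border <<- c(border, 3L); barom <<- c(barom, FALSE); bstereo <<- c(bstereo, "")
    } else if (glyph == ":") {
      border <<- c(border, 1L); barom <<- c(barom, TRUE); bstereo <<- c(bstereo, "")
    } else if (glyph == "-") {
      border <<- c(border, 1L); barom <<- c(barom, FALSE); bstereo <<- c(bstereo, "")
    } else {                                   # unspecified; resolved below
      border <<- c(border, 0L); barom <<- c(barom, FALSE); bstereo <<- c(bstereo, "")
    }
  }

  connect <- function(atom_id) {
    if (!is.na(prev)) add_bond(prev, atom_id, pending)
    prev <<- atom_id
    pending <<- ""
  }

  ring_closure <- function(digit) {
    key <- as.character(digit)
    if (is.null(ring_open[[key]])) {
      ring_open[[key]] <<- list(atom = prev, bond = pending)
    } else {
      op <- ring_open[[key]]
      glyph <- if (nzchar(pending)) pending else op$bond
      if (nzchar(pending) && nzchar(op$bond) && pending != op$bond &&
          !all(c(pending, op$bond) %in% c("/", "\\"))) {
        stop_sq("unparseable",
                sprintf("conflicting ring-closure bonds for %s in '%s'", key, s))
      }
      add_bond(op$atom, prev, glyph)
      ring_open[[key]] <<- NULL
    }
    pending <<- ""
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      close <- NA_integer_
      for (k in seq(i + 1L, n)) if (chars[k] == "]") { close <- k; break }
      if (is.na(close)) stop_sq("unparseable", sprintf("unclosed bracket in '%s'", s))
      at <- parse_bracket_atom(paste(chars[(i + 1L):(close - 1L)], collapse = ""), s)
      id <- add_atom(at$elem, at$arom, at$charge, at$hcount, TRUE, at$stereo, at$iso)
      connect(id)
      i <- close + 1L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        id <- add_atom(two, FALSE, 0L, 0L, FALSE, "", NA_integer_)
        i <- i + 2L
      } else {
        id <- add_atom(ch, FALSE, 0L, 0L, FALSE, "", NA_integer_)
        i <- i + 1L
      }
      connect(id)
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      id <- add_atom(toupper(ch), TRUE, 0L, 0L, FALSE, "", NA_integer_)
      connect(id)
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- ch
      i <- i + 1L
    } else if (ch == "(") {
      branch_stack <- c(branch_stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (!length(branch_stack)) stop_sq("unparseable", sprintf("unbalanced ')' in '%s'", s))
      prev <- branch_stack[length(branch_stack)]
      branch_stack <- branch_stack[-length(branch_stack)]
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      ring_closure(as.integer(ch))
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop_sq("unparseable", sprintf("truncated %% ring closure in '%s'", s))
      ring_closure(as.integer(paste0(chars[i + 1L], chars[i + 2L])))
      i <- i + 3L
    } else if (ch == ".") {
      prev <- NA_integer_
      pending <- ""
      i <- i + 1L
    } else {
      stop_sq("unparseable", sprintf("unexpected character '%s' in SMILES '%s'", ch, s))
    }
  }
  if (length(ring_open)) {
    stop_sq("unparseable", sprintf("unclosed ring bond in SMILES '%s'", s))
  }
  if (length(branch_stack)) {
    stop_sq("unparseable", sprintf("unbalanced '(' in SMILES '%s'", s))
  }

  mol <- new_mol(elem, arom, charge, hcount, hexp, stereo, iso,
                 data.frame(i = bi, j = bj, order = border, arom = barom,
                            stereo = bstereo, stringsAsFactors = FALSE))
  mol <- resolve_unspecified_bonds(mol)
  resolve_hydrogens(mol)
}

# [13CH3-], [nH], [N+], [C@@H] ... (no atom classes, no wildcards)
parse_bracket_atom <- function(body, smiles) {
  m <- regmatches(body, regexec(
    "^([0-9]*)([A-Za-z][a-z]?)(@{1,2})?(H[0-9]*)?([+-][0-9]*|\\+\\+|--)?$", body))[[1]]
  if (!length(m)) {
    stop_sq("unparseable", sprintf("bad bracket atom [%s] in '%s'", body, smiles))
  }
  sym <- m[3]
  ar <- sym %in% c("b", "c", "n", "o", "p", "s", "se", "as")
  el <- if (ar) {
    paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
  } else sym
  if (!el %in% names(ELEMENT_NUMBERS)) {
    stop_sq("unparseable", sprintf("unknown element '%s' in '%s'", el, smiles))
  }
  hc <- 0L
  if (nzchar(m[5])) {
    hc <- if (m[5] == "H") 1L else as.integer(substring(m[5], 2))
  }
  ch <- 0L
  if (nzchar(m[6])) {
    ch <- switch(m[6], "+" = 1L, "-" = -1L, "++" = 2L, "--" = -2L,
                 as.integer(m[6]))
  }
  list(elem = el, arom = ar, charge = ch, hcount = hc,
       stereo = if (is.na(m[4])) "" else m[4],
       iso = if (nzchar(m[2])) as.integer(m[2]) else NA_integer_)
}

# Bonds written without a glyph: aromatic when both ends are aromatic atoms and
# the bond lies on a ring; otherwise single.
resolve_unspecified_bonds <- function(mol) {
  unspec <- mol$bonds$order == 0L
  if (!any(unspec)) return(mol)
  mol$bonds$order[unspec] <- 1L
  cand <- unspec & mol$arom[mol$bonds$i] & mol$arom[mol$bonds$j]
  if (any(cand)) {
    on_ring <- mol_ring_bonds(mol)
    mol$bonds$arom[cand & on_ring] <- TRUE
  }
  mol
}
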