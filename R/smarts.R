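# SMARTS structural queries in the element-number dialect the pipeline emits
# and consumes: atoms as [#6]-style primitives, explicit bonds from
# {-, =, #, :}, "or" bond lists with comma (-,:), branches, reusable
# ring-closure digits. This is the dialect of published MCS query tables for
# this kind of workflow; hybrid glyphs written without the comma (-: or :-)
# are accepted and read as "single or aromatic".

BOND_GLYPH_TYPES <- c("-" = "single", "=" = "double", "#" = "triple", ":" = "arom")

#' Parse a SMARTS structural query
#'
#' Supports the query dialect used by this package: `[#n]` atom primitives,
#' explicit bonds `-`, `=`, `#`, `:` (comma-separated alternatives allowed),
#' branches and ring closures. Unspecified bonds match single or aromatic.
#'
#' @param smarts A single SMARTS string.
#' @return An `sq_pattern` object (atoms, bonds, allowed bond types).
#' @export
parse_smarts <- function(smarts) {
  if (!is.character(smarts) || length(smarts) != 1L || is.na(smarts) ||
      !nzchar(trimws(smarts))) {
    stop_sq("parse", "empty SMARTS pattern")
  }
  s <- gsub("[[:space:]]", "", smarts)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)

  atomic_num <- integer(); arom <- logical()
  bi <- integer(); bj <- integer(); ballowed <- list()
  prev <- NA_integer_
  pending <- character()     # accumulated bond glyphs for the next connection
  branch_stack <- integer()
  ring_open <- list()

  allowed_from <- function(glyphs) {
    if (!length(glyphs)) return(c("single", "arom"))   # unspecified
    unname(BOND_GLYPH_TYPES[glyphs])
  }
  add_bond <- function(a, b, glyphs) {
    bi <<- c(bi, a); bj <<- c(bj, b)
    ballowed <<- c(ballowed, list(allowed_from(glyphs)))
  }
  ring_closure <- function(digit) {
    key <- as.character(digit)
    if (is.null(ring_open[[key]])) {
      ring_open[[key]] <<- list(atom = prev, glyphs = pending)
    } else {
      op <- ring_open[[key]]
      glyphs <- if (length(pending)) pending else op$glyphs
      add_bond(op$atom, prev, glyphs)
      ring_open[[key]] <<- NULL
    }
    pending <<- character()
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      close <- NA_integer_
      for (k in seq(i + 1L, n)) if (chars[k] == "]") { close <- k; break }
      if (is.na(close)) stop_sq("parse", sprintf("unclosed bracket in SMARTS '%s'", s))
      body <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      m <- regmatches(body, regexec("^#([0-9]+)$", body))[[1]]
      if (!length(m)) {
        stop_sq("parse", sprintf("unsupported SMARTS atom [%s] in '%s'", body, s))
      }
      atomic_num <- c(atomic_num, as.integer(m[2])); arom <- c(arom, NA)
      id <- length(atomic_num)
      if (!is.na(prev)) add_bond(prev, id, pending)
      prev <- id; pending <- character()
      i <- close + 1L
    } else if (ch %in% c("-", "=", "#", ":")) {
      pending <- c(pending, ch)
      i <- i + 1L
    } else if (ch == ",") {
      i <- i + 1L                     # separator inside a bond alternative list
    } else if (ch == "(") {
      branch_stack <- c(branch_stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(branch_stack)) stop_sq("parse", sprintf("unbalanced ')' in '%s'", s))
      prev <- branch_stack[length(branch_stack)]
      branch_stack <- branch_stack[-length(branch_stack)]
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      ring_closure(as.integer(ch)); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop_sq("parse", sprintf("truncated %% closure in '%s'", s))
      ring_closure(as.integer(paste0(chars[i + 1L], chars[i + 2L])))
      i <- i + 3L
    } else {
      stop_sq("parse", sprintf("unexpected character '%s' in SMARTS '%s'", ch, s))
    }
  }
  if (length(ring_open)) stop_sq("parse", sprintf("unclosed ring bond in SMARTS '%s'", s))
  if (!length(atomic_num)) stop_sq("parse", sprintf("no atoms in SMARTS '%s'", s))

  pat <- structure(
    list(atomic_num = atomic_num, arom = arom,
         bonds = data.frame(i = bi, j = bj)),
    class = "sq_pattern"
  )
  pat$bonds$allowed <- ballowed
  if (length(pattern_components(pat)) != 1L) {
    stop_sq("parse", sprintf("disconnected SMARTS pattern '%s'", s))
  }
  pat
}

pattern_components <- function(pat) {
  m <- new_mol(
    elem = rep("C", length(pat$atomic_num)),
    arom = rep(FALSE, length(pat$atomic_num)),
    charge = integer(length(pat$atomic_num)),
    hcount = integer(length(pat$atomic_num)),
    hexp = rep(TRUE, length(pat$atomic_num)),
    stereo = rep("", length(pat$atomic_num)),
    iso = rep(NA_integer_, length(pat$atomic_num)),
    bonds = data.frame(i = pat$bonds$i, j = pat$bonds$j,
                       order = rep(1L, nrow(pat$bonds)),
                       arom = rep(FALSE, nrow(pat$bonds)),
                       stereo = rep("", nrow(pat$bonds)),
                       stringsAsFactors = FALSE)
  )
  mol_components(m)
}

#' @exportS3Method base::print
#' @noRd
print.sq_pattern <- function(x, ...) {
  cat("<sq_pattern> ", length(x$atomic_num), " atoms: ", render_smarts(x), "\n",
      sep = "")
  invisible(x)
}

pattern_n_atoms <- function(pat) length(pat$atomic_num)

# Render an sq_pattern (or an sq_mol) in the emitted SMARTS dialect: every
# atom an element-number primitive, every bond explicit.
render_smarts <- function(x) {
  if (is_mol(x)) x <- mol_to_pattern(x)
  n <- length(x$atomic_num)
  if (n == 0L) return("")
  adj <- vector("list", n)
  lookup <- matrix(0L, n, n)
  nb <- nrow(x$bonds)
  for (k in seq_len(nb)) {
    i <- x$bonds$i[k]; j <- x$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    lookup[i, j] <- k; lookup[j, i] <- k
  }
  glyph_of <- function(b) {
    al <- x$bonds$allowed[[b]]
    glyphs <- names(BOND_GLYPH_TYPES)[match(al, BOND_GLYPH_TYPES)]
    paste(glyphs, collapse = ",")
  }
  visited <- logical(n); used <- logical(nb)
  tree_child <- vector("list", n); closures <- vector("list", n)
  digit_next <- 1L
  dfs <- function(v) {
    for (w in adj[[v]]) {
      b <- lookup[v, w]
      if (used[b]) next
      if (!visited[w]) {
        used[b] <<- TRUE; visited[w] <<- TRUE
        tree_child[[v]] <<- c(tree_child[[v]], w)
        dfs(w)
      } else {
        used[b] <<- TRUE
        d <- digit_next; digit_next <<- digit_next + 1L
        closures[[v]] <<- c(closures[[v]], list(list(digit = d, bond = b)))
        closures[[w]] <<- c(closures[[w]], list(list(digit = d, bond = b)))
      }
    }
  }
  visited[1L] <- TRUE
  dfs(1L)
  emit <- function(v) {
    out <- paste0("[#", x$atomic_num[v], "]")
    for (cl in closures[[v]]) {
      dig <- if (cl$digit > 9L) sprintf("%%%02d", cl$digit) else as.character(cl$digit)
      out <- paste0(out, glyph_of(cl$bond), dig)
    }
    kids <- tree_child[[v]]
    for (k in seq_along(kids)) {
      w <- kids[k]
      part <- paste0(glyph_of(lookup[v, w]), emit(w))
      out <- if (k < length(kids)) paste0(out, "(", part, ")")
             else paste0(out, part)
    }
    out
  }
  emit(1L)
}

# Convert a molecule graph into a definite-bond pattern (used when a scaffold
# or an MCS result becomes a query).
mol_to_pattern <- function(mol) {
  heavy <- which(mol$elem != "H")
  mol <- mol_subgraph(mol, heavy)
  types <- mol_bond_types(mol)
  pat <- structure(
    list(atomic_num = mol_atomic_numbers(mol), arom = mol$arom,
         bonds = data.frame(i = mol$bonds$i, j = mol$bonds$j)),
    class = "sq_pattern"
  )
  pat$bonds$allowed <- lapply(types, identity)
  pat
}

#' Match a SMARTS query against a molecule
#'
#' @param pattern An `sq_pattern` from [parse_smarts()] (or a SMARTS string).
#' @param mol An internal molecule object or a SMILES string.
#' @param first_only Stop at the first embedding?
#' @return List of integer atom-index mappings (empty when no match).
#' @export
smarts_match <- function(pattern, mol, first_only = TRUE) {
  if (is.character(pattern)) pattern <- parse_smarts(pattern)
  if (is.character(mol)) mol <- mol_from_smiles(mol)
  match_pattern(pattern, mol, first_only = first_only)
}

#' @rdname smarts_match
#' @export
smarts_matches <- function(pattern, mol) {
  length(smarts_match(pattern, mol, first_only = TRUE)) > 0L
}
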