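# SMILES reading and writing for the heavy-atom subset handled by the
# package: organic-subset atoms, bracket atoms with charge / explicit H /
# atom-map, branches, ring closures, aromatic lowercase notation and the
# bond symbols - = # : . Stereo descriptors and isotopes are ignored.

#' Parse a SMILES string into a molecule
#'
#' Builds the heavy-atom molecular graph, perceives aromaticity (Kekule
#' input is normalized to aromatic form) and fills implicit hydrogens by
#' standard valence rules. Atom maps (`[CH3:1]`) are retained.
#'
#' @param s SMILES string for a single (possibly multi-fragment) molecule.
#' @return A molecule object.
#' @export
parse_smiles <- function(s) {
  s <- gsub("[@/\\\\]", "", trimws(s))
  if (!nchar(s)) stop("empty SMILES string")
  elem <- character(0); arom <- logical(0); charge <- integer(0)
  hcount <- integer(0); map <- integer(0); needs_h <- logical(0)
  b1 <- integer(0); b2 <- integer(0); bord <- character(0)

  add_atom <- function(el, ar, ch, hc, mp, implicit) {
    elem <<- c(elem, el); arom <<- c(arom, ar); charge <<- c(charge, ch)
    hcount <<- c(hcount, hc); map <<- c(map, mp); needs_h <<- c(needs_h, implicit)
    length(elem)
  }
  add_bond <- function(i, j, o) {
    b1 <<- c(b1, i); b2 <<- c(b2, j); bord <<- c(bord, o)
  }

  prev <- NA_integer_
  pend <- NA_character_       # pending explicit bond symbol
  stack <- integer(0)
  ring <- list()              # digit -> list(atom, order)
  i <- 1L; len <- nchar(s)
  getc <- function(k) substr(s, k, k)

  while (i <= len) {
    ch <- getc(i)
    if (ch == "(") {
      if (is.na(prev)) stop("branch start without preceding atom in ", s)
      stack <- c(stack, prev); i <- i + 1L; next
    }
    if (ch == ")") {
      if (!length(stack)) stop("unbalanced parenthesis in ", s)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L; next
    }
    if (ch %in% c("-", "=", "#", ":")) {
      pend <- switch(ch, "-" = "1", "=" = "2", "#" = "3", ":" = "ar")
      i <- i + 1L; next
    }
    if (ch == ".") {
      prev <- NA_integer_; pend <- NA_character_; i <- i + 1L; next
    }
    if (grepl("[0-9%]", ch)) {
      if (ch == "%") { digit <- substr(s, i + 1L, i + 2L); i <- i + 3L }
      else { digit <- ch; i <- i + 1L }
      if (is.na(prev)) stop("ring closure without atom in ", s)
      key <- digit
      if (!is.null(ring[[key]])) {
        op <- ring[[key]]
        o <- if (!is.na(pend)) pend else if (!is.na(op$order)) op$order
             else if (arom[prev] && arom[op$atom]) "ar" else "1"
        add_bond(op$atom, prev, o)
        ring[[key]] <- NULL
      } else {
        ring[[key]] <- list(atom = prev, order = pend)
      }
      pend <- NA_character_
      next
    }
    if (ch == "[") {
      close <- regexpr("]", substr(s, i, len), fixed = TRUE)
      if (close < 0) stop("unterminated bracket atom in ", s)
      body <- substr(s, i + 1L, i + close - 2L)
      i <- i + close
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(H[0-9]*)?(\\+{1,2}[0-9]*|-{1,2}[0-9]*)?(:([0-9]+))?$",
        body))[[1]]
      if (!length(m)) stop("cannot parse bracket atom [", body, "] in ", s)
      sym <- m[3]
      ar <- sym %in% c("b", "c", "n", "o", "p", "s")
      el <- if (ar) toupper(sym) else sym
      hc <- if (m[4] == "") 0L else if (m[4] == "H") 1L else as.integer(substr(m[4], 2L, 10L))
      chg <- 0L
      if (m[5] != "") {
        sign <- if (substr(m[5], 1L, 1L) == "+") 1L else -1L
        digits <- gsub("[+-]", "", m[5])
        nrep <- nchar(gsub("[^+-]", "", m[5]))
        chg <- sign * (if (digits == "") nrep else as.integer(digits))
      }
      mp <- if (m[7] == "") NA_integer_ else as.integer(m[7])
      a <- add_atom(el, ar, chg, hc, mp, FALSE)
    } else {
      two <- substr(s, i, i + 1L)
      if (two %in% c("Cl", "Br")) { el <- two; ar <- FALSE; i <- i + 2L }
      else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) { el <- ch; ar <- FALSE; i <- i + 1L }
      else if (ch %in% c("b", "c", "n", "o", "p", "s")) { el <- toupper(ch); ar <- TRUE; i <- i + 1L }
      else stop("unexpected character '", ch, "' in ", s)
      a <- add_atom(el, ar, 0L, NA_integer_, NA_integer_, TRUE)
    }
    if (!is.na(prev)) {
      o <- if (!is.na(pend)) pend else if (arom[prev] && arom[a]) "ar" else "1"
      add_bond(prev, a, o)
    }
    prev <- a; pend <- NA_character_
  }
  if (length(stack)) stop("unbalanced parenthesis in ", s)
  if (length(ring)) stop("unclosed ring bond in ", s)

  mol <- new_mol(
    data.frame(elem = elem, arom = arom, charge = charge,
               hcount = hcount, map = map, stringsAsFactors = FALSE),
    data.frame(a1 = b1, a2 = b2, order = bord, stringsAsFactors = FALSE)
  )
  mol <- normalize_aromaticity(mol)
  fill_implicit_h(mol, needs_h)
}

#' Write a molecule as SMILES
#'
#' With `canonical = TRUE` (default) atom order follows a canonical graph
#' ordering so that identical graphs yield byte-identical strings; this is
#' the canonical form used for compound identity everywhere in the package.
#'
#' @param mol molecule object.
#' @param canonical order atoms canonically before writing.
#' @param with_maps keep atom-map indices in the output.
#' @return A SMILES string.
#' @export
write_smiles <- function(mol, canonical = TRUE, with_maps = FALSE) {
  n <- n_atoms(mol)
  if (!n) return("")
  at <- mol$atoms
  if (canonical) {
    vlabs <- paste(at$elem, at$arom, at$charge, at$hcount,
                   if (with_maps) ifelse(is.na(at$map), 0L, at$map) else 0L)
    perm <- canon_graph(vlabs, mol$bonds$a1, mol$bonds$a2, mol$bonds$order)$perm
  } else {
    perm <- seq_len(n)
  }
  adj <- mol_adj(mol)

  visited <- logical(n)
  ring_num <- 0L
  ring_assign <- list()   # edge id -> digit
  tree_children <- vector("list", n)
  back_edges <- vector("list", n)

  # DFS in canonical order to classify tree vs ring-closure edges
  comp_starts <- integer(0)
  ordr <- order(perm)
  dfs <- function(v, parent_edge) {
    visited[v] <<- TRUE
    nbrs <- adj$nbr[[v]]; eids <- adj$eid[[v]]
    o <- order(perm[nbrs])
    for (k in o) {
      w <- nbrs[k]; e <- eids[k]
      if (!is.na(parent_edge) && e == parent_edge) next
      if (visited[w]) {
        if (is.null(ring_assign[[as.character(e)]])) {
          ring_num <<- ring_num + 1L
          ring_assign[[as.character(e)]] <<- ring_num
          back_edges[[w]] <<- c(back_edges[[w]], e)
          back_edges[[v]] <<- c(back_edges[[v]], e)
        }
      } else {
        tree_children[[v]] <<- c(tree_children[[v]], e)
        dfs(w, e)
      }
    }
  }
  for (v in ordr) if (!visited[v]) { comp_starts <- c(comp_starts, v); dfs(v, NA_integer_) }

  bond_sym <- function(o, i, j) {
    if (o == "ar") { if (at$arom[i] && at$arom[j]) "" else ":" }
    else if (o == "1") { if (at$arom[i] && at$arom[j]) "-" else "" }
    else if (o == "2") "="
    else "#"
  }

  atom_token <- function(i, incident_orders) {
    el <- at$elem[i]
    sym <- if (at$arom[i]) tolower(el) else el
    need_bracket <- !(el %in% ORGANIC_SUBSET) || at$charge[i] != 0L ||
      (with_maps && !is.na(at$map[i])) ||
      at$hcount[i] != implicit_h(el, incident_orders)
    if (!need_bracket) return(sym)
    h <- if (at$hcount[i] == 0L) "" else if (at$hcount[i] == 1L) "H" else paste0("H", at$hcount[i])
    chg <- at$charge[i]
    cs <- if (chg == 0L) "" else if (chg == 1L) "+" else if (chg == -1L) "-"
          else if (chg > 0L) paste0("+", chg) else paste0("-", abs(chg))
    mp <- if (with_maps && !is.na(at$map[i])) paste0(":", at$map[i]) else ""
    paste0("[", sym, h, cs, mp, "]")
  }

  emit <- function(v) {
    orders <- mol$bonds$order[adj$eid[[v]]]
    out <- atom_token(v, orders)
    for (e in back_edges[[v]]) {
      o <- mol$bonds$order[e]
      other <- if (mol$bonds$a1[e] == v) mol$bonds$a2[e] else mol$bonds$a1[e]
      num <- ring_assign[[as.character(e)]]
      numtok <- if (num > 9L) paste0("%", num) else as.character(num)
      out <- paste0(out, bond_sym(o, v, other), numtok)
    }
    kids <- tree_children[[v]]
    if (length(kids)) {
      for (idx in seq_along(kids)) {
        e <- kids[idx]
        w <- if (mol$bonds$a1[e] == v) mol$bonds$a2[e] else mol$bonds$a1[e]
        seg <- paste0(bond_sym(mol$bonds$order[e], v, w), emit(w))
        if (idx < length(kids)) out <- paste0(out, "(", seg, ")")
        else out <- paste0(out, seg)
      }
    }
    out
  }

  paste(vapply(comp_starts, emit, character(1)), collapse = ".")
}

# canonical certificate of the molecular graph (used by tests and identity
# checks; maps excluded)
mol_cert <- function(mol) {
  at <- mol$atoms
  graph_cert(paste(at$elem, at$arom, at$charge, at$hcount),
             mol$bonds$a1, mol$bonds$a2, mol$bonds$order)
}
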