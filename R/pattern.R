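# Substructure query engine. Supports the SMARTS subset the package emits
# and consumes: element symbols (aromatic lowercase), `#n` atomic element,
# `*` wildcard, charge, H<n> (total hydrogen count), D<n> (heavy degree),
# X<n> (total connections), recursive `$(...)` environments, `,` alternation
# with `;`/`&` conjunction inside brackets, the bond symbols `- = # : ~`
# (default bond: single-or-aromatic), branches and ring closures.

ATOMIC_NUM <- c(B = 5, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16, Cl = 17, Br = 35, I = 53)

empty_alt <- function() list(elem = NULL, arom = NA, charge = NULL,
                             H = NULL, D = NULL, X = NULL, rec = list())

parse_atom_primitives <- function(txt) {
  alt <- empty_alt()
  i <- 1L; len <- nchar(txt)
  while (i <= len) {
    rest <- substr(txt, i, len)
    if (grepl("^\\$\\(", rest)) {
      depth <- 0L; j <- i + 1L
      while (j <= len) {
        ch <- substr(txt, j, j)
        if (ch == "(") depth <- depth + 1L
        if (ch == ")") { depth <- depth - 1L; if (depth == 0L) break }
        j <- j + 1L
      }
      if (depth != 0L) stop("unbalanced $() in atom expression: ", txt)
      inner <- substr(txt, i + 2L, j - 1L)
      alt$rec <- c(alt$rec, list(parse_smarts(inner)))
      i <- j + 1L
    } else if (grepl("^#[0-9]+", rest)) {
      num <- regmatches(rest, regexpr("^#[0-9]+", rest))
      z <- as.integer(substr(num, 2L, 10L))
      el <- names(ATOMIC_NUM)[match(z, ATOMIC_NUM)]
      if (is.na(el)) stop("unsupported atomic number in pattern: ", num)
      alt$elem <- el; alt$arom <- NA
      i <- i + nchar(num)
    } else if (grepl("^(Cl|Br)", rest)) {
      alt$elem <- substr(rest, 1L, 2L); alt$arom <- FALSE; i <- i + 2L
    } else if (grepl("^[A-Z]", rest)) {
      ch <- substr(rest, 1L, 1L)
      if (ch == "H") {
        d <- regmatches(rest, regexpr("^H[0-9]?", rest))
        alt$H <- if (d == "H") 1L else as.integer(substr(d, 2L, 3L))
        i <- i + nchar(d)
      } else if (ch == "D") {
        d <- regmatches(rest, regexpr("^D[0-9]", rest))
        alt$D <- as.integer(substr(d, 2L, 2L)); i <- i + 2L
      } else if (ch == "X") {
        d <- regmatches(rest, regexpr("^X[0-9]", rest))
        alt$X <- as.integer(substr(d, 2L, 2L)); i <- i + 2L
      } else if (ch == "A") {
        alt$arom <- FALSE; i <- i + 1L
      } else {
        alt$elem <- ch; alt$arom <- FALSE; i <- i + 1L
      }
    } else if (grepl("^[a-z]", rest)) {
      ch <- substr(rest, 1L, 1L)
      if (ch == "a") { alt$arom <- TRUE; i <- i + 1L }
      else { alt$elem <- toupper(ch); alt$arom <- TRUE; i <- i + 1L }
    } else if (grepl("^\\+", rest)) {
      d <- regmatches(rest, regexpr("^\\++[0-9]*", rest))
      digits <- gsub("\\+", "", d)
      alt$charge <- if (digits == "") nchar(d) else as.integer(digits)
      i <- i + nchar(d)
    } else if (grepl("^-", rest)) {
      d <- regmatches(rest, regexpr("^-+[0-9]*", rest))
      digits <- gsub("-", "", d)
      alt$charge <- -(if (digits == "") nchar(d) else as.integer(digits))
      i <- i + nchar(d)
    } else if (substr(rest, 1L, 1L) == "*") {
      i <- i + 1L
    } else {
      stop("unsupported primitive at '", rest, "' in atom expression: ", txt)
    }
  }
  alt
}

# split on `,` at depth 0 (outside $())
split_alts <- function(txt) {
  parts <- character(0); depth <- 0L; cur <- ""
  for (k in seq_len(nchar(txt))) {
    ch <- substr(txt, k, k)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == "," && depth == 0L) { parts <- c(parts, cur); cur <- "" }
    else cur <- paste0(cur, ch)
  }
  c(parts, cur)
}

parse_bracket_expr <- function(body) {
  # strip trailing :map
  map <- NA_integer_
  m <- regmatches(body, regexpr(":[0-9]+$", body))
  if (length(m) && nchar(m)) {
    map <- as.integer(substr(m, 2L, 10L))
    body <- substr(body, 1L, nchar(body) - nchar(m))
  }
  alts <- lapply(split_alts(body), function(a) {
    parse_atom_primitives(gsub("[;&]", "", a))
  })
  list(alts = alts, map = map)
}

#' Parse a SMARTS pattern
#'
#' @param s pattern string (single component or branched/ringed graph).
#' @return A pattern object usable with [match_pattern()].
#' @export
parse_smarts <- function(s) {
  s <- trimws(s)
  atoms <- list(); maps <- integer(0)
  b1 <- integer(0); b2 <- integer(0); ballow <- list()
  prev <- NA_integer_; pend <- NULL
  stack <- integer(0); ring <- list()
  i <- 1L; len <- nchar(s)

  add_atom <- function(alts, map) {
    atoms[[length(atoms) + 1L]] <<- alts
    maps <<- c(maps, map)
    length(atoms)
  }
  add_bond <- function(a, b, allow) {
    b1 <<- c(b1, a); b2 <<- c(b2, b); ballow[[length(ballow) + 1L]] <<- allow
  }
  default_bond <- c("1", "ar")

  while (i <= len) {
    ch <- substr(s, i, i)
    if (ch == "(") { stack <- c(stack, prev); i <- i + 1L; next }
    if (ch == ")") { prev <- stack[length(stack)]; stack <- stack[-length(stack)]; i <- i + 1L; next }
    if (ch %in% c("-", "=", "#", ":", "~")) {
      pend <- switch(ch, "-" = "1", "=" = "2", "#" = "3", ":" = "ar", "~" = c("1", "2", "3", "ar"))
      i <- i + 1L; next
    }
    if (ch == ".") stop("multi-component patterns with '.' are not supported: ", s)
    if (grepl("[0-9%]", ch)) {
      if (ch == "%") { digit <- substr(s, i + 1L, i + 2L); i <- i + 3L }
      else { digit <- ch; i <- i + 1L }
      if (!is.null(ring[[digit]])) {
        op <- ring[[digit]]
        allow <- if (!is.null(pend)) pend else if (!is.null(op$allow)) op$allow else default_bond
        add_bond(op$atom, prev, allow)
        ring[[digit]] <- NULL
      } else ring[[digit]] <- list(atom = prev, allow = pend)
      pend <- NULL
      next
    }
    if (ch == "[") {
      depth <- 0L; j <- i
      while (j <= len) {
        cj <- substr(s, j, j)
        if (cj == "[") depth <- depth + 1L
        if (cj == "]") { depth <- depth - 1L; if (depth == 0L) break }
        j <- j + 1L
      }
      if (depth != 0L) stop("unterminated bracket in pattern: ", s)
      px <- parse_bracket_expr(substr(s, i + 1L, j - 1L))
      a <- add_atom(px$alts, px$map)
      i <- j + 1L
    } else {
      two <- substr(s, i, i + 1L)
      if (two %in% c("Cl", "Br")) { tok <- two; i <- i + 2L }
      else { tok <- ch; i <- i + 1L }
      a <- add_atom(list(parse_atom_primitives(tok)), NA_integer_)
    }
    if (!is.na(prev)) {
      add_bond(prev, a, if (!is.null(pend)) pend else default_bond)
    }
    prev <- a; pend <- NULL
  }
  if (length(ring)) stop("unclosed ring bond in pattern: ", s)
  structure(list(atoms = atoms, maps = maps,
                 bonds = list(a1 = b1, a2 = b2, allow = ballow)),
            class = "rm_pattern")
}

pattern_size <- function(pat) length(pat$atoms)

alt_ok <- function(alt, mol, adj, i) {
  at <- mol$atoms
  if (!is.null(alt$elem) && at$elem[i] != alt$elem) return(FALSE)
  if (!is.na(alt$arom) && at$arom[i] != alt$arom) return(FALSE)
  if (!is.null(alt$charge) && at$charge[i] != alt$charge) return(FALSE)
  if (!is.null(alt$H) && at$hcount[i] != alt$H) return(FALSE)
  deg <- length(adj$nbr[[i]])
  if (!is.null(alt$D) && deg != alt$D) return(FALSE)
  if (!is.null(alt$X) && deg + at$hcount[i] != alt$X) return(FALSE)
  if (length(alt$rec)) {
    for (rp in alt$rec) {
      if (!length(match_pattern(rp, mol, anchor = i, first_only = TRUE))) return(FALSE)
    }
  }
  TRUE
}

atom_matches <- function(pat, mol, adj, pa, i) {
  for (alt in pat$atoms[[pa]]) if (alt_ok(alt, mol, adj, i)) return(TRUE)
  FALSE
}

#' Match a pattern against a molecule
#'
#' Enumerates injective embeddings of the pattern graph into the molecule.
#' By default matching is substructure-style (extra molecule bonds among
#' matched atoms are allowed); `induced = TRUE` additionally requires that
#' no such extra bonds exist.
#'
#' @param pat pattern from [parse_smarts()].
#' @param mol molecule.
#' @param induced require an induced embedding.
#' @param first_only stop after the first embedding.
#' @param anchor optional molecule atom the first pattern atom must map to.
#' @return List of integer vectors (pattern atom index -> molecule atom index).
#' @export
match_pattern <- function(pat, mol, induced = FALSE, first_only = FALSE, anchor = NULL) {
  np <- pattern_size(pat)
  if (!np || !n_atoms(mol)) return(list())
  adj <- mol_adj(mol)

  # pattern adjacency
  padj <- adj_list(np, pat$bonds$a1, pat$bonds$a2)

  # visit order: components in index order, BFS within component
  ord <- integer(0); seen <- logical(np)
  for (s0 in seq_len(np)) {
    if (seen[s0]) next
    queue <- s0; seen[s0] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      ord <- c(ord, v)
      for (w in padj$nbr[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }

  # molecule bond order lookup
  key <- paste(mol$bonds$a1, mol$bonds$a2)
  bond_order_of <- function(i, j) {
    k <- match(paste(min(i, j), max(i, j)), key)
    if (is.na(k)) NA_character_ else mol$bonds$order[k]
  }

  results <- list()
  assign <- rep(NA_integer_, np)
  used <- logical(n_atoms(mol))

  try_place <- function(step) {
    if (length(results) && first_only) return(invisible(NULL))
    if (step > np) {
      if (induced) {
        img <- assign
        inset <- logical(n_atoms(mol)); inset[img] <- TRUE
        nmol_in <- sum(inset[mol$bonds$a1] & inset[mol$bonds$a2])
        if (nmol_in != length(pat$bonds$a1)) return(invisible(NULL))
      }
      results[[length(results) + 1L]] <<- assign
      return(invisible(NULL))
    }
    pa <- ord[step]
    back <- which(!is.na(assign[padj$nbr[[pa]]]))
    cands <- if (length(back)) {
      nb0 <- padj$nbr[[pa]][back[1L]]
      adj$nbr[[assign[nb0]]]
    } else if (!is.null(anchor) && pa == ord[1L]) {
      anchor
    } else {
      seq_len(n_atoms(mol))
    }
    for (i in cands) {
      if (used[i]) next
      if (!atom_matches(pat, mol, adj, pa, i)) next
      okb <- TRUE
      for (kk in seq_along(pat$bonds$a1)) {
        p1 <- pat$bonds$a1[kk]; p2 <- pat$bonds$a2[kk]
        other <- if (p1 == pa) p2 else if (p2 == pa) p1 else next
        if (is.na(assign[other])) next
        o <- bond_order_of(i, assign[other])
        if (is.na(o) || !(o %in% pat$bonds$allow[[kk]])) { okb <- FALSE; break }
      }
      if (!okb) next
      assign[pa] <<- i; used[i] <<- TRUE
      try_place(step + 1L)
      assign[pa] <<- NA_integer_; used[i] <<- FALSE
      if (length(results) && first_only) return(invisible(NULL))
    }
    invisible(NULL)
  }
  try_place(1L)
  results
}
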