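# SMIRKS serialization of composite rules, and application of textual
# SMIRKS/SMARTS rules to compounds. The structured rule object is the
# authoritative semantics; the emitted string is a faithful-but-slightly-
# more-permissive rendering (multiset-exact substituent options and
# multi-attachment substituents cannot be expressed in portable SMARTS).

# generic DFS writer for small pattern graphs with precomputed atom tokens
write_token_graph <- function(n, tokens, b1, b2, bsym) {
  if (!n) return("")
  adj <- adj_list(n, b1, b2)
  visited <- logical(n)
  ring_assign <- list(); ring_num <- 0L
  tree_children <- vector("list", n)
  back_edges <- vector("list", n)
  dfs <- function(v, pe) {
    visited[v] <<- TRUE
    nbrs <- adj$nbr[[v]]; eids <- adj$eid[[v]]
    if (is.null(nbrs)) return(invisible(NULL))
    for (k in order(nbrs)) {
      w <- nbrs[k]; e <- eids[k]
      if (!is.na(pe) && e == pe) next
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
  starts <- integer(0)
  for (v in seq_len(n)) if (!visited[v]) { starts <- c(starts, v); dfs(v, NA_integer_) }
  emit <- function(v) {
    out <- tokens[v]
    for (e in back_edges[[v]]) {
      out <- paste0(out, bsym[e], ring_assign[[as.character(e)]])
    }
    kids <- tree_children[[v]]
    for (idx in seq_along(kids)) {
      e <- kids[idx]
      w <- if (b1[e] == v) b2[e] else b1[e]
      seg <- paste0(bsym[e], emit(w))
      out <- if (idx < length(kids)) paste0(out, "(", seg, ")") else paste0(out, seg)
    }
    out
  }
  paste(vapply(starts, emit, character(1)), collapse = ".")
}

order_symbol <- function(o) switch(o, "1" = "-", "2" = "=", "3" = "#", "ar" = ":")

# render one leaf component as a rooted fragment for a $() environment:
# the backbone atom first, then its substituent subtrees
render_leaf_fragment <- function(core, groups, simple, key, choice, d) {
  # find a source member exhibiting this choice at this key
  for (id in simple$member_ids) {
    rxn <- groups$reactions[[id]]
    mol <- rxn$substrate
    adj <- mol_adj(mol)
    emb <- core$atom_of_pos[[id]][core$sub_pos]
    pos_of_atom <- integer(n_atoms(mol)); pos_of_atom[emb] <- core$sub_pos
    ch <- leaf_choices(mol, adj, emb, pos_of_atom, d)
    if (!identical(choice_at(ch, key), choice)) next
    p <- as.integer(strsplit(key, "+", fixed = TRUE)[[1]])
    if (length(p) != 1L) return(NULL)      # multi-attachment: inexpressible
    root <- emb[match(p, core$sub_pos)]
    dist <- bfs_dist(n_atoms(mol), adj, emb)
    included <- which(dist <= d & dist > 0)
    keep <- c(root, included)
    inset <- logical(n_atoms(mol)); inset[keep] <- TRUE
    # DFS from root over included atoms reachable without passing backbone
    tok <- function(a) {
      sym <- if (mol$atoms$arom[a]) tolower(mol$atoms$elem[a]) else mol$atoms$elem[a]
      if (mol$atoms$charge[a] != 0L) {
        paste0("[", sym, if (mol$atoms$charge[a] > 0) "+" else "-", "]")
      } else sym
    }
    visited <- logical(n_atoms(mol))
    rec <- function(a, from) {
      visited[a] <<- TRUE
      out <- tok(a)
      nbrs <- adj$nbr[[a]]; eids <- adj$eid[[a]]
      segs <- character(0)
      for (k in seq_along(nbrs)) {
        w <- nbrs[k]
        if (!inset[w] || visited[w] || (a == root && pos_of_atom[w] > 0L)) next
        if (a != root && pos_of_atom[w] > 0L) next
        segs <- c(segs, paste0(order_symbol(mol$bonds$order[eids[k]]), rec(w, a)))
      }
      if (length(segs) > 1L) {
        paste0(out, paste0("(", segs[-length(segs)], ")", collapse = ""), segs[length(segs)])
      } else paste0(out, paste(segs, collapse = ""))
    }
    # only render comps attached solely to this position (tree rendering;
    # ring closures through the backbone are inexpressible here)
    frag <- rec(root, NA)
    return(frag)
  }
  NULL
}

#' Serialize a composite rule as SMIRKS strings
#'
#' One SMIRKS per simple rule. Substrate-side atoms carry element,
#' aromaticity and charge; explicit-hydrogen states add H alternatives;
#' substituent options appear as recursive `$()` alternatives and
#' no-substituent positions as degree constraints. The product side encodes
#' the group's bond edits with atom maps; hydrogens are left implicit.
#'
#' @param rule composite rule.
#' @param groups the reaction-group set the rule was generated from.
#' @return Character vector of SMIRKS strings.
#' @export
emit_smirks <- function(rule, groups) {
  core <- rule$core
  sub_pos <- core$sub_pos
  npos <- nrow(core$atoms)

  prod_tokens <- vapply(seq_len(npos), function(p) {
    el <- core$atoms$elem[p]
    sym <- if (core$atoms$arom[p]) tolower(el) else el
    chg <- core$atoms$charge[p] + core$atoms$charge_delta[p]
    cs <- if (chg == 0L) "" else if (chg > 0L) strrep("+", chg) else strrep("-", -chg)
    paste0("[", sym, cs, ":", p, "]")
  }, character(1))
  pb <- core$bonds[core$bonds$order_prod != "0", , drop = FALSE]
  prod_side <- write_token_graph(npos, prod_tokens, pb$p1, pb$p2,
                                 vapply(pb$order_prod, order_symbol, character(1)))

  sb_keep <- core$bonds$order_sub != "0"
  sb <- core$bonds[sb_keep, , drop = FALSE]
  idx_of_pos <- integer(npos); idx_of_pos[sub_pos] <- seq_along(sub_pos)

  vapply(rule$simples, function(simple) {
    sub_tokens <- vapply(sub_pos, function(p) {
      el <- core$atoms$elem[p]
      sym <- if (core$atoms$arom[p]) tolower(el) else el
      chg <- core$atoms$charge[p]
      cs <- if (chg == 0L) "" else if (chg > 0L) strrep("+", chg) else strrep("-", -chg)
      base <- paste0(sym, cs)
      hvals <- NULL
      if (rule$h > 0L && p %in% core$h_order[seq_len(min(rule$h, length(core$h_order)))]) {
        hvals <- simple$h_sets[[as.character(p)]]
      }
      extras <- ""
      if (rule$d > 0L) {
        keys <- names(simple$options)
        mine <- keys[vapply(keys, function(k) {
          identical(strsplit(k, "+", fixed = TRUE)[[1]], as.character(p))
        }, logical(1))]
        if (length(mine) == 1L) {
          opts <- simple$options[[mine]]
          if (identical(opts, "EMPTY")) {
            extras <- paste0(";D", sum(sb$p1 == p | sb$p2 == p))
          } else {
            frags <- unlist(lapply(setdiff(opts, "EMPTY"), function(ch) {
              f <- render_leaf_fragment(core, groups, simple, mine, ch, rule$d)
              if (is.null(f)) character(0) else paste0("$(", f, ")")
            }))
            if (length(frags)) extras <- paste0(";", paste(frags, collapse = ","))
          }
        } else if (!length(mine)) {
          # no observed substituent record at this position at d>=1 means no
          # substituent is allowed there
          has_any <- any(vapply(keys, function(k) {
            p %in% as.integer(strsplit(k, "+", fixed = TRUE)[[1]])
          }, logical(1)))
          if (!has_any) extras <- paste0(";D", sum(sb$p1 == p | sb$p2 == p))
        }
      }
      alts <- if (is.null(hvals)) base else paste0(base, "H", hvals, collapse = ",")
      paste0("[", alts, extras, ":", p, "]")
    }, character(1))
    tokens_by_idx <- sub_tokens[order(idx_of_pos[sub_pos])]
    sub_side <- write_token_graph(length(sub_pos), tokens_by_idx,
                                  idx_of_pos[sb$p1], idx_of_pos[sb$p2],
                                  vapply(sb$order_sub, order_symbol, character(1)))
    paste0(sub_side, ">>", prod_side)
  }, character(1))
}

# ---- textual rule application ----------------------------------------------

#' Parse a SMIRKS string
#'
#' @param s `substrate>>products` pattern with atom maps.
#' @return A parsed SMIRKS object.
#' @export
parse_smirks <- function(s) {
  sides <- strsplit(s, ">>", fixed = TRUE)[[1]]
  if (length(sides) != 2L) stop("SMIRKS must contain exactly one '>>': ", s)
  lhs <- parse_smarts(sides[1])
  # split product side on top-level dots
  parts <- character(0); depth <- 0L; cur <- ""
  for (k in seq_len(nchar(sides[2]))) {
    ch <- substr(sides[2], k, k)
    if (ch %in% c("(", "[")) depth <- depth + 1L
    if (ch %in% c(")", "]")) depth <- depth - 1L
    if (ch == "." && depth == 0L) { parts <- c(parts, cur); cur <- "" }
    else cur <- paste0(cur, ch)
  }
  parts <- c(parts, cur)
  rhs <- lapply(parts, parse_smarts)
  structure(list(lhs = lhs, rhs = rhs, source = s), class = "rm_smirks")
}

#' Apply a textual SMIRKS rule to a compound
#'
#' Matches the substrate pattern and rewrites bonds and charges according
#' to the difference between the two sides; hydrogens are refilled by
#' valence on every edited atom. Intended for rule interchange (including
#' external SMARTS rule files); package-generated rules are applied exactly
#' through their structured form by [apply_rule()].
#'
#' @param sm SMIRKS object or string.
#' @param mol molecule or SMILES string.
#' @return List of predicted product sets (sorted canonical SMILES).
#' @export
apply_smirks <- function(sm, mol) {
  if (is.character(sm)) sm <- parse_smirks(sm)
  if (is.character(mol)) mol <- parse_smiles(mol)
  matches <- match_pattern(sm$lhs, mol)
  if (!length(matches)) return(list())

  lhs_maps <- sm$lhs$maps
  # rhs atom table: component, atom index, map, alt
  rhs_atoms <- do.call(rbind, lapply(seq_along(sm$rhs), function(ci) {
    pat <- sm$rhs[[ci]]
    data.frame(comp = ci, idx = seq_along(pat$atoms), map = pat$maps)
  }))
  rhs_alt <- function(ci, idx) sm$rhs[[ci]]$atoms[[idx]][[1L]]
  rhs_bonds <- do.call(rbind, lapply(seq_along(sm$rhs), function(ci) {
    pat <- sm$rhs[[ci]]
    if (!length(pat$bonds$a1)) return(NULL)
    data.frame(comp = ci, a1 = pat$bonds$a1, a2 = pat$bonds$a2,
               allow = I(pat$bonds$allow))
  }))

  resolve_order <- function(allow, arom1, arom2) {
    if (length(allow) == 1L) return(allow[[1L]])
    if (isTRUE(arom1) && isTRUE(arom2)) "ar" else "1"
  }

  out <- list()
  for (mm in matches) {
    atoms <- mol$atoms
    bonds <- mol$bonds
    atom_of_map <- stats::setNames(mm[!is.na(lhs_maps)],
                                   lhs_maps[!is.na(lhs_maps)])
    edited <- mm
    # new (product-only) atoms
    rhs_atom_idx <- matrix(NA_integer_, nrow = length(sm$rhs),
                           ncol = max(vapply(sm$rhs, pattern_size, integer(1))))
    for (r in seq_len(nrow(rhs_atoms))) {
      ci <- rhs_atoms$comp[r]; idx <- rhs_atoms$idx[r]; mp <- rhs_atoms$map[r]
      alt <- rhs_alt(ci, idx)
      if (!is.na(mp) && as.character(mp) %in% names(atom_of_map)) {
        a <- atom_of_map[[as.character(mp)]]
        atoms$charge[a] <- alt$charge %||% 0L
        rhs_atom_idx[ci, idx] <- a
      } else {
        atoms <- rbind(atoms, data.frame(
          elem = alt$elem %||% "C", arom = isTRUE(alt$arom),
          charge = alt$charge %||% 0L, hcount = alt$H %||% 0L,
          map = NA_integer_))
        rhs_atom_idx[ci, idx] <- nrow(atoms)
        edited <- c(edited, nrow(atoms))
      }
    }
    bkey <- paste(bonds$a1, bonds$a2)
    rhs_key <- if (is.null(rhs_bonds)) character(0) else {
      vapply(seq_len(nrow(rhs_bonds)), function(r) {
        m1 <- sm$rhs[[rhs_bonds$comp[r]]]$maps[rhs_bonds$a1[r]]
        m2 <- sm$rhs[[rhs_bonds$comp[r]]]$maps[rhs_bonds$a2[r]]
        paste(sort(c(m1, m2)), collapse = ">")
      }, character(1))
    }
    # lhs bonds between mapped atoms: cleave or re-order
    for (k in seq_along(sm$lhs$bonds$a1)) {
      p1 <- sm$lhs$bonds$a1[k]; p2 <- sm$lhs$bonds$a2[k]
      m1 <- lhs_maps[p1]; m2 <- lhs_maps[p2]
      if (is.na(m1) || is.na(m2)) next
      i <- atom_of_map[[as.character(m1)]]; j <- atom_of_map[[as.character(m2)]]
      idx <- match(paste(min(i, j), max(i, j)), bkey)
      rk <- match(paste(sort(c(m1, m2)), collapse = ">"), rhs_key)
      if (is.na(rk)) {
        if (!is.na(idx)) { bonds <- bonds[-idx, , drop = FALSE]; bkey <- bkey[-idx] }
      } else {
        r <- rhs_bonds[rk, ]
        alt1 <- rhs_alt(r$comp, r$a1); alt2 <- rhs_alt(r$comp, r$a2)
        o <- resolve_order(r$allow[[1L]], alt1$arom, alt2$arom)
        if (!is.na(idx)) bonds$order[idx] <- o
      }
    }
    # rhs bonds absent from lhs: formed
    if (!is.null(rhs_bonds)) for (r in seq_len(nrow(rhs_bonds))) {
      ci <- rhs_bonds$comp[r]
      m1 <- sm$rhs[[ci]]$maps[rhs_bonds$a1[r]]
      m2 <- sm$rhs[[ci]]$maps[rhs_bonds$a2[r]]
      in_lhs <- FALSE
      for (k in seq_along(sm$lhs$bonds$a1)) {
        lm1 <- lhs_maps[sm$lhs$bonds$a1[k]]; lm2 <- lhs_maps[sm$lhs$bonds$a2[k]]
        if (!is.na(m1) && !is.na(m2) && !is.na(lm1) && !is.na(lm2) &&
            setequal(c(m1, m2), c(lm1, lm2))) { in_lhs <- TRUE; break }
      }
      if (in_lhs) next
      i <- rhs_atom_idx[ci, rhs_bonds$a1[r]]; j <- rhs_atom_idx[ci, rhs_bonds$a2[r]]
      alt1 <- rhs_alt(ci, rhs_bonds$a1[r]); alt2 <- rhs_alt(ci, rhs_bonds$a2[r])
      o <- resolve_order(rhs_bonds$allow[[r]], alt1$arom, alt2$arom)
      bonds <- rbind(bonds, data.frame(a1 = min(i, j), a2 = max(i, j), order = o))
      bkey <- c(bkey, paste(min(i, j), max(i, j)))
    }
    prod <- new_mol(atoms, bonds)
    # refill hydrogens on edited atoms by valence
    adj2 <- mol_adj(prod)
    for (a in unique(edited)) {
      if (prod$atoms$charge[a] == 0L) {
        prod$atoms$hcount[a] <- implicit_h(prod$atoms$elem[a], atom_orders(prod, adj2, a))
      } else if (prod$atoms$elem[a] == "N" && prod$atoms$charge[a] == 1L) {
        prod$atoms$hcount[a] <- max(0L, 4L - floor(sum(order_num(atom_orders(prod, adj2, a)))))
      }
    }
    prod <- normalize_aromaticity(prod)
    comps <- components_of(n_atoms(prod), mol_adj(prod), seq_len(n_atoms(prod)))
    out <- c(out, list(sort(vapply(comps, function(cc) {
      write_smiles(subset_mol(prod, cc))
    }, character(1)))))
  }
  unique(out)
}

#' Read a plain-text rule file
#'
#' One SMIRKS/SMARTS transformation per line, `#` comments, optional
#' tab-separated label.
#'
#' @param path file path.
#' @return Named list of SMIRKS objects.
#' @export
read_rule_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (ln in seq_along(lines)) {
    raw <- trimws(sub("#.*$", "", lines[ln]))
    if (!nchar(raw)) next
    fields <- strsplit(raw, "\t", fixed = TRUE)[[1]]
    lab <- if (length(fields) > 1L) fields[2] else sprintf("rule%03d", length(out) + 1L)
    out[[lab]] <- parse_smirks(fields[1])
  }
  out
}
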