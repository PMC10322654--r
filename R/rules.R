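# Rule generation: align the reaction centers of a group, expand them by
# BFS to an adjustable diameter, combine substrate graphs without inventing
# unobserved substituent co-occurrences, and tune the resulting composite
# rule to a target genericity.
#
# A composite rule is represented structurally: a backbone pattern (the
# aligned reaction center plus incoming cosubstrate atoms and bond edits)
# shared by the whole group, and one or more simple rules, each a set of
# allowed substituent configurations ("leaf options") keyed by backbone
# attachment position. SMIRKS strings are a serialization of this object,
# not the object itself.

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- group core: aligned center + edits ------------------------------------

# labeled center graph of one member (substrate center atoms + incoming
# product atoms; edge labels carry before/after bond orders)
member_center_graph <- function(rxn, center) {
  ed <- center$edits
  sub <- rxn$substrate
  pm <- ed$prod_combined
  sub_atoms <- center$atoms
  k <- length(sub_atoms)
  inc <- ed$incoming_idx
  m <- length(inc)

  sub_map <- sub$atoms$map
  p_of_map <- ed$p_of_map

  vlabs <- character(k + m)
  changed <- logical(k + m)
  for (i in seq_len(k)) {
    a <- sub_atoms[i]
    mp <- as.character(sub_map[a])
    vlabs[i] <- paste("A", sub$atoms$elem[a], sub$atoms$arom[a], sub$atoms$charge[a],
                      ed$h_delta[[mp]], ed$charge_delta[[mp]], sep = "|")
    changed[i] <- a %in% center$changed_atoms
  }
  if (m) {
    for (j in seq_len(m)) {
      a <- inc[j]
      vlabs[k + j] <- paste("I", pm$atoms$elem[a], pm$atoms$arom[a],
                            pm$atoms$charge[a], pm$atoms$hcount[a], sep = "|")
      changed[k + j] <- TRUE
    }
  }

  # index helpers
  pos_of_sub <- integer(n_atoms(sub)); pos_of_sub[sub_atoms] <- seq_len(k)
  pos_of_pm <- integer(n_atoms(pm))
  pos_of_pm[p_of_map[as.character(sub_map[sub_atoms])]] <- seq_len(k)
  if (m) pos_of_pm[inc] <- k + seq_len(m)

  e1 <- integer(0); e2 <- integer(0); os <- character(0); op <- character(0)
  seen <- character(0)
  add_edge <- function(p1, p2, o_sub, o_prod) {
    a <- min(p1, p2); b <- max(p1, p2)
    key <- paste(a, b)
    if (key %in% seen) return(invisible(NULL))
    seen <<- c(seen, key)
    e1 <<- c(e1, a); e2 <<- c(e2, b); os <<- c(os, o_sub); op <<- c(op, o_prod)
  }
  # substrate bonds among center atoms
  sb <- sub$bonds
  pm_key <- paste(pm$bonds$a1, pm$bonds$a2)
  pm_order <- function(i, j) {
    kk <- match(paste(min(i, j), max(i, j)), pm_key)
    if (is.na(kk)) "0" else pm$bonds$order[kk]
  }
  for (bi in seq_len(nrow(sb))) {
    i <- sb$a1[bi]; j <- sb$a2[bi]
    if (pos_of_sub[i] && pos_of_sub[j]) {
      pi_ <- p_of_map[[as.character(sub_map[i])]]
      pj_ <- p_of_map[[as.character(sub_map[j])]]
      add_edge(pos_of_sub[i], pos_of_sub[j], sb$order[bi], pm_order(pi_, pj_))
    }
  }
  # product bonds among center positions (covers formed + incoming bonds)
  for (bi in seq_len(nrow(pm$bonds))) {
    i <- pm$bonds$a1[bi]; j <- pm$bonds$a2[bi]
    if (pos_of_pm[i] && pos_of_pm[j]) {
      p1 <- pos_of_pm[i]; p2 <- pos_of_pm[j]
      # substrate order, if both map back to substrate center atoms
      o_sub <- "0"
      if (p1 <= k && p2 <= k) {
        s1 <- sub_atoms[p1]; s2 <- sub_atoms[p2]
        kk <- which(sb$a1 == min(s1, s2) & sb$a2 == max(s1, s2))
        if (length(kk)) o_sub <- sb$order[kk]
      }
      add_edge(p1, p2, o_sub, pm$bonds$order[bi])
    }
  }
  elabs <- paste0(os, ">", op)
  cg <- canon_graph(vlabs, e1, e2, elabs)

  list(vlabs = vlabs, e1 = e1, e2 = e2, os = os, op = op,
       changed = changed, perm = cg$perm, cert = cg$cert,
       sub_atoms = sub_atoms, inc = inc, k = k, m = m)
}

# Build the shared backbone core for a reaction group. Errors if member
# centers are not isomorphic (which would indicate a clustering bug).
build_group_core <- function(groups, gid) {
  grp <- groups$groups[[gid]]
  mids <- grp$member_ids
  mg <- lapply(mids, function(id) {
    member_center_graph(groups$reactions[[id]], groups$centers[[id]])
  })
  names(mg) <- mids
  certs <- vapply(mg, `[[`, character(1), "cert")
  if (length(unique(certs)) != 1L) {
    stop("group ", gid, ": member reaction centers are not isomorphic; ",
         "fingerprint clustering is inconsistent")
  }
  rep_g <- mg[[1L]]
  npos <- rep_g$k + rep_g$m

  # canonical-position tables from the representative
  inv <- integer(npos)                # position -> rep vertex
  inv[rep_g$perm] <- seq_len(npos)
  atoms <- do.call(rbind, lapply(seq_len(npos), function(p) {
    v <- inv[p]
    f <- strsplit(rep_g$vlabs[v], "|", fixed = TRUE)[[1]]
    if (f[1] == "A") {
      data.frame(incoming = FALSE, elem = f[2], arom = as.logical(f[3]),
                 charge = as.integer(f[4]), h_delta = as.integer(f[5]),
                 charge_delta = as.integer(f[6]), inc_h = NA_integer_,
                 changed = rep_g$changed[v])
    } else {
      data.frame(incoming = TRUE, elem = f[2], arom = as.logical(f[3]),
                 charge = as.integer(f[4]), h_delta = 0L, charge_delta = 0L,
                 inc_h = as.integer(f[5]), changed = TRUE)
    }
  }))
  bonds <- data.frame(p1 = rep_g$perm[rep_g$e1], p2 = rep_g$perm[rep_g$e2],
                      order_sub = rep_g$os, order_prod = rep_g$op)
  sw <- bonds$p1 > bonds$p2
  tmp <- bonds$p1[sw]; bonds$p1[sw] <- bonds$p2[sw]; bonds$p2[sw] <- tmp
  bonds <- bonds[order(bonds$p1, bonds$p2), , drop = FALSE]

  # per-member: substrate atom of each non-incoming position
  atom_of_pos <- lapply(mg, function(g) {
    out <- rep(NA_integer_, npos)
    out[g$perm[seq_len(g$k)]] <- g$sub_atoms
    out
  })

  # explicit-hydrogen ordering: changed positions first, then the rest
  sub_pos <- which(!atoms$incoming)
  h_order <- c(sub_pos[atoms$changed[sub_pos]], sub_pos[!atoms$changed[sub_pos]])

  structure(list(group_id = gid, member_ids = mids, atoms = atoms,
                 bonds = bonds, cert = rep_g$cert, atom_of_pos = atom_of_pos,
                 sub_pos = sub_pos, h_order = h_order),
            class = "rm_core")
}

# substrate-side matcher pattern for the backbone
core_pattern <- function(core) {
  sub_pos <- core$sub_pos
  idx_of_pos <- integer(nrow(core$atoms)); idx_of_pos[sub_pos] <- seq_along(sub_pos)
  atoms <- lapply(sub_pos, function(p) {
    alt <- empty_alt()
    alt$elem <- core$atoms$elem[p]
    alt$arom <- core$atoms$arom[p]
    alt$charge <- core$atoms$charge[p]
    list(alt)
  })
  keep <- core$bonds$order_sub != "0" &
    !core$atoms$incoming[core$bonds$p1] & !core$atoms$incoming[core$bonds$p2]
  b <- core$bonds[keep, , drop = FALSE]
  structure(list(atoms = atoms, maps = rep(NA_integer_, length(sub_pos)),
                 bonds = list(a1 = idx_of_pos[b$p1], a2 = idx_of_pos[b$p2],
                              allow = as.list(b$order_sub))),
            class = "rm_pattern")
}

# ---- leaf components and substituent choices -------------------------------

# substituent configuration of a molecule around an embedded backbone at
# diameter d: named character vector, attachment-key -> choice signature
leaf_choices <- function(mol, adj, backbone_atoms, pos_of_atom, d) {
  n <- n_atoms(mol)
  dist <- bfs_dist(n, adj, backbone_atoms)
  included <- which(dist <= d & dist > 0)
  if (!length(included)) return(c())
  comps <- components_of(n, adj_subset(mol, adj, included), included)
  sigs <- character(0); keys <- character(0)
  for (comp in comps) {
    r <- leaf_signature(mol, adj, comp, dist, d, pos_of_atom)
    sigs <- c(sigs, r$sig); keys <- c(keys, r$key)
  }
  out <- vapply(split(sigs, keys), function(s) paste(sort(s), collapse = "&&"),
                character(1))
  out[order(names(out))]
}

# adjacency restricted to a vertex subset
adj_subset <- function(mol, adj, keep) {
  inset <- logical(n_atoms(mol)); inset[keep] <- TRUE
  b <- mol$bonds
  sel <- inset[b$a1] & inset[b$a2]
  adj_list(n_atoms(mol), b$a1[sel], b$a2[sel])
}

# canonical signature of one leaf component; pseudo-vertices represent the
# backbone positions it attaches to. Frontier atoms (at distance d) carry
# element and aromaticity only; interior atoms also charge.
leaf_signature <- function(mol, adj, comp, dist, d, pos_of_atom) {
  local <- integer(n_atoms(mol)); local[comp] <- seq_along(comp)
  vlabs <- vapply(comp, function(a) {
    if (dist[a] == d) paste("F", mol$atoms$elem[a], mol$atoms$arom[a], sep = "|")
    else paste("L", mol$atoms$elem[a], mol$atoms$arom[a], mol$atoms$charge[a], sep = "|")
  }, character(1))
  e1 <- integer(0); e2 <- integer(0); el <- character(0)
  b <- mol$bonds
  inset <- logical(n_atoms(mol)); inset[comp] <- TRUE
  pseudo <- integer(0)         # backbone position -> pseudo vertex index
  attach_pos <- integer(0)
  for (k in seq_len(nrow(b))) {
    i <- b$a1[k]; j <- b$a2[k]
    if (inset[i] && inset[j]) {
      e1 <- c(e1, local[i]); e2 <- c(e2, local[j]); el <- c(el, b$order[k])
    } else if (inset[i] && pos_of_atom[j] > 0L) {
      p <- pos_of_atom[j]
      if (!p %in% attach_pos) {
        attach_pos <- c(attach_pos, p)
        vlabs <- c(vlabs, paste0("B|", p))
        pseudo[as.character(p)] <- length(vlabs)
      }
      e1 <- c(e1, local[i]); e2 <- c(e2, pseudo[[as.character(p)]]); el <- c(el, b$order[k])
    } else if (inset[j] && pos_of_atom[i] > 0L) {
      p <- pos_of_atom[i]
      if (!p %in% attach_pos) {
        attach_pos <- c(attach_pos, p)
        vlabs <- c(vlabs, paste0("B|", p))
        pseudo[as.character(p)] <- length(vlabs)
      }
      e1 <- c(e1, local[j]); e2 <- c(e2, pseudo[[as.character(p)]]); el <- c(el, b$order[k])
    }
  }
  list(sig = graph_cert(vlabs, e1, e2, el),
       key = paste(sort(attach_pos), collapse = "+"))
}

# ---- embedding profiles -----------------------------------------------------

# All the state-independent information needed to evaluate a backbone
# against one compound: embeddings, per-diameter substituent choices,
# per-position hydrogen counts, and predicted product sets.
compound_profile <- function(core, mol, d_values) {
  pat <- core_pattern(core)
  embs <- match_pattern(pat, mol, induced = TRUE)
  adj <- mol_adj(mol)
  sub_pos <- core$sub_pos
  # hydrogen guard: an atom must carry the hydrogens the edit removes
  ok <- vapply(embs, function(e) {
    all(mol$atoms$hcount[e] + core$atoms$h_delta[sub_pos] >= 0L)
  }, logical(1))
  embs <- embs[ok]
  if (!length(embs)) return(list())
  lapply(embs, function(e) {
    pos_of_atom <- integer(n_atoms(mol))
    pos_of_atom[e] <- sub_pos
    choices <- lapply(d_values, function(d) {
      if (d == 0) c() else leaf_choices(mol, adj, e, pos_of_atom, d)
    })
    names(choices) <- as.character(d_values)
    list(emb = e,
         hvals = stats::setNames(mol$atoms$hcount[e], sub_pos),
         choices = choices,
         products = apply_edits(core, mol, e))
  })
}

# apply the group's bond edits through an embedding; returns the sorted
# canonical product set
apply_edits <- function(core, mol, emb) {
  sub_pos <- core$sub_pos
  atoms <- mol$atoms
  atoms$map <- NA_integer_
  atoms$hcount[emb] <- atoms$hcount[emb] + core$atoms$h_delta[sub_pos]
  atoms$charge[emb] <- atoms$charge[emb] + core$atoms$charge_delta[sub_pos]

  atom_of_pos <- rep(NA_integer_, nrow(core$atoms))
  atom_of_pos[sub_pos] <- emb
  inc_pos <- which(core$atoms$incoming)
  for (p in inc_pos) {
    atoms <- rbind(atoms, data.frame(
      elem = core$atoms$elem[p], arom = core$atoms$arom[p],
      charge = core$atoms$charge[p] + core$atoms$charge_delta[p],
      hcount = core$atoms$inc_h[p], map = NA_integer_))
    atom_of_pos[p] <- nrow(atoms)
  }

  bonds <- mol$bonds
  bkey <- paste(bonds$a1, bonds$a2)
  for (k in seq_len(nrow(core$bonds))) {
    p1 <- core$bonds$p1[k]; p2 <- core$bonds$p2[k]
    i <- atom_of_pos[p1]; j <- atom_of_pos[p2]
    a <- min(i, j); bmax <- max(i, j)
    o_sub <- core$bonds$order_sub[k]; o_prod <- core$bonds$order_prod[k]
    idx <- match(paste(a, bmax), bkey)
    if (o_prod == "0") {
      if (!is.na(idx)) { bonds <- bonds[-idx, , drop = FALSE]; bkey <- bkey[-idx] }
    } else if (o_sub == "0") {
      bonds <- rbind(bonds, data.frame(a1 = a, a2 = bmax, order = o_prod))
      bkey <- c(bkey, paste(a, bmax))
    } else if (o_sub != o_prod) {
      bonds$order[idx] <- o_prod
    }
  }
  out <- new_mol(atoms, bonds)
  out <- normalize_aromaticity_keep_h(out)
  comps <- components_of(n_atoms(out), mol_adj(out), seq_len(n_atoms(out)))
  sort(vapply(comps, function(cc) {
    write_smiles(subset_mol(out, cc))
  }, character(1)))
}

# aromaticity re-perception that leaves hydrogen counts untouched
normalize_aromaticity_keep_h <- function(mol) normalize_aromaticity(mol)

subset_mol <- function(mol, keep) {
  local <- integer(n_atoms(mol)); local[keep] <- seq_along(keep)
  b <- mol$bonds
  sel <- local[b$a1] > 0L & local[b$a2] > 0L
  new_mol(mol$atoms[keep, , drop = FALSE],
          data.frame(a1 = local[b$a1[sel]], a2 = local[b$a2[sel]],
                     order = b$order[sel]))
}

# ---- simple-rule combination (graph combination) ----------------------------

# observed substituent records for every member at diameter d
member_records <- function(core, groups, d) {
  lapply(core$member_ids, function(id) {
    rxn <- groups$reactions[[id]]
    mol <- rxn$substrate
    adj <- mol_adj(mol)
    e <- core$atom_of_pos[[id]]
    emb <- e[core$sub_pos]
    pos_of_atom <- integer(n_atoms(mol)); pos_of_atom[emb] <- core$sub_pos
    list(id = id,
         choices = if (d == 0) c() else leaf_choices(mol, adj, emb, pos_of_atom, d),
         hvals = stats::setNames(mol$atoms$hcount[emb], core$sub_pos))
  })
}

choice_at <- function(choices, key) {
  if (is.null(choices) || !key %in% names(choices)) return("EMPTY")
  choices[[key]]
}

# attachment keys are adjacent when their position sets touch (shared or
# bonded backbone positions); only adjacent keys constrain combination
keys_adjacent <- function(k1, k2, pos_adj) {
  ps1 <- as.integer(strsplit(k1, "+", fixed = TRUE)[[1]])
  ps2 <- as.integer(strsplit(k2, "+", fixed = TRUE)[[1]])
  for (p in ps1) for (q in ps2) {
    if (p == q || pos_adj[p, q]) return(TRUE)
  }
  FALSE
}

# greedy graph combination at one diameter: merge member substrate graphs
# unless that would create a substituent co-occurrence not observed in any
# source reaction (the over-generalization guard)
combine_records <- function(records, core) {
  np <- nrow(core$atoms)
  pos_adj <- matrix(FALSE, np, np)
  sel <- core$bonds$order_sub != "0"
  for (k in which(sel)) {
    pos_adj[core$bonds$p1[k], core$bonds$p2[k]] <- TRUE
    pos_adj[core$bonds$p2[k], core$bonds$p1[k]] <- TRUE
  }

  sig_of <- vapply(records, function(r) {
    paste(paste(names(r$choices), r$choices, sep = "="), collapse = ";")
  }, character(1))
  items <- lapply(unique(sig_of), function(s) {
    recs <- records[sig_of == s]
    list(records = recs, n = length(recs), sig = s)
  })
  ord <- order(-vapply(items, `[[`, integer(1), "n"),
               vapply(items, `[[`, character(1), "sig"))
  items <- items[ord]

  legal_union <- function(recs) {
    keys <- sort(unique(unlist(lapply(recs, function(r) names(r$choices)))))
    if (length(keys) > 1L) {
      for (i in seq_along(keys)) for (j in seq_along(keys)) {
        if (i >= j) next
        if (!keys_adjacent(keys[i], keys[j], pos_adj)) next
        o1 <- unique(vapply(recs, function(r) choice_at(r$choices, keys[i]), character(1)))
        o2 <- unique(vapply(recs, function(r) choice_at(r$choices, keys[j]), character(1)))
        for (c1 in o1) for (c2 in o2) {
          seen <- any(vapply(recs, function(r) {
            choice_at(r$choices, keys[i]) == c1 && choice_at(r$choices, keys[j]) == c2
          }, logical(1)))
          if (!seen) return(FALSE)
        }
      }
    }
    TRUE
  }

  clusters <- list()
  for (it in items) {
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      cand <- c(clusters[[ci]], it$records)
      if (legal_union(cand)) { clusters[[ci]] <- cand; placed <- TRUE; break }
    }
    if (!placed) clusters[[length(clusters) + 1L]] <- it$records
  }

  lapply(clusters, function(recs) {
    keys <- sort(unique(unlist(lapply(recs, function(r) names(r$choices)))))
    options <- lapply(keys, function(k) {
      sort(unique(vapply(recs, function(r) choice_at(r$choices, k), character(1))))
    })
    names(options) <- keys
    h_sets <- lapply(core$sub_pos, function(p) {
      sort(unique(vapply(recs, function(r) r$hvals[[as.character(p)]], integer(1))))
    })
    names(h_sets) <- as.character(core$sub_pos)
    list(options = options, h_sets = h_sets,
         member_ids = sort(vapply(recs, `[[`, character(1), "id")))
  })
}

# ---- composite rules --------------------------------------------------------

build_composite <- function(core, groups, d, h) {
  simples <- combine_records(member_records(core, groups, d), core)
  structure(list(core = core, group_id = core$group_id, d = d, h = h,
                 simples = simples, genericity = NA_real_,
                 ps = NA_integer_, ns = NA_integer_),
            class = "rm_rule")
}

#' @export
print.rm_rule <- function(x, ...) {
  cat("<composite rule ", x$group_id, "> ", length(x$simples), " simple rule(s), ",
      "diameter ", x$d, ", explicit-H ", x$h,
      if (!is.na(x$genericity)) paste0(", genericity ", signif(x$genericity, 4)) else "",
      "\n", sep = "")
  invisible(x)
}

# does one embedding profile satisfy one simple rule at state (d, h)?
profile_passes <- function(prof, simple, core, d, h) {
  if (d > 0) {
    ch <- prof$choices[[as.character(d)]]
    keys <- union(names(simple$options), names(ch))
    for (k in keys) {
      cc <- if (k %in% names(ch)) ch[[k]] else "EMPTY"
      opts <- simple$options[[k]] %||% "EMPTY"
      if (!cc %in% opts) return(FALSE)
    }
  }
  if (h > 0) {
    hp <- core$h_order[seq_len(min(h, length(core$h_order)))]
    for (p in hp) {
      if (!prof$hvals[[as.character(p)]] %in% simple$h_sets[[as.character(p)]]) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# Evaluate a rule on one compound profile list: which product sets fire
rule_fire <- function(rule, profs) {
  hits <- list()
  for (prof in profs) {
    pass <- any(vapply(rule$simples, function(s) {
      profile_passes(prof, s, rule$core, rule$d, rule$h)
    }, logical(1)))
    if (pass) hits[[length(hits) + 1L]] <- prof$products
  }
  unique(hits)
}

#' Apply a composite rule to a compound
#'
#' @param rule composite rule.
#' @param mol molecule (or SMILES string).
#' @return List of predicted product sets, each a sorted character vector of
#'   canonical product SMILES; empty list when the rule does not trigger.
#' @export
apply_rule <- function(rule, mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  profs <- compound_profile(rule$core, mol, rule$d)
  rule_fire(rule, profs)
}

#' Does a rule cover a reaction?
#'
#' A reaction is covered when the rule, applied to its substrate, yields the
#' observed product set among its predictions.
#'
#' @param rule composite rule.
#' @param rxn mapped reaction.
#' @return Logical.
#' @export
rule_covers <- function(rule, rxn) {
  obs <- observed_product_set(rxn)
  any(vapply(apply_rule(rule, rxn$substrate), identical, logical(1), y = obs))
}

observed_product_set <- function(rxn) {
  sort(vapply(rxn$products, function(p) write_smiles(strip_maps(p)), character(1)))
}

# observed reactions indexed by substrate canonical form
observed_index <- function(rxns) {
  idx <- list()
  for (r in rxns) {
    key <- mol_signature(r$substrate)
    idx[[key]] <- c(idx[[key]], list(observed_product_set(r)))
  }
  idx
}

# ---- genericity -------------------------------------------------------------

# PS/NS counts for a rule given per-compound profiles
genericity_counts <- function(rule, profiles, observed) {
  ps <- 0L; ns <- 0L
  for (key in names(profiles)) {
    sets <- rule_fire(rule, profiles[[key]])
    if (!length(sets)) next
    obs <- observed[[key]]
    hit <- length(obs) && any(vapply(sets, function(s) {
      any(vapply(obs, identical, logical(1), y = s))
    }, logical(1)))
    if (hit) ps <- ps + 1L else ns <- ns + 1L
  }
  list(ps = ps, ns = ns,
       value = if (ps > 0L) ns / ps else if (ns > 0L) Inf else NaN)
}

#' Compute the genericity of a rule over a compound universe
#'
#' Genericity is the ratio NS/PS: the number of compounds the rule triggers
#' on without any predicted product set matching an observed reaction (NS),
#' over the number where a prediction is observed (PS). `Inf` when PS is 0
#' with NS > 0; `NaN` when the rule never triggers.
#'
#' @param rule composite rule.
#' @param compounds character vector of compound SMILES (or parsed
#'   molecules).
#' @param observed list of mapped reactions, or a prebuilt observed index.
#' @return List with `ps`, `ns` and `value`.
#' @export
compute_genericity <- function(rule, compounds, observed) {
  mols <- as_compound_list(compounds)
  if (!is.list(observed) || (length(observed) && inherits(observed[[1]], "rm_rxn"))) {
    observed <- observed_index(observed)
  }
  profiles <- lapply(names(mols), function(sig) {
    compound_profile_cached(rule$core, mols[[sig]], sig, rule$d)
  })
  names(profiles) <- names(mols)
  genericity_counts(rule, profiles, observed)
}

as_compound_list <- function(compounds) {
  if (is.character(compounds)) compounds <- lapply(compounds, parse_smiles)
  sigs <- vapply(compounds, mol_signature, character(1))
  keep <- !duplicated(sigs)
  stats::setNames(compounds[keep], sigs[keep])
}

# ---- genericity tuning ------------------------------------------------------

# Ordered state path from most generic to most specific. The maximal
# diameter exceeds the largest member eccentricity by one so that the most
# specific state has no frontier atoms left: it matches exactly the member
# substrates.
state_path <- function(core, groups) {
  dmax <- 0L
  for (id in core$member_ids) {
    mol <- groups$reactions[[id]]$substrate
    emb <- core$atom_of_pos[[id]][core$sub_pos]
    dist <- bfs_dist(n_atoms(mol), mol_adj(mol), emb)
    dmax <- max(dmax, max(dist[is.finite(dist)]))
  }
  dmax <- as.integer(dmax) + 1L
  states <- lapply(0:dmax, function(d) c(d = d, h = 0L))
  hmax <- length(core$h_order)
  if (hmax > 0L) states <- c(states, lapply(seq_len(hmax), function(h) c(d = dmax, h = h)))
  states
}

#' Tune a group's composite rule to a target genericity
#'
#' Walks the specificity ladder from the bare reaction center (diameter 0)
#' through increasing BFS diameters and then increasing explicit-hydrogen
#' constraints, evaluating the genericity of each state over the compound
#' universe, and returns the state whose genericity is as close as possible
#' to the target (ties broken toward the more generic state). Sentinel
#' genericities (never triggers, or PS = 0) never win unless every state is
#' a sentinel, in which case the most generic state is returned. Every state
#' covers all group reactions by construction.
#'
#' @param groups reaction-group set from [cluster_reactions()].
#' @param gid group id (must be eligible unless `allow_singleton`).
#' @param target target genericity (>= 0).
#' @param compounds compound universe (SMILES or molecules).
#' @param observed reactions or observed index.
#' @param allow_singleton permit tuning a singleton group.
#' @return Composite rule with genericity metadata and the evaluated state
#'   trace in attribute `"trace"`.
#' @export
tune_genericity <- function(groups, gid, target, compounds, observed,
                            allow_singleton = FALSE) {
  grp <- groups$groups[[gid]]
  if (is.null(grp)) stop("unknown group: ", gid)
  if (!grp$eligible && !allow_singleton) {
    stop("group ", gid, " has fewer than 2 reactions; not eligible")
  }
  if (target < 0) stop("target genericity must be non-negative")
  core <- build_group_core(groups, gid)
  mols <- as_compound_list(compounds)
  if (!is.list(observed) || (length(observed) && inherits(observed[[1]], "rm_rxn"))) {
    observed <- observed_index(observed)
  }
  states <- state_path(core, groups)
  d_values <- sort(unique(vapply(states, function(s) as.integer(s[["d"]]), integer(1))))
  profiles <- lapply(names(mols), function(sig) {
    compound_profile_cached(core, mols[[sig]], sig, d_values)
  })
  names(profiles) <- names(mols)

  trace <- data.frame(d = integer(0), h = integer(0), ps = integer(0),
                      ns = integer(0), genericity = numeric(0))
  rules <- vector("list", length(states))
  dists <- numeric(length(states))
  for (i in seq_along(states)) {
    st <- states[[i]]
    rl <- build_composite(core, groups, st[["d"]], st[["h"]])
    gc_ <- genericity_counts(rl, profiles, observed)
    rl$genericity <- gc_$value; rl$ps <- gc_$ps; rl$ns <- gc_$ns
    rules[[i]] <- rl
    dists[i] <- if (is.nan(gc_$value) || is.infinite(gc_$value)) Inf
                else abs(gc_$value - target)
    trace <- rbind(trace, data.frame(d = st[["d"]], h = st[["h"]],
                                     ps = gc_$ps, ns = gc_$ns,
                                     genericity = gc_$value))
  }
  best <- if (all(is.infinite(dists))) 1L else which.min(dists)
  out <- rules[[best]]

  # coverage must never be lost by tuning
  for (id in core$member_ids) {
    if (!rule_covers(out, groups$reactions[[id]])) {
      stop("internal error: tuned rule for group ", gid,
           " fails to cover member reaction ", id)
    }
  }
  attr(out, "trace") <- trace
  out
}
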