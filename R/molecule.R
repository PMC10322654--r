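# Molecule objects: heavy-atom graphs with element, aromaticity flag, formal
# charge, total hydrogen count and optional atom-map index. Bond orders are
# "1", "2", "3" or "ar".

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_ELEMS <- c("B", "C", "N", "O", "P", "S")

# default valence alternatives used for implicit hydrogen filling
VALENCES <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

new_mol <- function(atoms, bonds) {
  if (nrow(bonds)) {
    sw <- bonds$a1 > bonds$a2
    tmp <- bonds$a1[sw]; bonds$a1[sw] <- bonds$a2[sw]; bonds$a2[sw] <- tmp
    bonds <- bonds[order(bonds$a1, bonds$a2), , drop = FALSE]
    rownames(bonds) <- NULL
  }
  structure(list(atoms = atoms, bonds = bonds), class = "rm_mol")
}

n_atoms <- function(mol) nrow(mol$atoms)

mol_adj <- function(mol) adj_list(n_atoms(mol), mol$bonds$a1, mol$bonds$a2)

# numeric bond order; aromatic counts 1.5
order_num <- function(o) {
  out <- rep(1.5, length(o))
  plain <- o != "ar"
  out[plain] <- as.numeric(o[plain])
  out
}

# implicit hydrogen count for an uncharged organic-subset atom given the
# orders of its incident bonds (standard SMILES valence filling)
implicit_h <- function(elem, orders) {
  vs <- VALENCES[[elem]]
  if (is.null(vs)) return(0L)
  bs <- floor(sum(order_num(orders)))
  v <- vs[vs >= bs]
  if (!length(v)) return(0L)
  as.integer(v[1L] - bs)
}

atom_orders <- function(mol, adj, i) mol$bonds$order[adj$eid[[i]]]

#' @export
print.rm_mol <- function(x, ...) {
  cat("<molecule> ", write_smiles(x), "  (", n_atoms(x), " heavy atoms)\n", sep = "")
  invisible(x)
}

#' Canonical identity string of a molecule
#'
#' The canonical SMILES with atom maps stripped; compound identity
#' throughout the package (pathway nodes, observed-reaction lookup,
#' compound universes) is equality of this string.
#'
#' @param mol molecule object.
#' @return Canonical SMILES string.
#' @export
mol_signature <- function(mol) write_smiles(mol, canonical = TRUE, with_maps = FALSE)

mol_identical <- function(a, b) mol_signature(a) == mol_signature(b)

# drop all atom maps
strip_maps <- function(mol) {
  mol$atoms$map <- NA_integer_
  mol
}

# simple ring membership per bond: a bond is in a ring iff its endpoints stay
# connected after removing it
bond_in_ring <- function(mol) {
  nb <- nrow(mol$bonds)
  if (!nb) return(logical(0))
  out <- logical(nb)
  for (k in seq_len(nb)) {
    e1 <- mol$bonds$a1[-k]; e2 <- mol$bonds$a2[-k]
    adj <- adj_list(n_atoms(mol), e1, e2)
    d <- bfs_dist(n_atoms(mol), adj, mol$bonds$a1[k])
    out[k] <- is.finite(d[mol$bonds$a2[k]])
  }
  out
}

# rings of size <= max_size as unique sorted atom sets, via shortest
# alternative path around each bond
find_rings <- function(mol, max_size = 6L) {
  nb <- nrow(mol$bonds)
  rings <- list()
  seen <- character(0)
  n <- n_atoms(mol)
  for (k in seq_len(nb)) {
    e1 <- mol$bonds$a1[-k]; e2 <- mol$bonds$a2[-k]
    adj <- adj_list(n, e1, e2)
    src <- mol$bonds$a1[k]; dst <- mol$bonds$a2[k]
    # BFS with parent tracking
    d <- rep(Inf, n); par <- rep(NA_integer_, n)
    d[src] <- 0; queue <- src
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj$nbr[[v]]) if (is.infinite(d[w])) {
        d[w] <- d[v] + 1; par[w] <- v; queue <- c(queue, w)
      }
    }
    if (!is.finite(d[dst]) || d[dst] > max_size - 1L) next
    path <- dst
    while (path[length(path)] != src) path <- c(path, par[path[length(path)]])
    key <- paste(sort(path), collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- sort(path)
    }
  }
  rings
}

# Perceive aromaticity: Hueckel-style check on rings of size 5-6 (benzene,
# pyridine, pyrrole/furan/thiophene chemotypes and their fused analogues).
# Kekule rings are upgraded to aromatic atoms/bonds; stray "ar" annotations
# not supported by any aromatic ring are demoted to single bonds.
normalize_aromaticity <- function(mol) {
  n <- n_atoms(mol)
  if (!n) return(mol)
  adj <- mol_adj(mol)
  rings <- find_rings(mol, 6L)
  rings <- Filter(function(r) length(r) %in% c(5L, 6L), rings)
  arom_atoms <- logical(n)
  arom_bonds <- logical(nrow(mol$bonds))
  for (r in rings) {
    in_r <- logical(n); in_r[r] <- TRUE
    pi_count <- 0
    ok <- TRUE
    for (a in r) {
      eids <- adj$eid[[a]]
      nbrs <- adj$nbr[[a]]
      ring_orders <- mol$bonds$order[eids[in_r[nbrs]]]
      exo_orders <- mol$bonds$order[eids[!in_r[nbrs]]]
      el <- mol$atoms$elem[a]
      if (el %in% c("C")) {
        if (any(ring_orders %in% c("2", "ar"))) pi_count <- pi_count + 1
        else if (any(exo_orders == "2")) { ok <- FALSE; break }  # cross-conjugated
        else { ok <- FALSE; break }
      } else if (el %in% c("N", "P")) {
        hc <- mol$atoms$hcount[a]
        deg <- length(nbrs)
        if (any(ring_orders == "2")) pi_count <- pi_count + 1
        else if (any(ring_orders == "ar")) {
          # pyrrole-type (lone pair in ring): N-H or three connections
          if ((!is.na(hc) && hc > 0) || deg == 3L) pi_count <- pi_count + 2
          else pi_count <- pi_count + 1
        } else pi_count <- pi_count + 2
      } else if (el %in% c("O", "S")) {
        if (any(ring_orders == "2")) { ok <- FALSE; break }
        pi_count <- pi_count + 2
      } else { ok <- FALSE; break }
    }
    if (ok && pi_count == 6) {
      arom_atoms[r] <- TRUE
      ring_eids <- which((in_r[mol$bonds$a1] & in_r[mol$bonds$a2]))
      # only bonds actually on the cycle (both endpoints in ring and each
      # endpoint has exactly two ring neighbours for simple rings); for our
      # size-limited rings every in-ring bond between ring atoms qualifies
      for (k in ring_eids) {
        a1 <- mol$bonds$a1[k]; a2 <- mol$bonds$a2[k]
        if (a1 %in% r && a2 %in% r) arom_bonds[k] <- TRUE
      }
    }
  }
  mol$atoms$arom <- arom_atoms
  ord <- mol$bonds$order
  ord[arom_bonds] <- "ar"
  ord[!arom_bonds & ord == "ar"] <- "1"
  mol$bonds$order <- ord
  mol
}

# fill implicit hydrogens (only for atoms flagged during parsing)
fill_implicit_h <- function(mol, needs_h) {
  adj <- mol_adj(mol)
  for (i in which(needs_h)) {
    mol$atoms$hcount[i] <- implicit_h(mol$atoms$elem[i], atom_orders(mol, adj, i))
  }
  mol
}
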