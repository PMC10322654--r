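# Reaction fingerprints: three part-tagged descriptor multisets summarizing
# the reaction center (bond formation/cleavage, bond-order changes, and
# center atom environments on both sides). Descriptors are canonical
# strings, so Tanimoto 1.0 is exact multiset equality - collision-free by
# construction, which is all the clustering threshold uses.

atom_fp_token <- function(elem, arom, charge = 0L) {
  paste0(elem, ifelse(arom, "~a", ""),
         ifelse(charge != 0L, sprintf("%+d", charge), ""))
}

# descriptor for a bond given endpoint tokens plus ring flag
bond_fp_desc <- function(tok1, tok2, in_ring, order_before, order_after, event) {
  ends <- sort(c(tok1, tok2))
  paste0(event, ":", ends[1], "*", ends[2],
         ifelse(in_ring, "@R", ""), ":", order_before, ">", order_after)
}

#' Compute the reaction fingerprint
#'
#' @param rxn mapped reaction.
#' @param center reaction center from [detect_reaction_center()].
#' @return A reaction-fingerprint object (three descriptor multisets).
#' @export
reaction_fingerprint <- function(rxn, center) {
  ed <- center$edits
  sub <- rxn$substrate
  pm <- ed$prod_combined
  sub_ring <- bond_in_ring(sub)
  pm_ring <- bond_in_ring(pm)
  map_to_idx <- match(seq_len(max(ed$sub_map)), ed$sub_map)

  sub_tok <- function(m) {
    i <- map_to_idx[m]
    atom_fp_token(sub$atoms$elem[i], sub$atoms$arom[i], sub$atoms$charge[i])
  }
  pm_tok <- function(i) atom_fp_token(pm$atoms$elem[i], pm$atoms$arom[i], pm$atoms$charge[i])

  sub_bond_ring <- function(m1, m2) {
    i <- map_to_idx[m1]; j <- map_to_idx[m2]
    k <- which((sub$bonds$a1 == min(i, j)) & (sub$bonds$a2 == max(i, j)))
    length(k) && sub_ring[k]
  }
  pm_bond_ring <- function(a1, a2) {
    k <- which((pm$bonds$a1 == min(a1, a2)) & (pm$bonds$a2 == max(a1, a2)))
    length(k) && pm_ring[k]
  }

  fc <- character(0)
  if (nrow(ed$cleaved)) {
    fc <- c(fc, mapply(function(m1, m2, o) {
      bond_fp_desc(sub_tok(m1), sub_tok(m2), sub_bond_ring(m1, m2), o, "0", "cleave")
    }, ed$cleaved$m1, ed$cleaved$m2, ed$cleaved$order))
  }
  if (nrow(ed$formed)) {
    fc <- c(fc, mapply(function(a1, a2, o) {
      bond_fp_desc(pm_tok(a1), pm_tok(a2), pm_bond_ring(a1, a2), "0", o, "form")
    }, ed$formed$a1, ed$formed$a2, ed$formed$order))
  }
  if (nrow(ed$incoming_formed)) {
    fc <- c(fc, mapply(function(a1, a2, o) {
      bond_fp_desc(pm_tok(a1), pm_tok(a2), pm_bond_ring(a1, a2), "0", o, "form")
    }, ed$incoming_formed$a1, ed$incoming_formed$a2, ed$incoming_formed$order))
  }

  bc <- character(0)
  if (nrow(ed$order_changed)) {
    bc <- c(bc, mapply(function(m1, m2, ob, oa) {
      bond_fp_desc(sub_tok(m1), sub_tok(m2), sub_bond_ring(m1, m2), ob, oa, "order")
    }, ed$order_changed$m1, ed$order_changed$m2,
       ed$order_changed$order_before, ed$order_changed$order_after))
  }

  # center atom environments of radius 1 restricted to the center-induced
  # subgraph on each side
  env_descs <- function(mol, atoms, tag) {
    if (!length(atoms)) return(character(0))
    inset <- logical(n_atoms(mol)); inset[atoms] <- TRUE
    adj <- mol_adj(mol)
    vapply(atoms, function(a) {
      nb <- adj$nbr[[a]]; eid <- adj$eid[[a]]
      keep <- inset[nb]
      toks <- sort(paste0(mol$bonds$order[eid[keep]], "-",
                          atom_fp_token(mol$atoms$elem[nb[keep]],
                                        mol$atoms$arom[nb[keep]],
                                        mol$atoms$charge[nb[keep]])))
      paste0(tag, ":", atom_fp_token(mol$atoms$elem[a], mol$atoms$arom[a],
                                     mol$atoms$charge[a]),
             "(", paste(toks, collapse = ","), ")")
    }, character(1))
  }
  prod_center <- c(ed$p_of_map[as.character(sub$atoms$map[center$atoms])],
                   ed$incoming_idx)
  ce <- c(env_descs(sub, center$atoms, "s"),
          env_descs(pm, prod_center, "p"))

  structure(list(fc = sort(as.character(unlist(fc))),
                 bc = sort(as.character(unlist(bc))),
                 ce = sort(as.character(unlist(ce)))),
            class = "rm_fp")
}

fp_all <- function(fp) {
  c(paste0("fc|", fp$fc, recycle0 = TRUE),
    paste0("bc|", fp$bc, recycle0 = TRUE),
    paste0("ce|", fp$ce, recycle0 = TRUE))
}

fp_key <- function(fp) paste(fp_all(fp), collapse = "")

#' @export
print.rm_fp <- function(x, ...) {
  cat("<reaction fingerprint> parts:",
      length(x$fc), "formation/cleavage,", length(x$bc), "bond-change,",
      length(x$ce), "center-environment\n")
  invisible(x)
}

#' Tanimoto similarity of two reaction fingerprints
#'
#' Multiset Jaccard over the part-tagged union of all three descriptor
#' multisets; 1.0 iff all parts are equal as multisets. Two empty
#' fingerprints are identical by convention (1.0).
#'
#' @param a,b reaction fingerprints.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  va <- fp_all(a); vb <- fp_all(b)
  if (!length(va) && !length(vb)) return(1.0)
  ta <- table(va); tb <- table(vb)
  keys <- union(names(ta), names(tb))
  ca <- ifelse(keys %in% names(ta), as.integer(ta[keys]), 0L)
  cb <- ifelse(keys %in% names(tb), as.integer(tb[keys]), 0L)
  sum(pmin(ca, cb)) / sum(pmax(ca, cb))
}

#' Cluster reactions by exact fingerprint identity
#'
#' Reactions whose fingerprints have Tanimoto exactly 1.0 (equal descriptor
#' multisets) form one group. Singleton groups are retained but flagged
#' ineligible for rule generation; groups are ordered by their first member
#' reaction-id, so the partition is input-order invariant.
#'
#' @param rxns list of mapped reactions with unique ids.
#' @param fgs functional group list used for center completion.
#' @return A reaction-group set.
#' @export
cluster_reactions <- function(rxns, fgs = default_functional_groups()) {
  ids <- vapply(rxns, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate reaction id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (!all(vapply(rxns, `[[`, logical(1), "mapped"))) {
    stop("all reactions must be mapped before clustering")
  }
  names(rxns) <- ids
  centers <- lapply(rxns, detect_reaction_center, fgs = fgs)
  fps <- lapply(ids, function(i) reaction_fingerprint(rxns[[i]], centers[[i]]))
  names(fps) <- ids
  keys <- vapply(fps, fp_key, character(1))

  ukeys <- unique(keys)
  members <- lapply(ukeys, function(k) sort(ids[keys == k]))
  first <- vapply(members, `[[`, character(1), 1L)
  ord <- order(first)
  members <- members[ord]; ukeys <- ukeys[ord]

  groups <- lapply(seq_along(ukeys), function(g) {
    list(id = sprintf("g%03d", g),
         fingerprint = fps[[members[[g]][1L]]],
         member_ids = members[[g]],
         eligible = length(members[[g]]) >= 2L)
  })
  names(groups) <- vapply(groups, `[[`, character(1), "id")
  structure(list(groups = groups, reactions = rxns, centers = centers,
                 fgs = fgs),
            class = "rm_groups")
}

#' @export
print.rm_groups <- function(x, ...) {
  ne <- sum(vapply(x$groups, `[[`, logical(1), "eligible"))
  cat("<reaction groups> ", length(x$reactions), " reactions in ",
      length(x$groups), " groups (", ne, " eligible)\n", sep = "")
  invisible(x)
}
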