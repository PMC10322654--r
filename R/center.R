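# Reaction centers: the changed atoms and bonds of a mapped reaction,
# extended to whole functional groups whenever a predefined group overlaps
# any changed atom.

# tabulate all bond edits of a mapped reaction, keyed by atom-map index
reaction_edits <- function(rxn) {
  stopifnot(rxn$mapped)
  sub <- rxn$substrate
  cp <- combined_products(rxn)
  pm <- cp$mol

  sub_map <- sub$atoms$map                       # atom idx -> map
  pmap <- pm$atoms$map                           # combined product idx -> map
  p_of_map <- match(sub_map, pmap)               # combined idx per substrate map
  names(p_of_map) <- as.character(sub_map)

  bond_tab <- function(mol, mapv) {
    b <- mol$bonds
    if (!nrow(b)) return(data.frame(m1 = integer(0), m2 = integer(0),
                                    order = character(0), a1 = integer(0), a2 = integer(0)))
    m1 <- mapv[b$a1]; m2 <- mapv[b$a2]
    keep <- !is.na(m1) & !is.na(m2)
    out <- data.frame(m1 = pmin(m1[keep], m2[keep]), m2 = pmax(m1[keep], m2[keep]),
                      order = b$order[keep], a1 = b$a1[keep], a2 = b$a2[keep])
    out[order(out$m1, out$m2), , drop = FALSE]
  }
  sb <- bond_tab(sub, sub_map)
  pb <- bond_tab(pm, pmap)
  skey <- paste(sb$m1, sb$m2); pkey <- paste(pb$m1, pb$m2)

  cleaved <- sb[!skey %in% pkey, , drop = FALSE]
  formed <- pb[!pkey %in% skey, , drop = FALSE]
  common_s <- sb[skey %in% pkey, , drop = FALSE]
  common_p <- pb[match(paste(common_s$m1, common_s$m2), pkey), , drop = FALSE]
  chg <- common_s$order != common_p$order
  order_changed <- data.frame(m1 = common_s$m1, m2 = common_s$m2,
                              order_before = common_s$order,
                              order_after = common_p$order)[chg, , drop = FALSE]

  # bonds involving incoming (unmapped) product atoms are always "formed"
  b <- pm$bonds
  inc_idx <- which(is.na(pmap))
  inc_formed <- if (nrow(b)) {
    touch <- (b$a1 %in% inc_idx) | (b$a2 %in% inc_idx)
    data.frame(a1 = b$a1[touch], a2 = b$a2[touch], order = b$order[touch])
  } else data.frame(a1 = integer(0), a2 = integer(0), order = character(0))

  # per-map attribute deltas
  sel <- p_of_map
  h_delta <- pm$atoms$hcount[sel] - sub$atoms$hcount
  charge_delta <- pm$atoms$charge[sel] - sub$atoms$charge
  names(h_delta) <- names(charge_delta) <- as.character(sub_map)

  list(cleaved = cleaved, formed = formed, order_changed = order_changed,
       incoming_formed = inc_formed, incoming_idx = inc_idx,
       h_delta = h_delta, charge_delta = charge_delta,
       prod_combined = pm, p_of_map = p_of_map, sub_map = sub_map)
}

#' Detect the reaction center of a mapped reaction
#'
#' The center comprises the endpoints of every formed, cleaved or
#' order-changed bond, every atom with a hydrogen-count or charge change,
#' and - when any of those atoms intersects a match of a configured
#' functional group - the entire matched group.
#'
#' @param rxn mapped reaction.
#' @param fgs functional group list from [load_functional_groups()] (or
#'   `NULL` for none).
#' @return A reaction-center object.
#' @export
detect_reaction_center <- function(rxn, fgs = default_functional_groups()) {
  ed <- reaction_edits(rxn)
  sub <- rxn$substrate
  map_to_idx <- match(seq_len(max(ed$sub_map)), ed$sub_map)  # map -> sub atom idx

  changed_maps <- unique(c(
    ed$cleaved$m1, ed$cleaved$m2,
    ed$order_changed$m1, ed$order_changed$m2,
    ed$formed$m1, ed$formed$m2,
    as.integer(names(ed$h_delta)[ed$h_delta != 0]),
    as.integer(names(ed$charge_delta)[ed$charge_delta != 0])
  ))
  # substrate-side endpoints of bonds formed to incoming atoms
  pmapv <- ed$prod_combined$atoms$map
  if (nrow(ed$incoming_formed)) {
    mm <- c(pmapv[ed$incoming_formed$a1], pmapv[ed$incoming_formed$a2])
    changed_maps <- unique(c(changed_maps, mm[!is.na(mm)]))
  }
  changed_atoms <- sort(map_to_idx[changed_maps])

  fg_hits <- list()
  center_atoms <- changed_atoms
  if (length(fgs)) {
    for (fg in fgs) {
      ms <- match_pattern(fg$pattern, sub)
      for (m in ms) {
        if (length(intersect(m, changed_atoms))) {
          center_atoms <- union(center_atoms, m)
          fg_hits[[length(fg_hits) + 1L]] <- list(name = fg$name, atoms = sort(m))
        }
      }
    }
  }
  center_atoms <- sort(center_atoms)

  structure(list(
    changed_atoms = changed_atoms,
    atoms = center_atoms,              # substrate-side center incl. groups
    completed_groups = fg_hits,
    edits = ed
  ), class = "rm_center")
}

#' @export
print.rm_center <- function(x, ...) {
  cat("<reaction center> ", length(x$atoms), " substrate atoms (",
      length(x$changed_atoms), " changed), ",
      nrow(x$edits$cleaved), " cleaved / ", nrow(x$edits$formed) +
        nrow(x$edits$incoming_formed), " formed / ",
      nrow(x$edits$order_changed), " order-changed bonds, ",
      length(x$completed_groups), " completed group(s)\n", sep = "")
  invisible(x)
}
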