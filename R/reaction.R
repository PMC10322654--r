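# Reactions: a single substrate transformed into one or more products, with
# an atom-atom mapping (AAM) between substrate and product heavy atoms.
# Product atoms without a map are tolerated only for configured implicit
# cosubstrate elements (by default oxygen, covering water/O2-derived atoms
# in hydrolysis and oxygenation reactions); they are tagged "incoming".

#' Parse one reaction SMILES line
#'
#' Accepts `substrate>>product1.product2` with or without atom maps. With
#' maps present the mapping is validated as an element-preserving bijection
#' from substrate heavy atoms onto mapped product heavy atoms; without maps
#' an unmapped reaction is returned, to be completed with [map_atoms()].
#'
#' @param line reaction SMILES.
#' @param id reaction identifier.
#' @param incoming_elems elements allowed to appear in products without a
#'   map (implicit cosubstrate atoms).
#' @return A reaction object (`mapped` flag indicates whether an AAM is
#'   established).
#' @export
parse_reaction <- function(line, id = "r1", incoming_elems = c("O")) {
  sides <- strsplit(line, ">>", fixed = TRUE)[[1]]
  if (length(sides) != 2L) stop("reaction ", id, ": expected exactly one '>>'")
  sub <- parse_smiles(sides[1])
  # substrate must be a single connected component
  adj <- mol_adj(sub)
  if (length(components_of(n_atoms(sub), adj, seq_len(n_atoms(sub)))) != 1L) {
    stop("reaction ", id, ": substrate has more than one component")
  }
  prods <- lapply(strsplit(sides[2], ".", fixed = TRUE)[[1]], parse_smiles)

  has_maps <- any(!is.na(sub$atoms$map)) ||
    any(vapply(prods, function(p) any(!is.na(p$atoms$map)), logical(1)))
  rxn <- structure(list(id = id, substrate = sub, products = prods,
                        mapped = FALSE, incoming = NULL,
                        incoming_elems = incoming_elems),
                   class = "rm_rxn")
  if (!has_maps) return(rxn)
  validate_mapping(rxn)
}

# check the AAM bijection and record incoming (unmapped cosubstrate) atoms
validate_mapping <- function(rxn) {
  sub <- rxn$substrate
  smap <- sub$atoms$map
  if (any(is.na(smap))) stop("reaction ", rxn$id, ": unmapped substrate atom(s)")
  if (anyDuplicated(smap)) stop("reaction ", rxn$id, ": duplicate substrate map index")
  ptab <- do.call(rbind, lapply(seq_along(rxn$products), function(pi) {
    p <- rxn$products[[pi]]
    data.frame(prod = pi, atom = seq_len(n_atoms(p)),
               map = p$atoms$map, elem = p$atoms$elem)
  }))
  mapped <- ptab[!is.na(ptab$map), , drop = FALSE]
  if (anyDuplicated(mapped$map)) stop("reaction ", rxn$id, ": duplicate product map index")
  if (!setequal(smap, mapped$map) || nrow(mapped) != length(smap)) {
    stop("reaction ", rxn$id, ": atom maps are not a bijection")
  }
  sel <- match(smap, mapped$map)
  if (any(sub$atoms$elem != mapped$elem[sel])) {
    bad <- which(sub$atoms$elem != mapped$elem[sel])[1]
    stop("reaction ", rxn$id, ": mapped atoms change element (map index ",
         smap[bad], ": ", sub$atoms$elem[bad], " -> ", mapped$elem[sel][bad], ")")
  }
  extra <- ptab[is.na(ptab$map), , drop = FALSE]
  if (nrow(extra) && !all(extra$elem %in% rxn$incoming_elems)) {
    bad <- setdiff(unique(extra$elem), rxn$incoming_elems)
    stop("reaction ", rxn$id, ": product gains non-cosubstrate atom(s): ",
         paste(bad, collapse = ", "))
  }
  rxn$incoming <- extra[, c("prod", "atom", "elem"), drop = FALSE]
  rxn$mapped <- TRUE
  rxn
}

#' @export
print.rm_rxn <- function(x, ...) {
  cat("<reaction ", x$id, if (x$mapped) " (mapped)>" else " (unmapped)>",
      " ", write_reaction_smiles(x), "\n", sep = "")
  invisible(x)
}

#' Serialize a reaction as reaction SMILES
#'
#' @param rxn reaction object.
#' @param with_maps include atom maps.
#' @return A reaction SMILES string.
#' @export
write_reaction_smiles <- function(rxn, with_maps = TRUE) {
  paste0(write_smiles(rxn$substrate, with_maps = with_maps), ">>",
         paste(vapply(rxn$products, write_smiles, character(1),
                      with_maps = with_maps), collapse = "."))
}

# combined product "super-molecule" with per-atom (prod, atom) origin
combined_products <- function(rxn) {
  atoms <- do.call(rbind, lapply(rxn$products, function(p) p$atoms))
  offs <- cumsum(c(0L, vapply(rxn$products, n_atoms, integer(1))))
  bonds <- do.call(rbind, lapply(seq_along(rxn$products), function(pi) {
    b <- rxn$products[[pi]]$bonds
    if (nrow(b)) { b$a1 <- b$a1 + offs[pi]; b$a2 <- b$a2 + offs[pi] }
    b
  }))
  origin <- do.call(rbind, lapply(seq_along(rxn$products), function(pi) {
    data.frame(prod = pi, atom = seq_len(n_atoms(rxn$products[[pi]])))
  }))
  list(mol = new_mol(atoms, bonds), origin = origin, offsets = offs)
}

#' Compute a minimal-edit atom-atom mapping
#'
#' Assigns atom maps by exhaustive branch-and-bound search over
#' element-respecting injections of substrate heavy atoms into product heavy
#' atoms, minimizing the number of changed bonds (formed + cleaved +
#' order-changed). Product atoms left unassigned must belong to
#' `incoming_elems`. Deterministic: atoms are explored in canonical rank
#' order and the first optimum found is kept.
#'
#' @param rxn unmapped reaction from [parse_reaction()].
#' @param max_atoms search budget: substrates above this heavy-atom count
#'   are rejected with advice to supply pre-mapped input.
#' @return The reaction with a validated mapping.
#' @export
map_atoms <- function(rxn, max_atoms = 15L) {
  if (rxn$mapped) return(rxn)
  sub <- rxn$substrate
  ns <- n_atoms(sub)
  if (ns > max_atoms) {
    stop("reaction ", rxn$id, ": ", ns, " heavy atoms exceeds the mapping ",
         "budget (", max_atoms, "); supply a pre-mapped reaction SMILES")
  }
  cp <- combined_products(rxn)
  pm <- cp$mol
  np <- n_atoms(pm)

  # element bookkeeping: substrate multiset must embed into products, and
  # any product surplus must be implicit-cosubstrate elements
  st <- table(sub$atoms$elem); pt <- table(pm$atoms$elem)
  for (el in names(st)) {
    if (is.na(pt[el]) || pt[el] < st[[el]]) {
      stop("reaction ", rxn$id, ": substrate atoms of element ", el,
           " cannot all be mapped (element multisets differ)")
    }
  }
  surplus <- character(0)
  for (el in names(pt)) {
    extra <- pt[[el]] - (if (el %in% names(st)) st[[el]] else 0L)
    if (extra > 0L) surplus <- c(surplus, rep(el, extra))
  }
  if (!all(surplus %in% rxn$incoming_elems)) {
    stop("reaction ", rxn$id, ": products gain non-cosubstrate atom(s): ",
         paste(setdiff(surplus, rxn$incoming_elems), collapse = ", "))
  }

  # canonical orders for determinism
  sperm <- canon_graph(paste(sub$atoms$elem, sub$atoms$arom, sub$atoms$charge, sub$atoms$hcount),
                       sub$bonds$a1, sub$bonds$a2, sub$bonds$order)$perm
  pperm <- canon_graph(paste(pm$atoms$elem, pm$atoms$arom, pm$atoms$charge, pm$atoms$hcount),
                       pm$bonds$a1, pm$bonds$a2, pm$bonds$order)$perm

  # substrate exploration order: connectivity-first, canonical tie-break
  sadj <- mol_adj(sub)
  ord <- integer(0); seen <- logical(ns)
  repeat {
    remaining <- which(!seen)
    if (!length(remaining)) break
    nxt <- remaining[which.min(sperm[remaining])]
    queue <- nxt; seen[nxt] <- TRUE
    while (length(queue)) {
      v <- queue[which.min(sperm[queue])]
      queue <- setdiff(queue, v)
      ord <- c(ord, v)
      for (w in sadj$nbr[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }

  sub_key <- paste(sub$bonds$a1, sub$bonds$a2)
  sub_order_of <- function(i, j) {
    k <- match(paste(min(i, j), max(i, j)), sub_key)
    if (is.na(k)) NA_character_ else sub$bonds$order[k]
  }
  pkey <- paste(pm$bonds$a1, pm$bonds$a2)
  p_order_of <- function(i, j) {
    k <- match(paste(min(i, j), max(i, j)), pkey)
    if (is.na(k)) NA_character_ else pm$bonds$order[k]
  }
  padj <- mol_adj(pm)

  best_cost <- Inf; best_assign <- NULL
  assign <- rep(NA_integer_, ns)
  usedp <- logical(np)

  final_cost <- function(partial_cost) {
    # add product bonds touching unassigned (incoming) atoms
    extra <- 0L
    img <- logical(np); img[assign] <- TRUE
    for (k in seq_along(pm$bonds$a1)) {
      if (!img[pm$bonds$a1[k]] || !img[pm$bonds$a2[k]]) extra <- extra + 1L
    }
    partial_cost + extra
  }

  place <- function(step, cost) {
    if (cost >= best_cost) return(invisible(NULL))
    if (step > ns) {
      fc <- final_cost(cost)
      if (fc < best_cost) { best_cost <<- fc; best_assign <<- assign }
      return(invisible(NULL))
    }
    sa <- ord[step]
    cands <- which(pm$atoms$elem == sub$atoms$elem[sa] & !usedp)
    cands <- cands[order(pperm[cands])]
    for (p in cands) {
      # incremental cost: substrate bonds from sa to assigned atoms, plus
      # product bonds from p to already-used images not present in substrate
      dc <- 0L
      ok <- TRUE
      for (idx in seq_along(sadj$nbr[[sa]])) {
        j <- sadj$nbr[[sa]][idx]
        if (is.na(assign[j])) next
        so <- sub$bonds$order[sadj$eid[[sa]][idx]]
        po <- p_order_of(p, assign[j])
        if (is.na(po) || po != so) dc <- dc + 1L   # cleaved or order-changed
      }
      for (idx in seq_along(padj$nbr[[p]])) {
        q <- padj$nbr[[p]][idx]
        if (!usedp[q]) next
        j <- which(assign == q)
        so <- sub_order_of(sa, j)
        if (is.na(so)) dc <- dc + 1L               # formed between mapped atoms
      }
      if (cost + dc >= best_cost) next
      assign[sa] <<- p; usedp[p] <<- TRUE
      place(step + 1L, cost + dc)
      assign[sa] <<- NA_integer_; usedp[p] <<- FALSE
    }
    invisible(NULL)
  }
  place(1L, 0L)
  if (is.null(best_assign)) stop("reaction ", rxn$id, ": no element-respecting mapping found")

  # write maps: substrate numbered by canonical order
  mapno <- integer(ns); mapno[order(sperm)] <- seq_len(ns)
  rxn$substrate$atoms$map <- mapno
  for (pi in seq_along(rxn$products)) rxn$products[[pi]]$atoms$map <- NA_integer_
  for (sa in seq_len(ns)) {
    tgt <- best_assign[sa]
    pi <- cp$origin$prod[tgt]; ai <- cp$origin$atom[tgt]
    rxn$products[[pi]]$atoms$map[ai] <- mapno[sa]
  }
  rxn$mapped <- FALSE
  validate_mapping(rxn)
}

# number of changed bonds for a mapped reaction, counting bonds formed to
# incoming cosubstrate atoms (same objective the mapper minimizes)
n_changed_bonds <- function(rxn) {
  ed <- reaction_edits(rxn)
  nrow(ed$cleaved) + nrow(ed$formed) + nrow(ed$order_changed) +
    nrow(ed$incoming_formed)
}

#' Read a reaction file
#'
#' One reaction SMILES per line; `#` starts a comment; an optional second
#' tab-separated field carries the reaction id (either field order works,
#' the one containing `>>` is taken as the reaction).
#'
#' @param path file path.
#' @param auto_map complete missing atom maps with [map_atoms()].
#' @param incoming_elems passed to [parse_reaction()].
#' @param max_atoms mapping budget for [map_atoms()].
#' @return List of reaction objects.
#' @export
read_reactions <- function(path, auto_map = TRUE, incoming_elems = c("O"),
                           max_atoms = 15L) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (ln in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[ln])
    raw <- trimws(raw)
    if (!nchar(raw)) next
    fields <- strsplit(raw, "\t", fixed = TRUE)[[1]]
    if (length(fields) == 1L) {
      smi <- fields[1]; id <- sprintf("r%04d", ln)
    } else {
      is_rxn <- grepl(">>", fields, fixed = TRUE)
      smi <- fields[is_rxn][1]; id <- fields[!is_rxn][1]
    }
    rxn <- tryCatch(parse_reaction(smi, id = id, incoming_elems = incoming_elems),
                    error = function(e) stop("line ", ln, ": ", conditionMessage(e)))
    if (!rxn$mapped && auto_map) rxn <- map_atoms(rxn, max_atoms = max_atoms)
    out[[length(out) + 1L]] <- rxn
  }
  out
}

#' Write reactions to a file
#'
#' @param rxns list of reaction objects.
#' @param path output path.
#' @export
write_reactions <- function(rxns, path) {
  writeLines(vapply(rxns, function(r) {
    paste(write_reaction_smiles(r), r$id, sep = "\t")
  }, character(1)), path)
}
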