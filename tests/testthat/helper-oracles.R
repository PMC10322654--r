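# Brute-force oracles and shared fixtures for the test suite. The oracles
# are deliberately independent of the implementation paths they check.

# hand-mapped ester hydrolyses sharing one fingerprint
mapped_ester_pair <- function() {
  list(
    parse_reaction(
      "[CH3:1][C:2](=[O:3])[O:4][CH3:5]>>[CH3:1][C:2](=[O:3])O.[OH:4][CH3:5]",
      "e1"),
    parse_reaction(
      paste0("[CH3:1][CH2:6][C:2](=[O:3])[O:4][CH3:5]>>",
             "[CH3:1][CH2:6][C:2](=[O:3])O.[OH:4][CH3:5]"),
      "e2")
  )
}

# all element-respecting injections of substrate atoms into product atoms,
# scored by changed bonds (cleaved + formed + order-changed, bonds touching
# unmapped product atoms included); returns the minimum cost
brute_force_min_edit <- function(rxn) {
  sub <- rxn$substrate
  cp <- ruleminer:::combined_products(rxn)
  pm <- cp$mol
  ns <- ruleminer:::n_atoms(sub)
  np <- ruleminer:::n_atoms(pm)

  bond_order <- function(mol, i, j) {
    k <- which(mol$bonds$a1 == min(i, j) & mol$bonds$a2 == max(i, j))
    if (length(k)) mol$bonds$order[k] else NA_character_
  }
  cost_of <- function(assign) {
    cost <- 0L
    for (b in seq_len(nrow(sub$bonds))) {
      po <- bond_order(pm, assign[sub$bonds$a1[b]], assign[sub$bonds$a2[b]])
      if (is.na(po) || po != sub$bonds$order[b]) cost <- cost + 1L
    }
    img <- logical(np); img[assign] <- TRUE
    for (b in seq_len(nrow(pm$bonds))) {
      i <- pm$bonds$a1[b]; j <- pm$bonds$a2[b]
      if (img[i] && img[j]) {
        so <- bond_order(sub, which(assign == i), which(assign == j))
        if (is.na(so)) cost <- cost + 1L
      } else cost <- cost + 1L
    }
    cost
  }
  best <- Inf
  assign <- rep(NA_integer_, ns)
  used <- logical(np)
  recurse <- function(k) {
    if (k > ns) { best <<- min(best, cost_of(assign)); return(invisible(NULL)) }
    for (p in which(pm$atoms$elem == sub$atoms$elem[k] & !used)) {
      assign[k] <<- p; used[p] <<- TRUE
      recurse(k + 1L)
      assign[k] <<- NA_integer_; used[p] <<- FALSE
    }
    invisible(NULL)
  }
  recurse(1L)
  best
}

# multiset Jaccard by explicit counting (oracle for tanimoto)
brute_tanimoto <- function(a, b) {
  va <- c(paste0("fc|", a$fc, recycle0 = TRUE),
          paste0("bc|", a$bc, recycle0 = TRUE),
          paste0("ce|", a$ce, recycle0 = TRUE))
  vb <- c(paste0("fc|", b$fc, recycle0 = TRUE),
          paste0("bc|", b$bc, recycle0 = TRUE),
          paste0("ce|", b$ce, recycle0 = TRUE))
  if (!length(va) && !length(vb)) return(1.0)
  inter <- 0L
  vb_pool <- vb
  for (x in va) {
    hit <- match(x, vb_pool)
    if (!is.na(hit)) { inter <- inter + 1L; vb_pool <- vb_pool[-hit] }
  }
  inter / (length(va) + length(vb) - inter)
}

random_fp <- function(alphabet = letters[1:6], max_len = 5L) {
  part <- function() sort(sample(alphabet, sample.int(max_len + 1L, 1L) - 1L,
                                 replace = TRUE))
  structure(list(fc = part(), bc = part(), ce = part()), class = "rm_fp")
}

# all set partitions of 1..n (restricted-growth strings)
set_partitions <- function(n) {
  out <- list()
  rec <- function(assign, maxb) {
    k <- length(assign) + 1L
    if (k > n) { out[[length(out) + 1L]] <<- assign; return(invisible(NULL)) }
    for (b in seq_len(maxb + 1L)) rec(c(assign, b), max(maxb, b))
    invisible(NULL)
  }
  rec(integer(0), 0L)
  out
}

# minimal number of legally combinable blocks by exhaustive partitioning
brute_min_simple_rules <- function(records, core) {
  n <- length(records)
  legal <- function(recs) {
    merged <- ruleminer:::combine_records(recs, core)
    length(merged) == 1L
  }
  best <- n
  for (p in set_partitions(n)) {
    ok <- TRUE
    for (b in unique(p)) {
      if (!legal(records[p == b])) { ok <- FALSE; break }
    }
    if (ok) best <- min(best, max(p))
  }
  best
}

# a 60-reaction multi-family corpus for update/equivalence stress tests
sixty_reaction_corpus <- function() {
  esters <- list()
  pools_r1 <- c("", "C", "CC", "CCC", "C(C)C", "CO")
  pools_r2 <- c("", "C", "CC")
  k <- 0
  for (r1 in pools_r1) for (r2 in pools_r2) {
    k <- k + 1
    esters[[k]] <- fx_ester_hydrolysis(r1, r2, sprintf("sx_est_%02d", k))
  }
  amides <- list()
  k <- 0
  for (r1 in c("C", "CC", "CCC")) for (r2 in c("C", "CC", "CCC")) {
    k <- k + 1
    amides[[k]] <- fx_amide_hydrolysis(r1, r2, sprintf("sx_ami_%02d", k))
  }
  aryl <- c("c1ccccc1", "c1ccc(F)cc1", "c1ccc(OC)cc1", "c1cccc(F)c1",
            "c1cccc(OC)c1", "c1ccc(CC)cc1")
  more <- c(
    lapply(1:6, function(i) fx_benzylic_hydroxylation(aryl[i], sprintf("sx_hyd_%02d", i))),
    lapply(1:6, function(i) fx_alcohol_oxidation(aryl[i], "", sprintf("sx_oxi_%02d", i))),
    lapply(1:5, function(i) fx_aromatic_dehalogenation(aryl[i], "Cl", sprintf("sx_dha_%02d", i))),
    lapply(1:4, function(i) {
      fx_aliphatic_dechlorination(c("C", "CC", "CCC", "C(C)C")[i], sprintf("sx_dhl_%02d", i))
    }),
    lapply(1:3, function(i) fx_nitro_reduction(aryl[i], sprintf("sx_nit_%02d", i))),
    lapply(1:6, function(i) fx_aldehyde_oxidation(aryl[i], sprintf("sx_ald_%02d", i))),
    lapply(1:3, function(i) {
      fx_hydrolytic_dechlorination(c("C", "CC", "CCC")[i], sprintf("sx_hdc_%02d", i))
    })
  )
  stopifnot(length(c(esters, amides, more)) == 60L)
  c(esters, amides, more)
}

# canonical description of a group partition (ignores group ids)
partition_key <- function(groups) {
  sort(unname(vapply(groups$groups, function(g) {
    paste(sort(g$member_ids), collapse = ",")
  }, character(1))))
}
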