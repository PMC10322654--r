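test_that("identity reactions have empty centers and fingerprints", {
  r <- parse_reaction("[CH3:1][CH2:2][OH:3]>>[CH3:1][CH2:2][OH:3]", "id")
  ctr <- detect_reaction_center(r)
  expect_length(ctr$atoms, 0)
  fp <- reaction_fingerprint(r, ctr)
  expect_length(ruleminer:::fp_all(fp), 0)
  expect_identical(tanimoto(fp, fp), 1.0)
})

test_that("ester hydrolysis center completes the whole ester group", {
  r <- mapped_ester_pair()[[1]]
  ctr <- detect_reaction_center(r)
  # cleaved acyl C-O plus completed ester: carbonyl C, =O, ester O, O-methyl C
  elems <- sort(r$substrate$atoms$elem[ctr$atoms])
  expect_identical(elems, c("C", "C", "O", "O"))
  expect_true(any(vapply(ctr$completed_groups, function(g) g$name == "ester",
                         logical(1))))
  expect_identical(nrow(ctr$edits$cleaved), 1L)
})

test_that("nitro reduction center contains the whole nitro group", {
  r <- fx_nitro_reduction("c1ccccc1", "n1")
  ctr <- detect_reaction_center(r)
  elems <- sort(r$substrate$atoms$elem[ctr$atoms])
  expect_true(all(c("N", "O", "O") %in% elems))
})

test_that("aromatic and aliphatic dechlorination fingerprints differ", {
  ar <- fx_aromatic_dehalogenation("c1ccccc1", "Cl", "a")
  al <- fx_aliphatic_dechlorination("CC", "b")
  fp_ar <- reaction_fingerprint(ar, detect_reaction_center(ar))
  fp_al <- reaction_fingerprint(al, detect_reaction_center(al))
  expect_lt(tanimoto(fp_ar, fp_al), 1.0)
})

test_that("remote substituents do not change the fingerprint", {
  pair <- mapped_ester_pair()
  fps <- lapply(pair, function(r) {
    reaction_fingerprint(r, detect_reaction_center(r))
  })
  expect_identical(tanimoto(fps[[1]], fps[[2]]), 1.0)
})

test_that("tanimoto definition: identity, disjoint, and 2-of-4 overlap", {
  fp <- function(ce) structure(list(fc = character(0), bc = character(0),
                                    ce = ce), class = "rm_fp")
  a <- fp(c("x", "y", "z")); b <- fp(c("x", "y", "w"))
  expect_identical(tanimoto(a, a), 1.0)
  expect_identical(tanimoto(a, fp(c("q", "r"))), 0.0)
  expect_identical(tanimoto(a, b), 0.5)
  # part-tagged: identical strings in different parts never match
  c1 <- structure(list(fc = "x", bc = character(0), ce = character(0)),
                  class = "rm_fp")
  c2 <- structure(list(fc = character(0), bc = "x", ce = character(0)),
                  class = "rm_fp")
  expect_identical(tanimoto(c1, c2), 0.0)
})

test_that("tanimoto agrees with a brute-force multiset oracle", {
  set.seed(11)
  for (i in 1:300) {
    a <- random_fp(); b <- random_fp()
    expect_equal(tanimoto(a, b), brute_tanimoto(a, b))
  }
})

test_that("clustering partitions reactions, keeps singletons, orders deterministically", {
  rxns <- c(mapped_ester_pair(),
            list(fx_ester_hydrolysis("CCC", "", "e3"),
                 fx_benzylic_hydroxylation("c1ccccc1", "h1"),
                 fx_benzylic_hydroxylation("c1ccc(F)cc1", "h2"),
                 fx_decarboxylation("c1ccccc1", "d1")))
  grps <- cluster_reactions(rxns)
  expect_length(grps$groups, 3L)
  eligible <- vapply(grps$groups, `[[`, logical(1), "eligible")
  expect_identical(sum(eligible), 2L)
  sizes <- sort(unname(vapply(grps$groups, function(g) length(g$member_ids),
                              integer(1))))
  expect_identical(sizes, c(1L, 2L, 3L))
  # every reaction lands in exactly one group
  all_members <- unname(unlist(lapply(grps$groups, `[[`, "member_ids")))
  expect_identical(sort(all_members),
                   sort(vapply(rxns, `[[`, character(1), "id")))
  # input order invariance
  grps2 <- cluster_reactions(rev(rxns))
  expect_identical(partition_key(grps), partition_key(grps2))
  # duplicated ids rejected
  expect_error(cluster_reactions(c(rxns, rxns[1])), "duplicate")
})

test_that("Tanimoto-1.0 grouping equals multiset-equality grouping", {
  rxns <- sixty_reaction_corpus()[1:25]
  grps <- cluster_reactions(rxns)
  fps <- lapply(rxns, function(r) {
    reaction_fingerprint(r, detect_reaction_center(r))
  })
  ids <- vapply(rxns, `[[`, character(1), "id")
  for (i in seq_along(rxns)) for (j in seq_along(rxns)) {
    if (i >= j) next
    same_group <- any(vapply(grps$groups, function(g) {
      all(c(ids[i], ids[j]) %in% g$member_ids)
    }, logical(1)))
    expect_identical(same_group, tanimoto(fps[[i]], fps[[j]]) == 1.0,
                     label = paste(ids[i], ids[j]))
  }
})
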