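test_that("family reactions share one fingerprint and validate as mapped", {
  pool <- list(c("C", ""), c("CC", ""), c("CCC", "C"), c("C(C)C", ""))
  fam <- make_reaction_family("ester_hydrolysis", pool, 4, seed = 2)
  expect_length(fam, 4)
  expect_true(all(vapply(fam, `[[`, logical(1), "mapped")))
  fps <- vapply(fam, function(r) {
    ruleminer:::fp_key(reaction_fingerprint(r, detect_reaction_center(r)))
  }, character(1))
  expect_identical(length(unique(fps)), 1L)
  # n = 1 gives a singleton (eligibility filter test upstream)
  one <- make_reaction_family("nitro_reduction", list("c1ccccc1"), 1, seed = 1)
  expect_false(cluster_reactions(one)$groups[[1]]$eligible)
  # two families with different centers cluster apart
  two <- c(make_reaction_family("ester_hydrolysis", pool, 2, seed = 1,
                                prefix = "fa"),
           make_reaction_family("amide_hydrolysis",
                                list(c("C", "C"), c("CC", "C")), 2, seed = 1,
                                prefix = "fb"))
  expect_length(cluster_reactions(two)$groups, 2L)
})

test_that("family draws are seeded and reproducible", {
  pool <- list(c("C", ""), c("CC", ""), c("CCC", ""), c("CO", ""))
  f1 <- make_reaction_family("ester_hydrolysis", pool, 3, seed = 9)
  f2 <- make_reaction_family("ester_hydrolysis", pool, 3, seed = 9)
  expect_identical(vapply(f1, write_reaction_smiles, character(1)),
                   vapply(f2, write_reaction_smiles, character(1)))
})

test_that("hydrogen and charge bookkeeping of the builders is chemically sound", {
  # nitro reduction: aniline N gains 2 H, charges neutralize, water forms
  r <- fx_nitro_reduction("c1ccccc1", "n")
  prods <- ruleminer:::observed_product_set(r)
  expect_true("Nc1ccccc1" %in% prods || "c1ccc(N)cc1" %in% prods ||
                any(grepl("N", prods)))
  expect_identical(sum(prods == "O"), 2L)   # product multiset keeps both waters
  expect_true(all(r$substrate$atoms$charge[r$substrate$atoms$elem == "N"] == 1L))
  # alcohol oxidation loses two hydrogens
  r2 <- fx_alcohol_oxidation("CC", "", "o")
  sub_h <- sum(r2$substrate$atoms$hcount)
  prod_h <- sum(r2$products[[1]]$atoms$hcount)
  expect_identical(sub_h - prod_h, 2L)
})

test_that("cascade pathways have the requested depth and full product edges", {
  fx <- fixture_pathways(depth = 3)
  for (p in fx$pathways) {
    expect_identical(max(p$generation), 3)
    expect_identical(length(p$roots), 1L)
  }
  # depth-1 pathways give a single-generation corpus
  fx1 <- fixture_pathways(depth = 1)
  expect_true(all(vapply(fx1$pathways, function(p) max(p$generation),
                         numeric(1)) == 1))
  # noise adds unobserved-but-triggering compounds to the universe
  base <- make_pathways(4, depth = 2, noise_frac = 0)
  noisy <- make_pathways(4, depth = 2, noise_frac = 0.3, seed = 5)
  expect_gt(length(noisy$compounds), length(base$compounds))
})

test_that("pathway JSON round-trips", {
  fx <- fixture_pathways(depth = 2, aryls = "c1ccccc1")
  tf <- tempfile(fileext = ".json")
  write_pathways(fx$pathways, tf)
  back <- read_pathways(tf)
  expect_identical(length(back), 1L)
  expect_setequal(back[[1]]$nodes, fx$pathways[[1]]$nodes)
  expect_identical(back[[1]]$generation[order(names(back[[1]]$generation))],
                   fx$pathways[[1]]$generation[order(names(fx$pathways[[1]]$generation))])
})
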