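test_that("parse_reaction validates mappings and shapes", {
  # element conservation is enforced across the mapping
  expect_error(parse_reaction("[CH3:1][OH:2]>>[CH3:1][NH2:2]", "bad"),
               "element")
  # absent maps give an unmapped reaction
  u <- parse_reaction("CCO>>CC=O", "u")
  expect_false(u$mapped)
  # an explicit 4-atom bijection is accepted
  m <- parse_reaction("[C:1](=[O:2])[O:3][C:4]>>[C:1](=[O:2])[O:3].[C:4]", "m")
  expect_true(m$mapped)
  expect_identical(sort(m$substrate$atoms$map), 1:4)
  # multi-component substrates are rejected
  expect_error(parse_reaction("CC.O>>CCO", "two"), "component")
  # unmapped product atoms must be cosubstrate elements
  expect_error(parse_reaction("[CH3:1][CH3:2]>>[CH3:1][CH2:2]N", "gainN"),
               "cosubstrate")
})

test_that("map_atoms finds minimal-edit mappings (brute-force oracle)", {
  cases <- c("CCO>>CCO",                       # identity: 0 edits
             "CC(=O)OC>>CC(=O)O.CO",           # ester hydrolysis
             "CCCl>>CC.Cl",                    # dechlorination
             "CC(O)C>>CC(=O)C",                # oxidation
             "NCC>>CC.N")
  for (s in cases) {
    r <- map_atoms(parse_reaction(s, s))
    expect_true(r$mapped, label = s)
    expect_equal(ruleminer:::n_changed_bonds(r), brute_force_min_edit(r),
                     label = s)
  }
  ident <- map_atoms(parse_reaction("CCO>>CCO", "id"))
  expect_identical(ruleminer:::n_changed_bonds(ident), 0L)
})

test_that("map_atoms is invariant under atom-order permutation", {
  variants <- c("CC(=O)OC>>CC(=O)O.CO",
                "COC(C)=O>>CO.CC(=O)O",
                "O=C(C)OC>>OC.OC(C)=O")
  mapped <- lapply(variants, function(s) map_atoms(parse_reaction(s, s)))
  costs <- vapply(mapped, ruleminer:::n_changed_bonds, integer(1))
  expect_true(all(costs == costs[1]))
  fps <- vapply(mapped, function(r) {
    ruleminer:::fp_key(reaction_fingerprint(r, detect_reaction_center(r)))
  }, character(1))
  expect_true(all(fps == fps[1]))
})

test_that("map_atoms rejects unmappable and oversized reactions", {
  # toluene -> benzyl alcohol gains an O: fine (cosubstrate), but gaining N is not
  expect_error(map_atoms(parse_reaction("CC>>CN", "gain")), "mapped|cosubstrate")
  expect_error(map_atoms(parse_reaction("CCCCCCCCCCCCCCCC>>CCCCCCCCCCCCCCCC", "big")),
               "budget|pre-mapped")
})

test_that("reaction files round-trip with ids and comments", {
  rxns <- mapped_ester_pair()
  tf <- tempfile(fileext = ".tsv")
  write_reactions(rxns, tf)
  cat("# a comment line\n", file = tf, append = TRUE)
  back <- read_reactions(tf)
  expect_identical(length(back), 2L)
  expect_identical(vapply(back, `[[`, character(1), "id"), c("e1", "e2"))
  expect_identical(write_reaction_smiles(back[[1]]), write_reaction_smiles(rxns[[1]]))
})
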