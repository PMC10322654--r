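# helpers to build amide families exercising the Fig-2-style combination
# cases; substituent pairs are chosen to differ (or not) within two bonds
# of the reaction center
amide_group <- function(pairs, prefix = "am") {
  rxns <- lapply(seq_along(pairs), function(i) {
    fx_amide_hydrolysis(pairs[[i]][1], pairs[[i]][2], sprintf("%s_%02d", prefix, i))
  })
  cluster_reactions(rxns)
}

n_simple_rules_at <- function(grps, d) {
  gid <- names(grps$groups)[1]
  core <- ruleminer:::build_group_core(grps, gid)
  rule <- ruleminer:::build_composite(core, grps, d, 0L)
  length(rule$simples)
}

test_that("substituent graphs combine unless unobserved co-occurrences arise", {
  # both substituent positions identical within the horizon: one rule
  expect_identical(n_simple_rules_at(
    amide_group(list(c("CCCC", "CC"), c("CCCCC", "CC"))), 2L), 1L)
  # one position varies: cross-combinations are all observed, one rule
  expect_identical(n_simple_rules_at(
    amide_group(list(c("C", "CC"), c("C", "C(C)C"))), 2L), 1L)
  expect_identical(n_simple_rules_at(
    amide_group(list(c("CC", "C"), c("C(C)C", "C"))), 2L), 1L)
  # both positions vary: merging would invent unobserved combinations,
  # so two simple rules remain
  expect_identical(n_simple_rules_at(
    amide_group(list(c("C", "CC"), c("CCC", "C(C)C"))), 2L), 2L)
})

test_that("greedy combination is optimal on small groups (brute-force partitions)", {
  cases <- list(
    list(c("C", "CC"), c("CCC", "C(C)C"), c("C", "C(C)C")),
    list(c("C", "C"), c("CC", "C"), c("CCC", "C"), c("C", "CC")),
    list(c("C", "CC"), c("CCC", "C(C)C"), c("CCCC", "CO"), c("C", "C(C)C")),
    list(c("C", "C"), c("CC", "CC"), c("CCC", "CCC"))
  )
  for (ci in seq_along(cases)) {
    grps <- amide_group(cases[[ci]], prefix = sprintf("bf%d", ci))
    gid <- names(grps$groups)[1]
    core <- ruleminer:::build_group_core(grps, gid)
    records <- ruleminer:::member_records(core, grps, 2L)
    greedy <- length(ruleminer:::combine_records(records, core))
    optimal <- brute_min_simple_rules(records, core)
    expect_identical(greedy, optimal, label = sprintf("case %d", ci))
  }
})

test_that("diameter semantics: bare center at d=0, exact molecule at saturation", {
  pair <- mapped_ester_pair()
  grps <- cluster_reactions(pair)
  gid <- names(grps$groups)[1]
  core <- ruleminer:::build_group_core(grps, gid)
  r0 <- ruleminer:::build_composite(core, grps, 0L, 0L)
  # d=0 triggers on any ester regardless of substituents
  expect_length(apply_rule(r0, "CCCCCC(=O)OCCC"), 1L)
  # saturating diameter (largest member eccentricity + 1): only the exact
  # member substrates trigger
  rsat <- ruleminer:::build_composite(core, grps, 3L, 0L)
  expect_length(apply_rule(rsat, "CC(=O)OC"), 1L)
  expect_length(apply_rule(rsat, "CCCC(=O)OC"), 0L)
  expect_length(apply_rule(rsat, "CCCCCC(=O)OCCC"), 0L)
})

test_that("coverage is conserved across every tuning state", {
  grps <- cluster_reactions(sixty_reaction_corpus()[c(1:6, 19:22)])
  for (gid in names(grps$groups)) {
    if (!grps$groups[[gid]]$eligible) next
    core <- ruleminer:::build_group_core(grps, gid)
    states <- ruleminer:::state_path(core, grps)
    for (st in states) {
      rule <- ruleminer:::build_composite(core, grps, st[["d"]], st[["h"]])
      for (id in core$member_ids) {
        expect_true(rule_covers(rule, grps$reactions[[id]]),
                    label = sprintf("%s d=%d h=%d %s", gid, st[["d"]], st[["h"]], id))
      }
    }
  }
})

test_that("genericity follows the NS/PS definition with sentinels", {
  gf <- genericity_fixture()
  grps <- cluster_reactions(gf$reactions)
  gid <- names(grps$groups)[1]
  core <- ruleminer:::build_group_core(grps, gid)
  rule <- ruleminer:::build_composite(core, grps, 0L, 0L)
  g <- compute_genericity(rule, gf$compounds, gf$reactions)
  expect_identical(g$ps, 2L)
  expect_identical(g$ns, 16L)
  expect_identical(g$value, 8)
  # no negatives -> 0
  g2 <- compute_genericity(rule, gf$compounds[1:2], gf$reactions)
  expect_identical(g2$value, 0)
  # trigger without any positive -> Inf
  g3 <- compute_genericity(rule, gf$compounds[11:14], gf$reactions)
  expect_identical(g3$value, Inf)
  # never triggers -> undefined
  g4 <- compute_genericity(rule, "c1ccccc1", gf$reactions)
  expect_true(is.nan(g4$value))
})

test_that("tuning selects the state closest to the target genericity", {
  gf <- genericity_fixture()
  grps <- cluster_reactions(gf$reactions)
  gid <- names(grps$groups)[1]
  rule <- tune_genericity(grps, gid, 5, gf$compounds, gf$reactions)
  tr <- attr(rule, "trace")
  expect_identical(tr$genericity[tr$d == 0 & tr$h == 0], 8)
  expect_identical(tr$genericity[tr$d == 1 & tr$h == 0], 4)
  expect_identical(tr$genericity[tr$d == 2 & tr$h == 0], 1)
  expect_identical(rule$d, 1L)
  # limit cases: very large target -> most generic; target 0 -> genericity 0..1
  expect_identical(tune_genericity(grps, gid, 1e6, gf$compounds, gf$reactions)$d, 0L)
  spec <- tune_genericity(grps, gid, 0, gf$compounds, gf$reactions)
  expect_identical(spec$genericity, 0)   # exact-match state has no negatives
  expect_identical(spec$d, 3L)
})

test_that("trigger sets shrink monotonically with diameter and explicit H", {
  pair <- c(mapped_ester_pair(), list(fx_ester_hydrolysis("C(C)C", "", "e3")))
  grps <- cluster_reactions(pair)
  gid <- names(grps$groups)[1]
  core <- ruleminer:::build_group_core(grps, gid)
  compounds <- compound_universe(60)
  trigger_set <- function(d, h) {
    rule <- ruleminer:::build_composite(core, grps, d, h)
    compounds[vapply(compounds, function(s) length(apply_rule(rule, s)) > 0,
                     logical(1))]
  }
  prev_d <- NULL
  for (d in 0:2) {
    cur <- trigger_set(d, 0L)
    if (!is.null(prev_d)) expect_true(all(cur %in% prev_d), label = paste("d", d))
    prev_d <- cur
    prev_h <- cur
    for (h in 1:3) {
      cur_h <- trigger_set(d, h)
      expect_true(all(cur_h %in% prev_h), label = paste("d", d, "h", h))
      prev_h <- cur_h
    }
  }
})

test_that("emitted SMIRKS parse and reproduce the source reactions", {
  grps <- cluster_reactions(c(
    mapped_ester_pair(),
    list(fx_nitro_reduction("c1ccccc1", "n1"),
         fx_nitro_reduction("c1ccc(F)cc1", "n2"),
         fx_benzylic_hydroxylation("c1ccccc1", "h1"),
         fx_benzylic_hydroxylation("c1ccc(F)cc1", "h2"))))
  subs <- vapply(unname(grps$reactions), function(r) mol_signature(r$substrate),
                 character(1))
  rs <- generate_ruleset(grps, 0, subs, unname(grps$reactions))
  for (gid in names(rs$rules)) {
    sm <- emit_smirks(rs$rules[[gid]], rs$groups)
    expect_true(all(nchar(sm) > 0))
    for (id in grps$groups[[gid]]$member_ids) {
      rxn <- grps$reactions[[id]]
      obs <- ruleminer:::observed_product_set(rxn)
      hit <- FALSE
      for (s in sm) {
        sets <- apply_smirks(s, rxn$substrate)
        if (any(vapply(sets, identical, logical(1), y = obs))) hit <- TRUE
      }
      expect_true(hit, label = paste(gid, id))
    }
  }
})

test_that("singleton groups are refused unless explicitly allowed", {
  grps <- cluster_reactions(list(fx_decarboxylation("c1ccccc1", "d1")))
  gid <- names(grps$groups)[1]
  expect_error(tune_genericity(grps, gid, 0, "c1ccccc1", list()), "eligible")
  rule <- tune_genericity(grps, gid, 0,
                          mol_signature(grps$reactions[[1]]$substrate),
                          unname(grps$reactions), allow_singleton = TRUE)
  expect_true(rule_covers(rule, grps$reactions[[1]]))
})
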