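make_base_ruleset <- function(rxns, compounds = NULL, target = 0) {
  grps <- cluster_reactions(rxns)
  if (is.null(compounds)) {
    compounds <- vapply(rxns, function(r) mol_signature(r$substrate), character(1))
  }
  generate_ruleset(grps, target, compounds, rxns)
}

test_that("fingerprint-identical reactions extend their group without new rules", {
  base <- mapped_ester_pair()
  rs <- make_base_ruleset(base)
  new <- list(fx_ester_hydrolysis("CCC", "", "e_new"))
  universe <- c(vapply(c(base, new), function(r) mol_signature(r$substrate),
                       character(1)))
  upd <- add_reactions(rs, new, universe, c(base, new))
  gid <- names(upd$ruleset$rules)[1]
  expect_identical(length(upd$ruleset$groups$groups[[gid]]$member_ids), 3L)
  expect_length(upd$report$rules_created, 0)
  expect_length(upd$report$groups_new, 0)
  expect_true(all(coverage(upd$ruleset, c(base, new))$uncovered == character(0)))
})

test_that("novel centers found new singleton groups without rules", {
  base <- mapped_ester_pair()
  rs <- make_base_ruleset(base)
  new <- list(fx_nitro_reduction("c1ccccc1", "n_new"))
  universe <- vapply(c(base, new), function(r) mol_signature(r$substrate),
                     character(1))
  upd <- add_reactions(rs, new, universe, c(base, new))
  expect_length(upd$report$groups_new, 1)
  expect_length(upd$report$rules_created, 0)
  gnew <- upd$report$groups_new
  expect_false(upd$ruleset$groups$groups[[gnew]]$eligible)
  # the novel reaction stays uncovered until a second member arrives
  expect_identical(coverage(upd$ruleset, c(base, new))$uncovered, "n_new")
  # a second member makes the group eligible and creates its rule
  new2 <- list(fx_nitro_reduction("c1ccc(F)cc1", "n_new2"))
  universe2 <- c(universe, mol_signature(new2[[1]]$substrate))
  upd2 <- add_reactions(upd$ruleset, new2, universe2, c(base, new, new2))
  expect_identical(upd2$report$groups_newly_eligible, gnew)
  expect_identical(upd2$report$rules_created, gnew)
  expect_length(coverage(upd2$ruleset, c(base, new, new2))$uncovered, 0)
})

test_that("unseen substituents extend a rule's options on update", {
  base <- list(fx_amide_hydrolysis("C", "C", "a1"),
               fx_amide_hydrolysis("C", "CC", "a2"))
  new <- list(fx_amide_hydrolysis("C", "C(C)C", "a3"))
  nsub <- mol_signature(new[[1]]$substrate)
  grps <- cluster_reactions(base)
  # the future substrate sits in the universe as a negative sample, so
  # target-0 tuning makes the rule specific enough to exclude it
  universe <- c(vapply(base, function(r) mol_signature(r$substrate), character(1)),
                nsub)
  rs <- generate_ruleset(grps, 0, universe, base)
  expect_length(apply_rule(rs$rules[[1]], nsub), 0)
  upd <- add_reactions(rs, new, universe, c(base, new))
  expect_identical(upd$report$rules_changed, names(rs$rules)[1])
  expect_gt(length(apply_rule(upd$ruleset$rules[[1]], nsub)), 0)
})

test_that("updates never shrink coverage and never touch unrelated rules", {
  rxns <- sixty_reaction_corpus()
  a <- rxns[1:40]; b <- rxns[41:60]
  universe <- vapply(rxns, function(r) mol_signature(r$substrate), character(1))
  rs <- make_base_ruleset(a, universe)
  cov_before <- coverage(rs, a)
  upd <- add_reactions(rs, b, universe, rxns)
  cov_after <- coverage(upd$ruleset, a)
  expect_true(all(cov_before$covered %in% cov_after$covered))
  untouched <- setdiff(names(rs$rules), upd$report$groups_touched)
  for (gid in untouched) {
    expect_identical(ruleminer:::strip_rule(rs$rules[[gid]]),
                     ruleminer:::strip_rule(upd$ruleset$rules[[gid]]))
  }
})

test_that("incremental updating equals batch clustering and generation", {
  rxns <- sixty_reaction_corpus()[1:36]
  universe <- vapply(rxns, function(r) mol_signature(r$substrate), character(1))
  obs <- rxns
  batch_all <- cluster_reactions(rxns)
  rs_all <- generate_ruleset(batch_all, 0, universe, obs)
  set.seed(91)
  for (split in 1:4) {
    sel <- sample(length(rxns), 24)
    a <- rxns[sel]; b <- rxns[-sel]
    rs_a <- generate_ruleset(cluster_reactions(a), 0, universe, obs)
    upd <- add_reactions(rs_a, b, universe, obs)
    expect_identical(partition_key(upd$ruleset$groups), partition_key(batch_all))
    # rules match up to group ids: compare by member-set key
    key_of <- function(rs) {
      ks <- vapply(names(rs$rules), function(gid) {
        paste(sort(rs$groups$groups[[gid]]$member_ids), collapse = ",")
      }, character(1))
      stats::setNames(names(rs$rules), ks)
    }
    ka <- key_of(upd$ruleset); kb <- key_of(rs_all)
    expect_setequal(names(ka), names(kb))
    for (k in names(ka)) {
      expect_identical(ruleminer:::strip_rule(upd$ruleset$rules[[ka[[k]]]]),
                       ruleminer:::strip_rule(rs_all$rules[[kb[[k]]]]),
                       label = k)
    }
  }
})

test_that("unmappable reactions are skipped with a warning and reported", {
  base <- mapped_ester_pair()
  rs <- make_base_ruleset(base)
  bad <- parse_reaction("CC>>CN", "bad1")   # gains nitrogen: unmappable
  universe <- vapply(base, function(r) mol_signature(r$substrate), character(1))
  expect_warning(
    upd <- add_reactions(rs, list(bad), universe, base),
    "skipping"
  )
  expect_identical(upd$report$reactions_skipped, "bad1")
  expect_identical(upd$report$reactions_added, 0L)
})
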