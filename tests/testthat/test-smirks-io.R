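test_that("rule sets persist to JSON and reconstruct identically", {
  fc <- fixture_corpus(singleton = TRUE)
  grps <- cluster_reactions(fc$reactions)
  rs <- generate_ruleset(grps, 0, fc$compounds, fc$reactions)
  tf <- tempfile(fileext = ".json")
  write_ruleset(rs, tf)
  rs2 <- read_ruleset(tf)
  expect_identical(names(rs2$rules), names(rs$rules))
  expect_identical(rs2$config$target_genericity, rs$config$target_genericity)
  for (gid in names(rs$rules)) {
    expect_identical(ruleminer:::strip_rule(rs2$rules[[gid]]),
                     ruleminer:::strip_rule(rs$rules[[gid]]), label = gid)
  }
  # singleton groups and their fingerprints survive persistence
  expect_identical(partition_key(rs2$groups), partition_key(rs$groups))
})

test_that("textual SMIRKS application handles edits, charges and new atoms", {
  # nitro reduction written as a textual rule
  out <- apply_smirks("[c:1][N+:2](=[O:3])[O-:4]>>[c:1][N:2].[O:3].[O:4]",
                      "[O-][N+](=O)c1ccccc1")
  expect_true(any(vapply(out, function(s) "Nc1ccccc1" %in% s, logical(1))))
  # ester hydrolysis with an incoming hydroxyl oxygen
  out2 <- apply_smirks("[C:1](=[O:2])-[O:3][C:4]>>[C:1](=[O:2])O.[O:3][C:4]",
                       "CC(=O)OC")
  expect_true(any(vapply(out2, function(s) {
    identical(s, sort(c(write_smiles(parse_smiles("CC(=O)O")),
                        write_smiles(parse_smiles("CO")))))
  }, logical(1))))
  # no match: empty result
  expect_length(apply_smirks("[C:1]Cl>>[C:1]O", "CCO"), 0)
})

test_that("exported rule files read back and apply", {
  grps <- cluster_reactions(mapped_ester_pair())
  subs <- vapply(unname(grps$reactions), function(r) mol_signature(r$substrate),
                 character(1))
  rs <- generate_ruleset(grps, 10, subs, unname(grps$reactions))
  tf <- tempfile(fileext = ".txt")
  export_rules(rs, tf)
  rules <- read_rule_file(tf)
  expect_gte(length(rules), 1)
  out <- apply_smirks(rules[[1]], "CC(=O)OC")
  expect_gte(length(out), 1)
})

test_that("the command-line interface drives the core workflow", {
  tmp <- tempfile("clirun")
  dir.create(tmp)
  rxfile <- file.path(tmp, "reactions.tsv")
  write_reactions(mapped_ester_pair(), rxfile)
  groups_json <- file.path(tmp, "groups.json")
  rules_json <- file.path(tmp, "rules.json")
  rules_txt <- file.path(tmp, "rules.txt")

  expect_invisible(rm_cli(c("cluster", "--reactions", rxfile,
                            "--out", groups_json)))
  expect_true(file.exists(groups_json))
  rm_cli(c("generate", "--groups", groups_json, "--target-genericity", "0",
           "--out", rules_json))
  rs <- read_ruleset(rules_json)
  expect_length(rs$rules, 1)
  out <- capture.output(rm_cli(c("apply", "--ruleset", rules_json,
                                 "--compound", "CC(=O)OC")))
  expect_true(any(grepl("\t", out)))
  rm_cli(c("export", "--ruleset", rules_json, "--out", rules_txt))
  expect_gte(length(readLines(rules_txt)), 1)
  out2 <- capture.output(rm_cli(c("coverage", "--ruleset", rules_json,
                                  "--reactions", rxfile)))
  expect_length(out2, 0)   # everything covered, nothing listed
})
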