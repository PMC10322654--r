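# shared toy objects for the pathway-level checks: observed A -> B -> C,
# rules for hydrolytic dechlorination and alcohol oxidation, and a model
# that predicts the detour A -> X -> C through an unobserved intermediate
toy_world <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    rxns <- list(
      fx_hydrolytic_dechlorination("CO", "toyAB"),   # A -> B (+ HCl)
      fx_alcohol_oxidation("CO", "", "toyBC"),       # B -> C
      fx_alcohol_oxidation("CCl", "", "toyAX"),      # A -> X
      fx_hydrolytic_dechlorination("C=O", "toyXC")   # X -> C (+ HCl)
    )
    grps <- cluster_reactions(rxns)
    subs <- vapply(rxns, function(r) mol_signature(r$substrate), character(1))
    rs <- generate_ruleset(grps, 0, subs, rxns)
    A <- mol_signature(rxns[[1]]$substrate)
    oxid <- names(rs$rules)[vapply(names(rs$rules), function(g) {
      "toyAX" %in% grps$groups[[g]]$member_ids
    }, logical(1))]
    dech <- names(rs$rules)[vapply(names(rs$rules), function(g) {
      "toyXC" %in% grps$groups[[g]]$member_ids
    }, logical(1))]
    X <- apply_rule(rs$rules[[oxid]], A)[[1]][1]
    cache <<- list(rxns = rxns, rs = rs, A = A, X = X, oxid = oxid, dech = dech)
    cache
  }
})

test_that("precision and recall follow their definitions", {
  ev <- ruleminer:::new_eval_report(0.5, tp = 3, fp = 1, fn = 1)
  expect_identical(ev$precision, 0.75)
  expect_identical(ev$recall, 0.75)
  # no predictions at all: precision 1 by convention, recall 0, AUC 0
  ev0 <- ruleminer:::new_eval_report(c(0, 0.5, 1), tp = c(0, 0, 0),
                                     fp = c(0, 0, 0), fn = c(2, 2, 2))
  expect_true(all(ev0$precision == 1))
  expect_true(all(ev0$recall == 0))
  expect_identical(ev0$auc, 0)
})

test_that("an oracle model yields a perfect precision-recall curve", {
  fc <- fixture_corpus(singleton = FALSE)
  grps <- cluster_reactions(fc$reactions)
  rs <- generate_ruleset(grps, 0, fc$compounds, fc$reactions)
  ev <- single_gen(oracle_model(fc$reactions), rs, fc$reactions)
  expect_true(all(ev$precision == 1))
  expect_true(all(ev$recall == 1))
  expect_identical(ev$auc, 1)
})

test_that("the 2-generation intermediate-credit toy matches the hand computation", {
  tw <- toy_world()
  mdl <- table_model(data.frame(compound = c(tw$A, tw$X),
                                rule = c(tw$oxid, tw$dech), prob = 1))
  pw <- pathway_graph("toy", list(
    list(parent = tw$A, children = list("OCCO")),
    list(parent = "OCCO", children = list("OCC=O"))))
  ev <- multi_gen(mdl, tw$rs, list(pw), thresholds = 0.5, gen_weight = 0.5)
  # C matched at generation 2 (weight 0.5); B missed at generation 1
  # (weight 1); X and the HCl co-product are exempt from FP
  expect_identical(ev$tp, 0.5)
  expect_identical(ev$fn, 1)
  expect_identical(ev$fp, 0)
  expect_identical(ev$precision, 1)
  expect_equal(ev$recall, 1 / 3)
  # disabling the intermediate exemption punishes X
  ev2 <- multi_gen(mdl, tw$rs, list(pw), thresholds = 0.5, gen_weight = 0.5,
                   exempt_intermediates = FALSE)
  expect_identical(ev2$fp, 1)   # X at generation 1 (HCl still co-product-exempt)
})

test_that("co-products of correct products are not false positives", {
  tw <- toy_world()
  # dechlorination of A itself: products B (observed) + HCl (co-product)
  mdl <- table_model(data.frame(compound = tw$A, rule = tw$dech, prob = 1))
  pw <- pathway_graph("cop", list(list(parent = tw$A, children = list("OCCO"))))
  ev <- multi_gen(mdl, tw$rs, list(pw), thresholds = 0.5)
  expect_identical(ev$fp, 0)
  ev2 <- multi_gen(mdl, tw$rs, list(pw), thresholds = 0.5,
                   exempt_coproducts = FALSE)
  expect_identical(ev2$fp, 1)
})

test_that("multi-gen on depth-1 pathways with weight 1 reduces to single-gen", {
  tw <- toy_world()
  om <- oracle_model(tw$rxns)
  rA <- tw$rxns[[1]]
  pw <- pathway_graph("d1", list(list(
    parent = tw$A,
    children = as.list(ruleminer:::observed_product_set(rA)))))
  ev_m <- multi_gen(om, tw$rs, list(pw), gen_weight = 1,
                    exempt_intermediates = FALSE, exempt_coproducts = FALSE)
  ev_s <- single_gen(om, tw$rs, list(rA))
  expect_equal(ev_m$tp, ev_s$tp)
  expect_equal(ev_m$fp, ev_s$fp)
  expect_equal(ev_m$fn, ev_s$fn)
  expect_equal(ev_m$auc, ev_s$auc)
})

test_that("weighted TP + FN equals the total weighted observed nodes", {
  fx <- fixture_pathways(depth = 3)
  grps <- cluster_reactions(fx$reactions)
  rs <- generate_ruleset(grps, 0, fx$compounds, fx$reactions)
  w <- 0.5
  total <- sum(vapply(fx$pathways, function(p) {
    obs <- setdiff(p$nodes, p$roots)
    sum(w^(p$generation[obs] - 1))
  }, numeric(1)))
  for (model in list(oracle_model(fx$reactions), random_model(4))) {
    ev <- multi_gen(model, rs, fx$pathways, thresholds = c(0, 0.4, 0.9),
                    gen_weight = w)
    expect_equal(ev$tp + ev$fn, rep(total, 3))
  }
})

test_that("cyclic pathways are rejected", {
  expect_error(pathway_graph("cyc", list(
    list(parent = "CCO", children = list("CC=O")),
    list(parent = "CC=O", children = list("CCO")))), "cyclic")
})

test_that("repeated splits are seeded and reproducible", {
  fc <- fixture_corpus(singleton = FALSE)
  grps <- cluster_reactions(fc$reactions)
  rs <- generate_ruleset(grps, 0, fc$compounds, fc$reactions)
  e1 <- repeated_split_eval(rs, fc$reactions, reps = 2, seed = 3, n_chains = 2)
  e2 <- repeated_split_eval(rs, fc$reactions, reps = 2, seed = 3, n_chains = 2)
  expect_identical(e1$rep_aucs, e2$rep_aucs)
  expect_error(repeated_split_eval(rs, fc$reactions, train_frac = 1.2), "train_frac")
})

test_that("a random-probability model scores near the triggered-positive rate", {
  fc <- fixture_corpus(noise = TRUE, singleton = FALSE)
  grps <- cluster_reactions(fc$reactions)
  rs <- generate_ruleset(grps, 0, fc$compounds, fc$reactions)
  aucs <- vapply(1:10, function(s) {
    single_gen(random_model(s), rs, fc$reactions)$auc
  }, numeric(1))
  # the curve interpolates between perfect coverage at threshold 0 and
  # nothing at threshold 1; its area stays in a broad but informative band
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 1)
})
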