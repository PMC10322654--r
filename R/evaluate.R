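# Prediction performance evaluation. Single-gen works at reaction level:
# predicted transformation products of each test substrate are compared
# with the documented ones over a probability-threshold sweep, giving
# precision = TP/(TP+FP) and recall = TP/(TP+FN), where FN counts only
# documented products that were not predicted. Multi-gen evaluates whole
# pathways breadth-first from the root compounds, discounting deeper
# generations and exempting productive intermediates and co-products from
# the false-positive count. AUC is the area under the precision-recall
# curve by the trapezoidal rule.

default_thresholds <- function() seq(0, 1, length.out = 101L)

pr_auc <- function(recall, precision) {
  ord <- order(recall, precision)
  r <- recall[ord]; p <- precision[ord]
  # anchor the curve at recall 0 with the precision of its strictest point
  r <- c(0, r); p <- c(p[1L], p)
  sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

new_eval_report <- function(thresholds, tp, fp, fn, reps = 1L) {
  precision <- ifelse(tp + fp == 0, 1.0, tp / (tp + fp))
  recall <- ifelse(tp + fn == 0, 0.0, tp / (tp + fn))
  structure(list(thresholds = thresholds, precision = precision,
                 recall = recall, tp = tp, fp = fp, fn = fn,
                 auc = pr_auc(recall, precision), reps = reps),
            class = "rm_eval")
}

#' @export
print.rm_eval <- function(x, ...) {
  cat("<evaluation report> ", length(x$thresholds), " thresholds, AUC ",
      round(x$auc, 4), if (x$reps > 1L) paste0(" (mean of ", x$reps, " reps)"),
      "\n", sep = "")
  invisible(x)
}

#' Single-generation (reaction-level) evaluation
#'
#' For each threshold, the products of every rule with predicted
#' probability at or above the threshold are collected per test substrate
#' and compared - as canonical-form sets - with the documented products of
#' that substrate.
#'
#' @param model model for [predict_rule_probs()].
#' @param rs rule set.
#' @param test_rxns held-out reactions.
#' @param thresholds descending or ascending probability grid.
#' @return Evaluation report with per-threshold precision/recall and AUC.
#' @export
single_gen <- function(model, rs, test_rxns, thresholds = default_thresholds()) {
  obs_idx <- observed_index(test_rxns)
  subs <- names(obs_idx)
  probs <- predict_rule_probs(model, rs, subs)
  mols <- as_compound_list(subs)

  # per substrate and rule: flattened predicted products
  rule_products <- lapply(seq_along(subs), function(i) {
    lapply(names(rs$rules), function(gid) {
      sets <- apply_rule_cached(rs$rules[[gid]], mols[[subs[i]]], subs[i])
      unique(unlist(sets))
    })
  })
  observed_prods <- lapply(subs, function(s) unique(unlist(obs_idx[[s]])))

  tp <- fp <- fn <- numeric(length(thresholds))
  for (ti in seq_along(thresholds)) {
    t <- thresholds[ti]
    for (i in seq_along(subs)) {
      on <- which(probs[i, ] >= t)
      pred <- unique(unlist(rule_products[[i]][on]))
      obs <- observed_prods[[i]]
      tp[ti] <- tp[ti] + length(intersect(pred, obs))
      fp[ti] <- fp[ti] + length(setdiff(pred, obs))
      fn[ti] <- fn[ti] + length(setdiff(obs, pred))
    }
  }
  new_eval_report(thresholds, tp, fp, fn)
}

# breadth-first pathway prediction from the roots at one threshold
predict_pathway <- function(probs_of, rs, pw, threshold) {
  gmax <- max(pw$generation)
  node_gen <- stats::setNames(rep(0L, length(pw$roots)), pw$roots)
  apps <- list()        # (parent, products) applications
  frontier <- pw$roots
  gen <- 0L
  while (length(frontier) && gen < gmax) {
    gen <- gen + 1L
    nxt <- character(0)
    for (parent in frontier) {
      pr <- probs_of(parent)
      pmol <- parse_smiles(parent)
      for (gid in names(rs$rules)) {
        if (pr[[gid]] < threshold) next
        sets <- apply_rule_cached(rs$rules[[gid]], pmol, parent)
        for (s in sets) {
          apps[[length(apps) + 1L]] <- list(parent = parent, products = s)
          for (child in s) {
            if (!child %in% names(node_gen)) {
              node_gen[child] <- gen
              nxt <- c(nxt, child)
            }
          }
        }
      }
    }
    frontier <- unique(nxt)
  }
  list(node_gen = node_gen, apps = apps)
}

#' Multi-generation (pathway-level) evaluation
#'
#' Pathways are predicted breadth-first from their roots, expanding every
#' predicted compound whose rule probability meets the threshold, down to
#' the deepest observed generation. A compound at generation g contributes
#' weight `gen_weight^(g-1)`. Unobserved intermediates leading to a
#' correctly predicted downstream product, and unobserved co-products
#' formed by a reaction that also yields a correct product, are not counted
#' as false positives (both exemptions can be disabled).
#'
#' @param model model for [predict_rule_probs()].
#' @param rs rule set.
#' @param pathways list of pathway objects.
#' @param thresholds probability grid.
#' @param gen_weight per-generation weight decay in (0, 1].
#' @param exempt_intermediates exempt productive intermediates from FP.
#' @param exempt_coproducts exempt co-products of correct products from FP.
#' @return Evaluation report.
#' @export
multi_gen <- function(model, rs, pathways, thresholds = default_thresholds(),
                      gen_weight = 0.5, exempt_intermediates = TRUE,
                      exempt_coproducts = TRUE) {
  # probability cache over all compounds that can appear
  prob_cache <- new.env(parent = emptyenv())
  probs_of <- function(sig) {
    hit <- prob_cache[[sig]]
    if (!is.null(hit)) return(hit)
    pm <- predict_rule_probs(model, rs, sig)
    p <- stats::setNames(as.numeric(pm[1L, ]), colnames(pm))
    prob_cache[[sig]] <- p
    p
  }

  tp <- fp <- fn <- numeric(length(thresholds))
  for (pw in pathways) {
    obs_gen <- pw$generation
    obs_nodes <- setdiff(pw$nodes, pw$roots)
    for (ti in seq_along(thresholds)) {
      pred <- predict_pathway(probs_of, rs, pw, thresholds[ti])
      pred_nodes <- setdiff(names(pred$node_gen), pw$roots)
      matched <- intersect(pred_nodes, obs_nodes)
      tp[ti] <- tp[ti] + sum(gen_weight^(obs_gen[matched] - 1))
      fn[ti] <- fn[ti] + sum(gen_weight^(obs_gen[setdiff(obs_nodes, matched)] - 1))

      unmatched <- setdiff(pred_nodes, obs_nodes)
      if (length(unmatched)) {
        exempt <- character(0)
        if (exempt_coproducts) {
          for (app in pred$apps) {
            if (any(app$products %in% matched)) {
              exempt <- c(exempt, setdiff(app$products, matched))
            }
          }
        }
        if (exempt_intermediates) {
          # does any predicted descendant of this node match an observed one?
          leads_to_match <- function(node, seen = character(0)) {
            if (node %in% seen) return(FALSE)
            for (app in pred$apps) {
              if (app$parent == node) {
                if (any(app$products %in% matched)) return(TRUE)
                for (ch in app$products) {
                  if (leads_to_match(ch, c(seen, node))) return(TRUE)
                }
              }
            }
            FALSE
          }
          for (u in setdiff(unmatched, exempt)) {
            if (leads_to_match(u)) exempt <- c(exempt, u)
          }
        }
        rest <- setdiff(unmatched, exempt)
        fp[ti] <- fp[ti] + sum(gen_weight^(pred$node_gen[rest] - 1))
      }
    }
  }
  new_eval_report(thresholds, tp, fp, fn)
}

#' Repeated compound-wise train/test split evaluation
#'
#' Compounds are split train/test (all reactions of a compound stay
#' together); per repetition a classifier-chain ensemble is trained on the
#' training compounds and evaluated single-gen on the test reactions. The
#' rule set itself is fixed.
#'
#' @param rs rule set.
#' @param rxns reactions to evaluate on.
#' @param compounds compound universe (defaults to the reaction
#'   substrates); negative-sample compounds may be included.
#' @param train_frac fraction of compounds used for training.
#' @param reps repetitions.
#' @param seed master seed.
#' @param thresholds probability grid.
#' @param n_chains chains per ensemble.
#' @return Aggregated report (mean curve and mean AUC) with per-rep AUCs
#'   in `$rep_aucs`.
#' @export
repeated_split_eval <- function(rs, rxns, compounds = NULL, train_frac = 0.8,
                                reps = 10L, seed = 1L,
                                thresholds = default_thresholds(),
                                n_chains = 5L) {
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  subs <- unique(vapply(rxns, function(r) mol_signature(r$substrate), character(1)))
  all_compounds <- unique(c(subs, if (!is.null(compounds)) {
    names(as_compound_list(compounds))
  }))
  if (length(all_compounds) < 2L) stop("need at least 2 compounds to split")
  obs <- observed_index(rxns)

  tp <- fp <- fn <- matrix(0, reps, length(thresholds))
  rep_aucs <- numeric(reps)
  for (rep in seq_len(reps)) {
    set.seed(seed + rep)
    ntrain <- max(1L, round(train_frac * length(all_compounds)))
    train_c <- sample(all_compounds, ntrain)
    test_rxns <- Filter(function(r) {
      !mol_signature(r$substrate) %in% train_c
    }, rxns)
    if (!length(test_rxns)) { rep_aucs[rep] <- NA_real_; next }
    samples <- build_samples(train_c, rs, obs)
    model <- train_ecc(samples, n_chains = n_chains, seed = seed + rep)
    ev <- single_gen(model, rs, test_rxns, thresholds)
    tp[rep, ] <- ev$tp; fp[rep, ] <- ev$fp; fn[rep, ] <- ev$fn
    rep_aucs[rep] <- ev$auc
  }
  out <- new_eval_report(thresholds, colMeans(tp), colMeans(fp), colMeans(fn),
                         reps = reps)
  out$auc <- mean(rep_aucs, na.rm = TRUE)
  out$rep_aucs <- rep_aucs
  out
}

#' Genericity scan: select the optimal target genericity
#'
#' For each genericity level, rules are regenerated from the training
#' reactions at that target, a classifier-chain ensemble is trained, and
#' the mean predicted probability of the true rule of each held-out test
#' reaction is recorded (zero when no rule reproduces the reaction). The
#' level with the highest mean probability across repetitions is reported
#' as the optimum.
#'
#' @param rxns mapped reactions.
#' @param compounds compound universe.
#' @param levels genericity level grid.
#' @param train_frac training fraction of compounds.
#' @param reps number of train/test splits.
#' @param seed master seed.
#' @param fgs functional groups for clustering.
#' @param n_chains chains per ensemble.
#' @return List: `table` (level, mean, sd), `best` (argmax level).
#' @export
genericity_scan <- function(rxns, compounds, levels = c(0, 1, 5, 10, 20, 50),
                            train_frac = 0.8, reps = 5L, seed = 1L,
                            fgs = default_functional_groups(), n_chains = 5L) {
  if (!length(levels)) stop("levels must be non-empty")
  all_compounds <- unique(c(
    vapply(rxns, function(r) mol_signature(r$substrate), character(1)),
    names(as_compound_list(compounds))))
  scores <- matrix(NA_real_, reps, length(levels),
                   dimnames = list(NULL, as.character(levels)))
  for (rep in seq_len(reps)) {
    set.seed(seed + rep)
    ntrain <- max(1L, round(train_frac * length(all_compounds)))
    train_c <- sample(all_compounds, ntrain)
    train_rxns <- Filter(function(r) mol_signature(r$substrate) %in% train_c, rxns)
    test_rxns <- Filter(function(r) !mol_signature(r$substrate) %in% train_c, rxns)
    if (length(test_rxns) == 0L || length(train_rxns) == 0L) next
    grps <- cluster_reactions(train_rxns, fgs = fgs)
    train_obs <- observed_index(train_rxns)
    for (li in seq_along(levels)) {
      rs <- generate_ruleset(grps, levels[li], train_c, train_obs)
      if (!length(rs$rules)) { scores[rep, li] <- 0; next }
      samples <- build_samples(train_c, rs, train_obs)
      model <- train_ecc(samples, n_chains = n_chains, seed = seed + rep)
      test_subs <- vapply(test_rxns, function(r) mol_signature(r$substrate),
                          character(1))
      probs <- predict_rule_probs(model, rs, unique(test_subs))
      vals <- vapply(test_rxns, function(r) {
        sig <- mol_signature(r$substrate)
        obs_set <- observed_product_set(r)
        best <- 0
        for (gid in names(rs$rules)) {
          sets <- apply_rule_cached(rs$rules[[gid]], r$substrate, sig)
          if (any(vapply(sets, identical, logical(1), y = obs_set))) {
            best <- max(best, probs[sig, gid])
          }
        }
        best
      }, numeric(1))
      scores[rep, li] <- mean(vals)
    }
  }
  tab <- data.frame(level = levels,
                    mean = colMeans(scores, na.rm = TRUE),
                    sd = apply(scores, 2, stats::sd, na.rm = TRUE))
  list(table = tab, best = levels[which.max(tab$mean)], scores = scores)
}
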