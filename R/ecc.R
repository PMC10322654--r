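# Ensemble of classifier chains for multi-label rule prediction. Each chain
# orders the labels by its own seeded permutation; the classifier of each
# label sees the compound features plus the labels earlier in the chain
# (ground truth while training, predicted probabilities at prediction
# time). Base classifiers are L2-regularized logistic regressions; labels
# with a single observed class fall back to a constant probability.
# Predictions are averaged over chains, so they are reproducible given the
# training seed.

#' Train an ensemble of classifier chains
#'
#' @param samples training samples from [build_samples()].
#' @param n_chains number of chains.
#' @param seed master seed; chain permutations and all fits derive from it.
#' @param lambda ridge penalty of the base logistic regressions.
#' @return An ECC model.
#' @export
train_ecc <- function(samples, n_chains = 10L, seed = 1L, lambda = 0.01) {
  labs <- samples$label
  feats <- samples$features
  rids <- samples$rule_ids
  if (!nrow(feats)) stop("empty training set")
  y_chain <- labs
  y_chain[is.na(y_chain)] <- 0      # chain features: known positives only

  chains <- vector("list", n_chains)
  for (ci in seq_len(n_chains)) {
    set.seed(seed + ci)
    ord <- sample(seq_along(rids))
    models <- vector("list", length(rids))
    chain_feats <- NULL
    for (k in seq_along(ord)) {
      j <- ord[k]
      x <- if (is.null(chain_feats)) feats else cbind(feats, chain_feats)
      rows <- which(!is.na(labs[, j]))
      y <- labs[rows, j]
      if (length(rows) == 0L || length(unique(y)) < 2L || min(table(y)) < 2L) {
        # one-class labels (and near-degenerate ones glmnet refuses) fall
        # back to the empirical positive rate
        p <- if (length(rows)) mean(y) else 0.5
        models[[k]] <- list(type = "const", p = p, label = j)
      } else {
        # small-sample warnings are expected on fixture-sized data
        fit <- suppressWarnings(
          glmnet::glmnet(x[rows, , drop = FALSE], y, family = "binomial",
                         alpha = 0, lambda = lambda, standardize = TRUE))
        models[[k]] <- list(type = "glmnet", fit = fit, label = j)
      }
      chain_feats <- cbind(chain_feats, y_chain[, j])
    }
    chains[[ci]] <- list(order = ord, models = models)
  }
  structure(list(chains = chains, rule_ids = rids, seed = seed,
                 n_features = ncol(feats), lambda = lambda),
            class = "rm_ecc")
}

#' @export
print.rm_ecc <- function(x, ...) {
  cat("<classifier-chain ensemble> ", length(x$chains), " chains x ",
      length(x$rule_ids), " labels (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

# probability matrix (compounds x rules) for a feature matrix
predict_ecc <- function(model, features) {
  n <- nrow(features)
  nl <- length(model$rule_ids)
  acc <- matrix(0, n, nl, dimnames = list(rownames(features), model$rule_ids))
  for (chain in model$chains) {
    probs <- matrix(0, n, nl)
    chain_feats <- NULL
    for (k in seq_along(chain$order)) {
      j <- chain$order[k]
      m <- chain$models[[k]]
      x <- if (is.null(chain_feats)) features else cbind(features, chain_feats)
      p <- if (m$type == "const") rep(m$p, n)
           else as.numeric(stats::predict(m$fit, x, type = "response"))
      probs[, j] <- p
      chain_feats <- cbind(chain_feats, p)
    }
    acc <- acc + probs
  }
  acc / length(model$chains)
}

#' Per-rule trigger probabilities for compounds
#'
#' Dispatches on the model type: an ECC model predicts from structural
#' keys and trigger bits; an oracle model (see [oracle_model()]) assigns
#' probability 1 to rules whose prediction is observed and 0 otherwise; a
#' random model draws seeded uniform probabilities (a negative control).
#'
#' @param model model object.
#' @param rs rule set.
#' @param compounds SMILES vector or molecule list.
#' @return Matrix of probabilities, compounds x rules.
#' @export
predict_rule_probs <- function(model, rs, compounds) {
  UseMethod("predict_rule_probs")
}

#' @export
predict_rule_probs.rm_ecc <- function(model, rs, compounds) {
  bf <- build_features(compounds, rs, key_width = model$n_features - length(rs$rules))
  predict_ecc(model, bf$features)
}

#' @export
predict_rule_probs.rm_oracle <- function(model, rs, compounds) {
  mols <- as_compound_list(compounds)
  rids <- names(rs$rules)
  out <- matrix(0, length(mols), length(rids),
                dimnames = list(names(mols), rids))
  for (j in seq_along(rids)) {
    rule <- rs$rules[[rids[j]]]
    for (i in seq_along(mols)) {
      sig <- names(mols)[i]
      sets <- apply_rule_cached(rule, mols[[i]], sig)
      if (!length(sets)) next
      obs <- model$observed[[sig]]
      hit <- length(obs) && any(vapply(sets, function(s) {
        any(vapply(obs, identical, logical(1), y = s))
      }, logical(1)))
      if (hit) out[i, j] <- 1
    }
  }
  out
}

#' @export
predict_rule_probs.rm_random <- function(model, rs, compounds) {
  mols <- as_compound_list(compounds)
  rids <- names(rs$rules)
  set.seed(model$seed)
  matrix(stats::runif(length(mols) * length(rids)), length(mols), length(rids),
         dimnames = list(names(mols), rids))
}

#' Oracle and random reference models
#'
#' The oracle assigns probability 1 exactly to rules whose application to a
#' compound reproduces an observed reaction; the random model draws seeded
#' uniform probabilities. Both are reference points for evaluating the
#' pipeline itself.
#'
#' @param observed reactions (or observed index).
#' @return A model usable with [predict_rule_probs()].
#' @export
oracle_model <- function(observed) {
  if (!is.list(observed) || (length(observed) && inherits(observed[[1]], "rm_rxn"))) {
    observed <- observed_index(observed)
  }
  structure(list(observed = observed), class = "rm_oracle")
}

#' @rdname oracle_model
#' @param seed seed for the uniform draws.
#' @export
random_model <- function(seed = 1L) {
  structure(list(seed = seed), class = "rm_random")
}

#' Fixed-probability lookup model
#'
#' Assigns predetermined probabilities per (compound, rule) pair; pairs
#' absent from the table get probability 0. Useful for constructing exact
#' evaluation scenarios.
#'
#' @param table data frame with columns `compound` (SMILES), `rule` (group
#'   id) and `prob`.
#' @return A model usable with [predict_rule_probs()].
#' @export
table_model <- function(table) {
  table$compound <- vapply(table$compound, function(s) {
    mol_signature(parse_smiles(s))
  }, character(1))
  structure(list(table = table), class = "rm_table")
}

#' @export
predict_rule_probs.rm_table <- function(model, rs, compounds) {
  mols <- as_compound_list(compounds)
  rids <- names(rs$rules)
  out <- matrix(0, length(mols), length(rids),
                dimnames = list(names(mols), rids))
  for (k in seq_len(nrow(model$table))) {
    sig <- model$table$compound[k]; gid <- model$table$rule[k]
    if (sig %in% rownames(out) && gid %in% rids) {
      out[sig, gid] <- model$table$prob[k]
    }
  }
  out
}
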