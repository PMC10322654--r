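# Compound featurization and PS/NS training-sample construction. Features
# are MACCS structural keys (computed through Open Babel via ChemmineOB)
# concatenated with per-rule trigger bits; labels are per-rule
# positive/negative flags, defined only where the rule triggers.

#' MACCS structural keys for a set of compounds
#'
#' @param smiles character vector of SMILES.
#' @param width number of key bits to keep.
#' @return Binary matrix, one row per compound.
#' @export
structural_keys <- function(smiles, width = 166L) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("structural keys require the ChemmineOB package")
  }
  mols <- ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"), identity)
  fp <- ChemmineOB::fingerprint_OB(mols, "MACCS")
  if (is.null(dim(fp))) fp <- matrix(fp, nrow = length(smiles), byrow = TRUE)
  fp <- fp[, seq_len(min(width, ncol(fp))), drop = FALSE]
  if (ncol(fp) < width) {
    fp <- cbind(fp, matrix(0, nrow(fp), width - ncol(fp)))
  }
  storage.mode(fp) <- "double"
  rownames(fp) <- NULL
  fp
}

# trigger / PS / NS status of every rule on every compound
rule_status <- function(compounds, rs, observed) {
  mols <- as_compound_list(compounds)
  if (!is.list(observed) || (length(observed) && inherits(observed[[1]], "rm_rxn"))) {
    observed <- observed_index(observed)
  }
  rids <- names(rs$rules)
  n <- length(mols)
  trig <- matrix(FALSE, n, length(rids), dimnames = list(names(mols), rids))
  lab <- matrix(NA_real_, n, length(rids), dimnames = list(names(mols), rids))
  for (j in seq_along(rids)) {
    rule <- rs$rules[[rids[j]]]
    for (i in seq_len(n)) {
      sig <- names(mols)[i]
      sets <- apply_rule_cached(rule, mols[[i]], sig)
      if (!length(sets)) next
      trig[i, j] <- TRUE
      obs <- observed[[sig]]
      hit <- length(obs) && any(vapply(sets, function(s) {
        any(vapply(obs, identical, logical(1), y = s))
      }, logical(1)))
      lab[i, j] <- if (hit) 1 else 0
    }
  }
  list(mols = mols, trigger = trig, label = lab)
}

# profile cache shared across rules/splits (keyed by backbone certificate
# and compound canonical form; profiles are state-independent)
profile_cache <- new.env(parent = emptyenv())

compound_profile_cached <- function(core, mol, sig, d_values) {
  key <- paste(core$cert, sig, sep = "\r")
  hit <- profile_cache[[key]]
  have <- if (is.null(hit)) integer(0) else hit$d_values
  missing_d <- setdiff(d_values, have)
  if (is.null(hit)) {
    profile_cache[[key]] <- list(d_values = d_values,
                                 profs = compound_profile(core, mol, d_values))
  } else if (length(missing_d)) {
    extra <- compound_profile(core, mol, missing_d)
    profs <- hit$profs
    for (i in seq_along(profs)) {
      profs[[i]]$choices <- c(profs[[i]]$choices, extra[[i]]$choices)
    }
    profile_cache[[key]] <- list(d_values = c(have, missing_d), profs = profs)
  }
  profile_cache[[key]]$profs
}

apply_rule_cached <- function(rule, mol, sig) {
  profs <- compound_profile_cached(rule$core, mol, sig, rule$d)
  rule_fire(rule, profs)
}

#' Build multi-label training samples
#'
#' One sample per compound: MACCS structural keys plus per-rule trigger
#' bits as features, and per-rule labels - positive when the rule triggers
#' and a predicted product set is observed for that compound, negative when
#' it triggers without an observed match, missing when it does not trigger.
#' Compounds triggering no rule are retained with all-missing labels.
#'
#' @param compounds compound universe (SMILES or molecules).
#' @param rs rule set.
#' @param observed reactions (or observed index).
#' @param key_width number of structural key bits.
#' @return A training-sample object.
#' @export
build_samples <- function(compounds, rs, observed, key_width = 166L) {
  st <- rule_status(compounds, rs, observed)
  keys <- structural_keys(names(st$mols), width = key_width)
  feats <- cbind(keys, st$trigger * 1)
  colnames(feats) <- c(paste0("k", seq_len(ncol(keys))), colnames(st$trigger))
  structure(list(features = feats, label = st$label, trigger = st$trigger,
                 compound = names(st$mols), rule_ids = colnames(st$trigger),
                 key_width = ncol(keys)),
            class = "rm_samples")
}

#' @export
print.rm_samples <- function(x, ...) {
  cat("<training samples> ", length(x$compound), " compounds x ",
      length(x$rule_ids), " rules; ",
      sum(x$label == 1, na.rm = TRUE), " positive / ",
      sum(x$label == 0, na.rm = TRUE), " negative labels\n", sep = "")
  invisible(x)
}

# features for prediction on new compounds (same layout as build_samples)
build_features <- function(compounds, rs, key_width = 166L) {
  mols <- as_compound_list(compounds)
  rids <- names(rs$rules)
  trig <- matrix(0, length(mols), length(rids),
                 dimnames = list(names(mols), rids))
  for (j in seq_along(rids)) {
    rule <- rs$rules[[rids[j]]]
    for (i in seq_along(mols)) {
      if (length(apply_rule_cached(rule, mols[[i]], names(mols)[i]))) trig[i, j] <- 1
    }
  }
  keys <- structural_keys(names(mols), width = key_width)
  feats <- cbind(keys, trig)
  colnames(feats) <- c(paste0("k", seq_len(ncol(keys))), rids)
  list(features = feats, trigger = trig == 1, compound = names(mols))
}
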