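# Incremental rule-set updates: new reactions join the stored group whose
# fingerprint matches at Tanimoto 1.0 (including previously singleton
# groups), otherwise found new groups. Only touched groups have their rules
# regenerated; untouched rules are reused unchanged.

#' Add new reactions to a rule set
#'
#' @param rs rule set.
#' @param new list of reactions (mapped, or mappable with [map_atoms()]).
#' @param compounds compound universe for genericity re-tuning.
#' @param observed reactions (or observed index) defining positive samples.
#' @param target target genericity; defaults to the rule set's stored
#'   configuration.
#' @return List with the updated rule set (`ruleset`) and an update report
#'   (`report`) counting rules changed/created, new and newly eligible
#'   groups, and skipped (unmappable) reactions.
#' @export
add_reactions <- function(rs, new, compounds, observed,
                          target = rs$config$target_genericity) {
  old_groups <- rs$groups
  skipped <- character(0)
  ok <- list()
  for (r in new) {
    if (!r$mapped) {
      r2 <- tryCatch(map_atoms(r), error = function(e) {
        warning("skipping unmappable reaction ", r$id, ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (is.null(r2)) { skipped <- c(skipped, r$id); next }
      r <- r2
    }
    ok[[length(ok) + 1L]] <- r
  }
  old_ids <- names(old_groups$reactions)
  dup <- vapply(ok, function(r) r$id %in% old_ids, logical(1))
  if (any(dup)) {
    stop("reaction id(s) already present: ",
         paste(vapply(ok[dup], `[[`, character(1), "id"), collapse = ", "))
  }

  # fingerprint the new reactions against stored group fingerprints
  new_centers <- lapply(ok, detect_reaction_center, fgs = old_groups$fgs)
  new_fps <- lapply(seq_along(ok), function(i) {
    reaction_fingerprint(ok[[i]], new_centers[[i]])
  })
  stored_keys <- vapply(old_groups$groups, function(g) fp_key(g$fingerprint),
                        character(1))

  membership <- lapply(old_groups$groups, `[[`, "member_ids")
  touched <- character(0)
  pending <- list()   # fingerprint key -> reaction ids (novel centers)
  for (i in seq_along(ok)) {
    key <- fp_key(new_fps[[i]])
    hit <- names(stored_keys)[stored_keys == key]
    if (length(hit) == 1L) {
      membership[[hit]] <- c(membership[[hit]], ok[[i]]$id)
      touched <- c(touched, hit)
    } else if (length(hit) > 1L) {
      stop("stored fingerprints are not unique; corrupt rule set")
    } else {
      pending[[key]] <- c(pending[[key]], ok[[i]]$id)
    }
  }
  # found new groups, ordered by first member id
  new_groups <- character(0)
  if (length(pending)) {
    firsts <- vapply(pending, function(ids) sort(ids)[1], character(1))
    nextno <- length(membership)
    for (k in order(firsts)) {
      nextno <- nextno + 1L
      gid <- sprintf("g%03d", nextno)
      membership[[gid]] <- sort(pending[[k]])
      new_groups <- c(new_groups, gid)
      touched <- c(touched, gid)
    }
  }
  touched <- unique(touched)

  all_rxns <- c(unname(old_groups$reactions), ok)
  groups2 <- groups_from_membership(all_rxns, membership, old_groups$fgs)

  was_eligible <- vapply(old_groups$groups, `[[`, logical(1), "eligible")
  rules2 <- rs$rules
  changed <- character(0); created <- character(0); newly_eligible <- character(0)
  for (gid in touched) {
    if (!groups2$groups[[gid]]$eligible) next
    new_rule <- tune_genericity(groups2, gid, target, compounds, observed)
    attr(new_rule, "trace") <- NULL
    had_rule <- gid %in% names(rules2)
    if (had_rule) {
      old_rule <- rules2[[gid]]
      attr(old_rule, "trace") <- NULL
      if (!identical(strip_rule(old_rule), strip_rule(new_rule))) {
        changed <- c(changed, gid)
      }
    } else {
      created <- c(created, gid)
      if (gid %in% names(old_groups$groups) && !was_eligible[[gid]]) {
        newly_eligible <- c(newly_eligible, gid)
      }
    }
    rules2[[gid]] <- new_rule
  }

  rs2 <- structure(list(groups = groups2, rules = rules2,
                        config = list(target_genericity = target)),
                   class = "rm_ruleset")
  report <- list(reactions_added = length(ok), reactions_skipped = skipped,
                 groups_touched = sort(touched), groups_new = new_groups,
                 groups_newly_eligible = sort(newly_eligible),
                 rules_changed = sort(changed), rules_created = sort(created))
  list(ruleset = rs2, report = report)
}

# comparable payload of a rule (drops environments/cache-like parts)
strip_rule <- function(rule) {
  list(d = rule$d, h = rule$h,
       simples = lapply(rule$simples, function(s) s[c("options", "h_sets")]),
       cert = rule$core$cert)
}
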