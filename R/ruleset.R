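# Rule sets: the persisted object tying together reactions, groups (with
# their stored fingerprints, singletons included) and one tuned composite
# rule per eligible group.

#' Generate a rule set from clustered reaction groups
#'
#' One composite rule is tuned per eligible group (at least two member
#' reactions); singleton groups are carried along with their fingerprints so
#' that later updates can expand them.
#'
#' @param groups reaction-group set from [cluster_reactions()].
#' @param target target genericity for every rule.
#' @param compounds compound universe used for genericity evaluation.
#' @param observed reactions (or observed index) defining positive samples.
#' @return A rule set.
#' @export
generate_ruleset <- function(groups, target, compounds, observed) {
  eligible <- names(groups$groups)[vapply(groups$groups, `[[`, logical(1), "eligible")]
  rules <- lapply(eligible, function(gid) {
    tune_genericity(groups, gid, target, compounds, observed)
  })
  names(rules) <- eligible
  structure(list(groups = groups, rules = rules,
                 config = list(target_genericity = target)),
            class = "rm_ruleset")
}

#' @export
print.rm_ruleset <- function(x, ...) {
  cat("<rule set> ", length(x$rules), " composite rules over ",
      length(x$groups$groups), " groups (",
      length(x$groups$reactions), " reactions), target genericity ",
      x$config$target_genericity, "\n", sep = "")
  invisible(x)
}

#' Partition reactions into covered and uncovered
#'
#' A reaction is covered when some rule applied to its substrate reproduces
#' its observed product set.
#'
#' @param rs rule set.
#' @param rxns list of mapped reactions.
#' @return List with `covered` and `uncovered` character vectors of
#'   reaction ids.
#' @export
coverage <- function(rs, rxns) {
  ids <- vapply(rxns, `[[`, character(1), "id")
  cov <- vapply(rxns, function(r) {
    any(vapply(rs$rules, rule_covers, logical(1), rxn = r))
  }, logical(1))
  list(covered = ids[cov], uncovered = ids[!cov])
}

# rebuild an rm_groups object from explicit membership (used when loading a
# persisted rule set; centers and fingerprints are recomputed)
groups_from_membership <- function(rxns, membership, fgs) {
  ids <- vapply(rxns, `[[`, character(1), "id")
  names(rxns) <- ids
  centers <- lapply(rxns, detect_reaction_center, fgs = fgs)
  fps <- lapply(ids, function(i) reaction_fingerprint(rxns[[i]], centers[[i]]))
  names(fps) <- ids
  groups <- lapply(names(membership), function(gid) {
    mem <- sort(membership[[gid]])
    list(id = gid, fingerprint = fps[[mem[1]]], member_ids = mem,
         eligible = length(mem) >= 2L)
  })
  names(groups) <- names(membership)
  structure(list(groups = groups, reactions = rxns, centers = centers,
                 fgs = fgs), class = "rm_groups")
}

#' Write a rule set to JSON
#'
#' Persists reactions (as mapped reaction SMILES), group membership and
#' fingerprints, rule states and SMIRKS strings, and the functional-group
#' configuration. [read_ruleset()] reconstructs the identical object.
#'
#' @param rs rule set.
#' @param path output file.
#' @export
write_ruleset <- function(rs, path) {
  obj <- list(
    format = "ruleminer-ruleset-1",
    config = rs$config,
    functional_groups = lapply(rs$groups$fgs, function(f) {
      list(name = f$name, smarts = f$smarts)
    }),
    reactions = lapply(unname(rs$groups$reactions), function(r) {
      list(id = r$id, smiles = write_reaction_smiles(r),
           incoming_elems = r$incoming_elems)
    }),
    groups = lapply(unname(rs$groups$groups), function(g) {
      list(id = g$id, member_ids = g$member_ids, eligible = g$eligible,
           fingerprint = unclass(g$fingerprint))
    }),
    rules = lapply(names(rs$rules), function(gid) {
      r <- rs$rules[[gid]]
      list(group_id = gid, d = r$d, h = r$h, genericity = r$genericity,
           ps = r$ps, ns = r$ns, smirks = emit_smirks(r, rs$groups))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a rule set from JSON
#'
#' @param path file written by [write_ruleset()].
#' @return A rule set.
#' @export
read_ruleset <- function(path) {
  obj <- jsonlite::read_json(path)
  fgs <- lapply(obj$functional_groups, function(f) {
    list(name = f$name, smarts = f$smarts, pattern = parse_smarts(f$smarts))
  })
  rxns <- lapply(obj$reactions, function(r) {
    parse_reaction(r$smiles, id = r$id,
                   incoming_elems = as.character(unlist(r$incoming_elems)))
  })
  membership <- stats::setNames(
    lapply(obj$groups, function(g) as.character(unlist(g$member_ids))),
    vapply(obj$groups, `[[`, character(1), "id"))
  groups <- groups_from_membership(rxns, membership, fgs)
  rules <- list()
  for (r in obj$rules) {
    core <- build_group_core(groups, r$group_id)
    rl <- build_composite(core, groups, as.integer(r$d), as.integer(r$h))
    rl$genericity <- as.numeric(r$genericity)
    rl$ps <- as.integer(r$ps); rl$ns <- as.integer(r$ns)
    rules[[r$group_id]] <- rl
  }
  tg <- obj$config$target_genericity
  tg <- if (is.null(tg)) NA_real_ else as.numeric(tg)
  structure(list(groups = groups, rules = rules,
                 config = list(target_genericity = tg)),
            class = "rm_ruleset")
}

#' Export rules as plain-text SMIRKS
#'
#' One simple-rule SMIRKS per line with a tab-separated rule label, for
#' interoperability with external rule collections.
#'
#' @param rs rule set.
#' @param path output file.
#' @export
export_rules <- function(rs, path) {
  lines <- character(0)
  for (gid in names(rs$rules)) {
    sm <- emit_smirks(rs$rules[[gid]], rs$groups)
    lines <- c(lines, paste0(sm, "\t", gid, ".", seq_along(sm)))
  }
  writeLines(lines, path)
  invisible(path)
}
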