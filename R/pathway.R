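# Pathway graphs: directed compound graphs (nodes are canonical compound
# forms, edges parent -> child via a reaction), rooted at entry compounds,
# with generations measured as shortest edge distance from a root.

#' Build a pathway graph
#'
#' @param id pathway id.
#' @param edges list of edges, each `list(parent, children)` with SMILES
#'   (optionally `reaction` carrying the reaction SMILES or id).
#' @return A pathway object.
#' @export
pathway_graph <- function(id, edges) {
  canon <- function(s) mol_signature(parse_smiles(s))
  el <- do.call(rbind, lapply(edges, function(e) {
    parent <- canon(e$parent)
    children <- vapply(unlist(e$children), canon, character(1))
    data.frame(parent = parent, child = children,
               reaction = e$reaction %||% NA_character_)
  }))
  # collapse duplicate edges between identical canonical forms
  el <- el[!duplicated(el[, c("parent", "child")]), , drop = FALSE]
  nodes <- unique(c(el$parent, el$child))
  g <- igraph::graph_from_data_frame(el[, c("parent", "child")],
                                     vertices = nodes, directed = TRUE)
  if (!igraph::is_dag(g)) stop("pathway ", id, " is cyclic")
  roots <- nodes[igraph::degree(g, mode = "in") == 0]
  if (!length(roots)) stop("pathway ", id, " has no root")
  d <- igraph::distances(g, v = roots, mode = "out")
  gen <- apply(d, 2, min)
  if (any(is.infinite(gen))) stop("pathway ", id, ": node unreachable from any root")
  structure(list(id = id, edges = el, nodes = nodes, roots = roots,
                 generation = gen, graph = g), class = "rm_pathway")
}

#' @export
print.rm_pathway <- function(x, ...) {
  cat("<pathway ", x$id, "> ", length(x$nodes), " compounds, ",
      nrow(x$edges), " edges, max generation ", max(x$generation), "\n", sep = "")
  invisible(x)
}

#' Read pathways from JSON
#'
#' Format: an array of `{pathway-id, edges: [{parent-smiles,
#' reaction-smiles, children-smiles[]}]}` objects.
#'
#' @param path file path.
#' @return List of pathway objects.
#' @export
read_pathways <- function(path) {
  obj <- jsonlite::read_json(path)
  lapply(obj, function(p) {
    edges <- lapply(p$edges, function(e) {
      list(parent = e[["parent-smiles"]],
           reaction = e[["reaction-smiles"]] %||% NA_character_,
           children = as.character(unlist(e[["children-smiles"]])))
    })
    pathway_graph(p[["pathway-id"]], edges)
  })
}

#' Write pathways to JSON
#'
#' @param pathways list of pathway objects.
#' @param path output path.
#' @export
write_pathways <- function(pathways, path) {
  obj <- lapply(pathways, function(p) {
    list(`pathway-id` = p$id,
         edges = lapply(seq_len(nrow(p$edges)), function(i) {
           list(`parent-smiles` = p$edges$parent[i],
                `reaction-smiles` = p$edges$reaction[i],
                `children-smiles` = list(p$edges$child[i]))
         }))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(path)
}
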