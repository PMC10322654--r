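# Low-level labeled-graph utilities shared by molecules, reaction centers and
# leaf signatures. Graphs are plain edge lists on vertices 1..n; nothing here
# knows about chemistry.

# adjacency list: for each vertex an integer vector of neighbours plus the
# index of the corresponding edge row
adj_list <- function(n, e1, e2) {
  nbr <- vector("list", n)
  eid <- vector("list", n)
  for (k in seq_along(e1)) {
    i <- e1[k]; j <- e2[k]
    nbr[[i]] <- c(nbr[[i]], j); eid[[i]] <- c(eid[[i]], k)
    nbr[[j]] <- c(nbr[[j]], i); eid[[j]] <- c(eid[[j]], k)
  }
  list(nbr = nbr, eid = eid)
}

# multi-source BFS distance; unreachable vertices get Inf
bfs_dist <- function(n, adj, sources) {
  d <- rep(Inf, n)
  if (length(sources) == 0L) return(d)
  d[sources] <- 0
  queue <- sources
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj$nbr[[v]]) {
      if (is.infinite(d[w])) {
        d[w] <- d[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  d
}

# connected components over a vertex subset (vertices outside `keep` ignored);
# returns list of integer vectors
components_of <- function(n, adj, keep) {
  keep_set <- logical(n); keep_set[keep] <- TRUE
  seen <- logical(n)
  out <- list()
  for (s in keep) {
    if (seen[s]) next
    comp <- integer(0)
    queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      comp <- c(comp, v)
      for (w in adj$nbr[[v]]) {
        if (keep_set[w] && !seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    out[[length(out) + 1L]] <- sort(comp)
  }
  out
}

refine_ranks <- function(ranks, vadj, elabs) {
  n <- length(ranks)
  repeat {
    keys <- character(n)
    for (i in seq_len(n)) {
      nb <- vadj$nbr[[i]]
      if (length(nb)) {
        tok <- sort(paste0(elabs[vadj$eid[[i]]], "~", ranks[nb]))
        keys[i] <- paste0(ranks[i], "|", paste(tok, collapse = ","))
      } else {
        keys[i] <- paste0(ranks[i], "|")
      }
    }
    new <- match(keys, sort(unique(keys)))
    if (length(unique(new)) == length(unique(ranks))) return(new)
    ranks <- new
  }
}

# Canonical vertex ordering of a labeled graph by iterative partition
# refinement with exhaustive tie-breaking (minimum-certificate rule). Exact
# for any graph; intended for molecule-sized inputs.
canon_graph <- function(vlabs, e1, e2, elabs) {
  n <- length(vlabs)
  if (n == 0L) return(list(perm = integer(0), cert = ""))
  vadj <- adj_list(n, e1, e2)

  cert_of <- function(ranks) {
    ord <- order(ranks)
    pos <- integer(n); pos[ord] <- seq_len(n)
    es <- character(length(e1))
    if (length(e1)) {
      p1 <- pmin(pos[e1], pos[e2]); p2 <- pmax(pos[e1], pos[e2])
      es <- sort(paste0(p1, "-", p2, ":", elabs))
    }
    paste(paste(vlabs[ord], collapse = ";"), paste(es, collapse = ";"), sep = "||")
  }

  best <- NULL
  search <- function(ranks) {
    ranks <- refine_ranks(ranks, vadj, elabs)
    if (length(unique(ranks)) == n) {
      cert <- cert_of(ranks)
      if (is.null(best) || cert < best$cert) best <<- list(ranks = ranks, cert = cert)
      return(invisible(NULL))
    }
    tab <- table(ranks)
    cls <- as.integer(names(tab)[tab > 1L][1L])
    for (a in which(ranks == cls)) {
      r2 <- ranks * 2L
      r2[a] <- r2[a] - 1L
      search(r2)
    }
    invisible(NULL)
  }
  search(match(vlabs, sort(unique(vlabs))))
  pos <- integer(n); pos[order(best$ranks)] <- seq_len(n)
  list(perm = pos, cert = best$cert)
}

# certificate only (identity string for a labeled graph)
graph_cert <- function(vlabs, e1, e2, elabs) canon_graph(vlabs, e1, e2, elabs)$cert
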