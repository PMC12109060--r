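#' Build a confidence-filtered protein-protein interaction network
#'
#' Edges below the confidence cutoff (default 700 on the 0-1000 STRING
#' combined-score scale, i.e. 70% confidence) are dropped, self-loops and
#' duplicate pairs removed (keeping the highest score per pair), and nodes
#' with no more than 2 remaining edges discarded. Pruning is a single pass
#' by default; `prune = "kcore"` iterates the degree rule to the 3-core.
#'
#' @param edges Data frame with columns `protein1`, `protein2`,
#'   `combined_score` (0-1000).
#' @param score_cutoff Minimum combined score kept (edges with score <
#'   cutoff are dropped).
#' @param min_degree_keep Minimum node degree kept after edge filtering
#'   (nodes with degree below this are removed).
#' @param prune `"once"` (single pass, default) or `"kcore"` (iterate).
#' @return An object of class `ppi_network`: list with `nodes`, `edges`
#'   (filtered data frame) and `adjacency` (named list of neighbour
#'   vectors).
#' @export
#' @examples
#' e <- data.frame(protein1 = c("A","A","A","B","B","C"),
#'                 protein2 = c("B","C","D","C","D","D"),
#'                 combined_score = 900)
#' build_ppi_network(e)$nodes  # the K4 survives intact
build_ppi_network <- function(edges, score_cutoff = 700,
                              min_degree_keep = 3,
                              prune = c("once", "kcore")) {
  prune <- match.arg(prune)
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% names(edges)))
    ts_stop("parse_error",
            paste("edge list needs columns:", paste(need, collapse = ", ")))
  bad <- which(!is.finite(edges$combined_score) |
                 edges$combined_score < 0 | edges$combined_score > 1000 |
                 is.na(edges$protein1) | is.na(edges$protein2) |
                 edges$protein1 == "" | edges$protein2 == "")
  if (length(bad))
    ts_stop("parse_error",
            sprintf("malformed edge row(s): %s",
                    paste(head(bad, 5L), collapse = ", ")))
  e <- edges[edges$combined_score >= score_cutoff, , drop = FALSE]
  e <- e[e$protein1 != e$protein2, , drop = FALSE]
  if (nrow(e)) {
    a <- pmin(e$protein1, e$protein2)
    b <- pmax(e$protein1, e$protein2)
    key <- paste(a, b, sep = "\r")
    ord <- order(key, -e$combined_score)
    e <- data.frame(protein1 = a, protein2 = b,
                    combined_score = e$combined_score,
                    stringsAsFactors = FALSE)[ord, ]
    e <- e[!duplicated(paste(e$protein1, e$protein2, sep = "\r")), ]
  }
  repeat {
    nodes <- sort(unique(c(e$protein1, e$protein2)))
    deg <- table(factor(c(e$protein1, e$protein2), levels = nodes))
    drop <- names(deg)[deg < min_degree_keep]
    if (!length(drop) || !nrow(e)) break
    e <- e[!(e$protein1 %in% drop | e$protein2 %in% drop), , drop = FALSE]
    if (prune == "once") break
  }
  nodes <- sort(unique(c(e$protein1, e$protein2)))
  adjacency <- lapply(setNames(nodes, nodes), function(v) {
    sort(unique(c(e$protein2[e$protein1 == v], e$protein1[e$protein2 == v])))
  })
  rownames(e) <- NULL
  structure(list(nodes = nodes, edges = e, adjacency = adjacency),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("<ppi_network>", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

# Integer adjacency list (indices into net$nodes) for the algorithms below.
.adj_idx <- function(net) {
  lapply(net$adjacency, function(nb) match(nb, net$nodes))
}

#' Degree centrality
#'
#' Number of edges incident to each node.
#'
#' @param net A [build_ppi_network()] result.
#' @return Named integer vector over `net$nodes`.
#' @export
degree_centrality <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  vapply(net$adjacency, length, integer(1))
}

# Breadth-first shortest-path distances (unweighted) from one source;
# returns an integer vector with NA for unreachable nodes.
.bfs_dist <- function(adj, src) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  dist[src] <- 0L
  frontier <- src
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Closeness centrality (harmonic by default)
#'
#' Harmonic closeness sums the reciprocal shortest-path distances to every
#' other node, with unreachable nodes contributing zero - well defined on
#' the disconnected graphs that confidence pruning can create, and the
#' convention used by hub-ranking tools. `method = "classic"` returns
#' Freeman closeness, `1 / sum(d)`, computed within each node's connected
#' component.
#'
#' @param net A [build_ppi_network()] result.
#' @param method `"harmonic"` (default) or `"classic"`.
#' @return Named numeric vector.
#' @export
closeness_centrality <- function(net, method = c("harmonic", "classic")) {
  stopifnot(inherits(net, "ppi_network"))
  method <- match.arg(method)
  adj <- .adj_idx(net)
  out <- vapply(seq_along(adj), function(v) {
    d <- .bfs_dist(adj, v)[-v]
    d <- d[!is.na(d)]
    if (!length(d)) return(0)
    if (method == "harmonic") sum(1 / d) else 1 / sum(d)
  }, numeric(1))
  setNames(out, net$nodes)
}

# Bron-Kerbosch maximal-clique enumeration with pivoting, on integer
# adjacency. Calls `emit(clique)` for every maximal clique (including
# singletons of isolated nodes).
.bron_kerbosch <- function(adj, emit) {
  bk <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      emit(R)
      return(invisible(NULL))
    }
    pool <- c(P, X)
    pivot <- pool[which.max(vapply(pool, function(u)
      sum(P %in% adj[[u]]), integer(1)))]
    for (v in setdiff(P, adj[[pivot]])) {
      bk(c(R, v), intersect(P, adj[[v]]), intersect(X, adj[[v]]))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(integer(0), seq_along(adj), integer(0))
}

#' Maximal clique centrality (MCC)
#'
#' For each node, the sum over all maximal cliques containing it of
#' `(|C| - 1)!`. Maximal cliques are enumerated with the Bron-Kerbosch
#' algorithm with pivoting; an isolated node forms its own maximal clique
#' of size 1 and scores `0! = 1`.
#'
#' @param net A [build_ppi_network()] result.
#' @param node_cap Refuse graphs larger than this (clique enumeration is
#'   exponential in the worst case).
#' @return Named numeric vector.
#' @export
#' @examples
#' e <- data.frame(protein1 = c("A","A","B"), protein2 = c("B","C","C"),
#'                 combined_score = 900)
#' mcc(build_ppi_network(e, min_degree_keep = 0))  # triangle: all 2
mcc <- function(net, node_cap = 5000L) {
  stopifnot(inherits(net, "ppi_network"))
  if (length(net$nodes) > node_cap)
    ts_stop("resource_limit",
            sprintf("graph has %d nodes; clique enumeration capped at %d",
                    length(net$nodes), node_cap))
  adj <- .adj_idx(net)
  score <- numeric(length(adj))
  .bron_kerbosch(adj, function(clique) {
    score[clique] <<- score[clique] + factorial(length(clique) - 1L)
  })
  setNames(score, net$nodes)
}

#' Maximal neighbourhood component (MNC)
#'
#' For each node `v`, the size of the largest connected component of the
#' subgraph induced by the neighbours of `v` (with `v` itself excluded). A
#' star centre whose leaves are mutually unconnected scores 1; a node with
#' no neighbours scores 0.
#'
#' @param net A [build_ppi_network()] result.
#' @return Named integer vector.
#' @export
mnc <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  adj <- .adj_idx(net)
  out <- vapply(seq_along(adj), function(v) {
    nb <- adj[[v]]
    if (!length(nb)) return(0L)
    sub <- lapply(setNames(nb, nb), function(u) intersect(adj[[u]], nb))
    seen <- setNames(rep(FALSE, length(nb)), nb)
    best <- 0L
    for (s in nb) {
      if (seen[as.character(s)]) next
      comp <- s
      frontier <- s
      seen[as.character(s)] <- TRUE
      while (length(frontier)) {
        nxt <- unique(unlist(sub[as.character(frontier)], use.names = FALSE))
        nxt <- nxt[!seen[as.character(nxt)]]
        seen[as.character(nxt)] <- TRUE
        comp <- c(comp, nxt)
        frontier <- nxt
      }
      best <- max(best, length(comp))
    }
    best
  }, integer(1))
  setNames(out, net$nodes)
}

#' All four hub-ranking centralities of a network
#'
#' @param net A [build_ppi_network()] result.
#' @param closeness_method Passed to [closeness_centrality()].
#' @return Data frame `gene`, `degree`, `closeness`, `mcc`, `mnc`.
#' @export
centrality_table <- function(net, closeness_method = "harmonic") {
  data.frame(gene = net$nodes,
             degree = as.integer(degree_centrality(net)),
             closeness = unname(closeness_centrality(net, closeness_method)),
             mcc = unname(mcc(net)),
             mnc = as.integer(mnc(net)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Top-k hub consensus across centrality algorithms
#'
#' Each algorithm ranks genes by score descending with a deterministic
#' tie-break (score descending, then gene symbol ascending) and contributes
#' its first `k` genes; the consensus is the intersection of all
#' per-algorithm top-k lists. The rank-k cut is strict (ties beyond k are
#' excluded), which keeps the lists reproducible.
#'
#' @param tab A [centrality_table()] result.
#' @param k Hub-list length per algorithm.
#' @param algorithms Which score columns participate.
#' @return List with `top` (named list of character vectors per algorithm)
#'   and `consensus` (sorted character vector).
#' @export
top_k_consensus <- function(tab, k = 15L,
                            algorithms = c("mcc", "mnc", "degree",
                                           "closeness")) {
  miss <- setdiff(algorithms, names(tab))
  if (length(miss))
    ts_stop("invalid_records",
            paste("centrality table lacks column(s):",
                  paste(miss, collapse = ", ")))
  top <- lapply(setNames(algorithms, algorithms), function(a) {
    ord <- order(-tab[[a]], tab$gene)
    tab$gene[ord][seq_len(min(k, nrow(tab)))]
  })
  list(top = top, consensus = sort(Reduce(intersect, top)))
}

#' Cross-subtype key-hub intersection
#'
#' Intersects per-subtype hub (consensus) gene lists to find the hubs every
#' subtype shares, per regulation direction.
#'
#' @param hub_lists List of character vectors, one per subtype.
#' @return Sorted character vector of common hub genes.
#' @export
#' @examples
#' key_hub_intersection(list(c("MAPK1", "ESR1"), c("MAPK1", "AKT1")))
key_hub_intersection <- function(hub_lists) {
  if (!length(hub_lists)) return(character(0))
  sort(Reduce(intersect, hub_lists))
}
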