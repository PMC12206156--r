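#' Topological order of the alignment graph
#'
#' Kahn's algorithm; deterministic (ready nodes and successor visits are
#' ordered by node rank, then node id).
#'
#' @param graph An `alignment_graph`.
#' @return Node ids in an order where every edge goes from an earlier to a
#'   later position.
#' @export
topological_order <- function(graph) {
  ord <- topo_sort_positions(graph$nodes, graph$edges)
  if (is.null(ord)) {
    # name one edge inside the cyclic remainder
    nodes <- graph$nodes; edges <- graph$edges
    fpos <- match(edges$from, nodes$id)
    tpos <- match(edges$to, nodes$id)
    done <- peel_acyclic(nodes, edges)
    bad <- which(!(fpos %in% done) & !(tpos %in% done))[1L]
    stop(sprintf("graph contains a cycle through edge %d -> %d",
                 edges$from[bad], edges$to[bad]), call. = FALSE)
  }
  graph$nodes$id[ord]
}

# positions of nodes removable by Kahn peeling (complement = cyclic core)
peel_acyclic <- function(nodes, edges) {
  np <- nrow(nodes)
  tpos <- match(edges$to, nodes$id)
  fpos <- match(edges$from, nodes$id)
  indeg <- tabulate(tpos, np)
  adj <- succ_list(np, fpos, tpos)
  queue <- which(indeg == 0L)
  done <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    done <- c(done, v)
    ws <- adj[[v]]
    indeg[ws] <- indeg[ws] - 1L
    queue <- c(queue, ws[indeg[ws] == 0L])
  }
  done
}

#' Maximum total-weight path
#'
#' Computes, in topological order, `DP[u] = max over predecessors v of
#' DP[v] + w(v, u)` (nodes without predecessors score 0), finds the node
#' with the largest DP value and reconstructs the path ending there by
#' backtracking stored best predecessors. Runs in O(|E|). Weights are
#' integral throughout, so ties are exact; equal-scoring predecessors are
#' resolved by preferring the path carrying fewer labeled nodes (the
#' parsimonious one — an equally supported bypass beats a walk through a
#' spurious repeat copy), then backbone edges, then the smaller-rank
#' predecessor, then a non-N label — zero-coverage stretches therefore
#' fall back to the backbone.
#'
#' @param graph A simplified `alignment_graph`.
#' @return A `genome_path`: ordered node ids, total weight, and the
#'   concatenated labels (virtual nodes contribute nothing).
#' @export
max_weight_path <- function(graph) {
  nodes <- graph$nodes; edges <- graph$edges
  if (nrow(nodes) == 0L) stop("empty graph", call. = FALSE)
  ord <- topo_sort_positions(nodes, edges)
  if (is.null(ord)) stop("graph contains a cycle", call. = FALSE)
  np <- nrow(nodes)
  topo_of <- integer(np); topo_of[ord] <- seq_len(np)

  if (nrow(edges)) {
    fpos <- match(edges$from, nodes$id)
    tpos <- match(edges$to, nodes$id)
    fi <- topo_of[fpos]; ti <- topo_of[tpos]
    eord <- order(ti)
    res <- cpp_dag_dp(np, fi[eord], ti[eord],
                      as.integer(round(edges$weight[eord])),
                      edges$is_backbone[eord],
                      nodes$rank[ord],
                      (nodes$label == "N")[ord],
                      (nodes$label != "")[ord])
    dp <- res$dp; bp <- res$best_pred
  } else {
    dp <- rep(0, np); bp <- integer(np)
  }

  m <- max(dp)
  cand <- which(dp == m)                       # topo positions
  cand_rank <- nodes$rank[ord[cand]]
  cand_id <- nodes$id[ord[cand]]
  pick <- cand[order(-cand_rank, cand_id)][1L]  # largest rank, smallest id

  path <- integer(0); u <- pick
  repeat {
    path <- c(u, path)
    if (bp[u] == 0L) break
    u <- bp[u]
  }
  node_ids <- nodes$id[ord[path]]
  labels <- nodes$label[ord[path]]
  structure(list(node_ids = node_ids,
                 total_weight = as.numeric(m),
                 sequence = paste(labels[labels != ""], collapse = "")),
            class = "genome_path")
}

#' @export
print.genome_path <- function(x, ...) {
  cat(sprintf("<genome_path> %d nodes, total weight %d, %d bp\n",
              length(x$node_ids), as.integer(x$total_weight),
              nchar(x$sequence)))
  invisible(x)
}

#' Recompute a path's weight from the graph edges
#'
#' Audit helper: sums the weights of the edges traversed by `path`.
#'
#' @param graph An `alignment_graph`.
#' @param path A `genome_path` (or a vector of node ids).
#' @return The summed edge weight; errors if consecutive nodes are not
#'   connected.
#' @export
path_weight <- function(graph, path) {
  ids <- if (inherits(path, "genome_path")) path$node_ids else path
  if (length(ids) < 2L) return(0)
  w <- mapply(function(a, b) edge_weight(graph, a, b),
              ids[-length(ids)], ids[-1L])
  if (anyNA(w)) stop("path uses a non-existent edge", call. = FALSE)
  sum(w)
}

#' Sequence of a genome path
#'
#' @param path A `genome_path`.
#' @param id Identifier for the resulting record (e.g. encoding the
#'   iteration number).
#' @return A [seq_record].
#' @export
path_sequence <- function(path, id = "consensus") {
  stopifnot(inherits(path, "genome_path"))
  if (!nzchar(path$sequence))
    stop("path has no labeled nodes", call. = FALSE)
  seq_record(id, path$sequence)
}
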