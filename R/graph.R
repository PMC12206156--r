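#' Alignment graph
#'
#' A weighted DAG over single-base nodes. The backbone genome contributes
#' one labeled node per base plus two virtual (unlabeled) source/sink
#' nodes; threading reads adds nodes for mismatched and inserted bases and
#' increments edge weights, which count supporting reads.
#'
#' Nodes carry a `rank`: backbone nodes are ranked by position, a mismatch
#' node at backbone position `j` is ranked just before `j`, and insertion
#' nodes are ranked strictly between their flanking backbone positions (in
#' read order for consecutive insertions). Every edge created by threading
#' goes strictly forward in rank, so the graph is acyclic by construction;
#' node merging re-validates acyclicity.
#'
#' @name alignment_graph
NULL

SOURCE_ID <- 1L

#' Initialise the backbone graph
#'
#' Builds the initial graph: one labeled node per backbone base, an edge of
#' weight 0 between each pair of consecutive bases, and virtual source/sink
#' nodes attached with zero-weight edges. Backbone edges are flagged and
#' never removed, so the consensus path can traverse zero-coverage gaps
#' along the backbone.
#'
#' @param backbone A [seq_record].
#' @return An `alignment_graph` object.
#' @examples
#' g <- init_backbone_graph(seq_record("ref", "ACG"))
#' nrow(g$nodes)  # 3 backbone nodes + source + sink
#' @export
init_backbone_graph <- function(backbone) {
  stopifnot(inherits(backbone, "seq_record"))
  n <- nchar(backbone$sequence)
  if (n < 1L) stop("empty backbone", call. = FALSE)
  chars <- seq_chars(backbone)
  sink_id <- n + 2L
  nodes <- data.frame(
    id = c(SOURCE_ID, seq_len(n) + 1L, sink_id),
    label = c("", chars, ""),
    backbone_index = c(NA_integer_, 0:(n - 1L), NA_integer_),
    rank = c(-1, 0:(n - 1L), n),
    stringsAsFactors = FALSE)
  internal_from <- if (n >= 2L) 1L + seq_len(n - 1L) else integer(0)
  edges <- data.frame(
    from = c(SOURCE_ID, internal_from, n + 1L),
    to = c(2L, internal_from + 1L, sink_id),
    weight = 0,
    is_backbone = TRUE)
  structure(list(nodes = nodes, edges = edges, backbone = backbone,
                 backbone_chars = chars, source_id = SOURCE_ID,
                 sink_id = sink_id, n_backbone = n,
                 next_id = sink_id + 1L),
            class = "alignment_graph")
}

#' @export
print.alignment_graph <- function(x, ...) {
  cat(sprintf(paste0("<alignment_graph> backbone %s (%d bp), %d nodes, ",
                     "%d edges, total weight %d\n"),
              x$backbone$id, x$n_backbone, nrow(x$nodes), nrow(x$edges),
              as.integer(sum(x$edges$weight))))
  invisible(x)
}

# walk one read's CIGAR along the backbone; returns the per-base node
# assignment (backbone node id or NA for a to-be-created node), plus the
# label/rank of new nodes, in read order
thread_one <- function(backbone_chars, aln) {
  n <- length(backbone_chars)
  ops <- aln$cigar$ops
  lens <- aln$cigar$lens
  rchars <- strsplit(aln$read_sequence, "", fixed = TRUE)[[1L]]
  qcons <- ops %in% c("M", "=", "X", "I", "S")
  tcons <- ops %in% c("M", "=", "X", "D")
  if (aln$target_start + sum(lens[tcons]) > n)
    stop("CIGAR walks past the backbone end", call. = FALSE)
  qstart <- cumsum(c(0L, (lens * qcons)))[seq_along(ops)]
  tstart <- aln$target_start + cumsum(c(0L, (lens * tcons)))[seq_along(ops)]
  ids <- vector("list", length(ops))
  labs <- vector("list", length(ops))
  rks <- vector("list", length(ops))
  for (k in seq_along(ops)) {
    op <- ops[k]; len <- lens[k]
    if (op %in% c("M", "=", "X")) {
      tp <- tstart[k] + 0:(len - 1L)
      rc <- rchars[qstart[k] + seq_len(len)]
      bc <- backbone_chars[tp + 1L]
      is_match <- if (op == "X") rep(FALSE, len) else
        (rc == bc & rc != "N")
      ids[[k]] <- ifelse(is_match, tp + 2L, NA_integer_)
      labs[[k]] <- rc
      rks[[k]] <- tp - 0.25
    } else if (op == "I") {
      rc <- rchars[qstart[k] + seq_len(len)]
      ids[[k]] <- rep(NA_integer_, len)
      labs[[k]] <- rc
      rks[[k]] <- (tstart[k] - 1L) + 0.5 * seq_len(len) / (len + 1L)
    }
    # D advances the target cursor only; S/H consume nothing here
  }
  list(node_id = unlist(ids), label = unlist(labs), rank = unlist(rks))
}

#' Thread one read alignment into the graph
#'
#' Walks the CIGAR: a read base matching the backbone base maps to the
#' existing backbone node and increments the entering edge's weight by 1;
#' a mismatched or inserted base creates a new node labeled with the read
#' base; a deletion adds a weight-1 edge bypassing the deleted backbone
#' nodes. The read's first node gets a zero-weight edge from the virtual
#' source when it is not a backbone node. `N` never matches any base.
#'
#' @param graph An `alignment_graph`.
#' @param aln A [read_alignment].
#' @return The updated graph.
#' @export
thread_alignment <- function(graph, aln) {
  thread_alignments(graph, list(aln))
}

#' Thread a set of read alignments into the graph
#'
#' Bulk version of [thread_alignment()]; edge weights contributed by all
#' reads are accumulated in one pass.
#'
#' @param graph An `alignment_graph`.
#' @param alns List of [read_alignment] objects.
#' @return The updated graph.
#' @export
thread_alignments <- function(graph, alns) {
  stopifnot(inherits(graph, "alignment_graph"))
  if (length(alns) == 0L) return(graph)
  next_id <- graph$next_id
  nn_id <- nn_lab <- nn_rank <- vector("list", length(alns))
  ef <- et <- ew <- vector("list", length(alns))
  for (i in seq_along(alns)) {
    r <- thread_one(graph$backbone_chars, alns[[i]])
    nid <- r$node_id
    L <- length(nid)
    if (L == 0L) next
    new <- which(is.na(nid))
    if (length(new)) {
      nid[new] <- next_id + seq_along(new) - 1L
      next_id <- next_id + length(new)
      nn_id[[i]] <- nid[new]
      nn_lab[[i]] <- r$label[new]
      nn_rank[[i]] <- r$rank[new]
    }
    from <- to <- integer(0); w <- numeric(0)
    if (L >= 2L) {
      from <- nid[-L]; to <- nid[-1L]; w <- rep(1, L - 1L)
    }
    if (nid[1L] >= graph$sink_id + 1L) {  # read starts on a created node
      from <- c(graph$source_id, from); to <- c(nid[1L], to); w <- c(0, w)
    }
    ef[[i]] <- from; et[[i]] <- to; ew[[i]] <- w
  }
  ids_new <- unlist(nn_id)
  if (length(ids_new)) {
    new_nodes <- data.frame(id = ids_new,
                            label = unlist(nn_lab),
                            backbone_index = NA_integer_,
                            rank = unlist(nn_rank),
                            stringsAsFactors = FALSE)
    graph$nodes <- rbind(graph$nodes, new_nodes)
  }

  all_from <- c(graph$edges$from, unlist(ef))
  all_to <- c(graph$edges$to, unlist(et))
  all_w <- c(graph$edges$weight, unlist(ew))
  M <- as.numeric(next_id)
  key <- as.numeric(all_from) * M + as.numeric(all_to)
  agg <- rowsum(all_w, key)
  k <- as.numeric(rownames(agg))
  bb_key <- as.numeric(graph$edges$from[graph$edges$is_backbone]) * M +
    as.numeric(graph$edges$to[graph$edges$is_backbone])
  graph$edges <- data.frame(from = as.integer(k %/% M),
                            to = as.integer(k %% M),
                            weight = as.numeric(agg[, 1L]),
                            is_backbone = k %in% bb_key)
  graph$next_id <- next_id
  if (!validate_dag(graph))
    stop("threading produced a cycle (corrupt alignment?)", call. = FALSE)
  graph
}

#' Simplify the alignment graph
#'
#' Repeatedly merges nodes that carry the same label and share a parent
#' (union of in/out edges, entering-edge weights summed), then collapses
#' parallel edges between one ordered node pair into a single edge with the
#' summed weight, until a fixpoint. Two backbone nodes never merge; a
#' created node may merge into a backbone node with equal label and shared
#' parent. A candidate merge that would create a cycle is skipped with a
#' warning. Acyclicity is re-validated after every merge round.
#'
#' @param graph An `alignment_graph`.
#' @return The simplified graph.
#' @export
simplify_graph <- function(graph) {
  stopifnot(inherits(graph, "alignment_graph"))
  graph <- collapse_parallel_edges(graph)
  for (round in seq_len(1000L)) {
    res <- simplify_round(graph)
    if (is.null(res)) break
    graph <- res
  }
  if (!validate_dag(graph))
    stop("internal error: simplification broke acyclicity", call. = FALSE)
  graph
}

# One merge round; NULL when nothing merged (fixpoint reached).
#
# Candidate pairs joined by a direct edge are never merged (the merge
# would collapse that edge into a self-loop, i.e. a cycle) — this is the
# usual partial-order-graph rule and covers homopolymer insert-vs-match
# ambiguity. The rare indirect-cycle case is caught by re-validating the
# rebuilt graph and re-running the round with the offending groups
# excluded.
simplify_round <- function(graph) {
  nodes <- graph$nodes; edges <- graph$edges
  np <- nrow(nodes)
  fpos <- match(edges$from, nodes$id)
  tpos <- match(edges$to, nodes$id)
  mergeable <- nodes$label[tpos] != ""
  if (!any(mergeable)) return(NULL)
  key <- paste0(fpos[mergeable], "\r", nodes$label[tpos][mergeable])
  groups <- split(tpos[mergeable], key)
  groups <- groups[lengths(groups) >= 2L]
  if (length(groups) == 0L) return(NULL)

  hasbb <- !is.na(nodes$backbone_index)
  rk <- nodes$rank; ids <- nodes$id
  succ <- succ_list(np, fpos, tpos)
  pred <- succ_list(np, tpos, fpos)
  # order members so the preferred representative (backbone, then smallest
  # rank/id) comes first
  groups <- lapply(groups, function(g) {
    g <- unique(g)
    g[order(!hasbb[g], rk[g], ids[g])]
  })

  # nodes reachable from `start` within a rank window; NULL when the
  # exploration cap is hit (treated as "may be reachable")
  reach_set <- function(adj, start, lo, hi, cap = 400L) {
    seen <- integer(0)
    frontier <- start
    while (length(frontier)) {
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[rk[nxt] >= lo & rk[nxt] <= hi]
      nxt <- setdiff(nxt, seen)
      if (!length(nxt)) break
      seen <- c(seen, nxt)
      if (length(seen) > cap) return(NULL)
      frontier <- nxt
    }
    seen
  }

  attempt <- function(excluded) {
    parent <- seq_len(np)
    n_union <- 0L
    for (gi in seq_along(groups)) {
      if (excluded[gi]) next
      g <- groups[[gi]]
      # greedily partition the group into merge sub-sets: a member joins
      # the first sub-set it can merge with safely, else founds a new one
      # (e.g. a backbone base and the reads' insertions of that same base
      # form two sets: the insertions all merge, the backbone stays apart)
      subsets <- list(g[1L])
      for (b in g[-1L]) {
        rb <- b; while (parent[rb] != rb) rb <- parent[rb]
        placed <- FALSE
        for (si in seq_along(subsets)) {
          acc <- subsets[[si]]
          ra <- acc[1L]; while (parent[ra] != ra) ra <- parent[ra]
          if (ra == rb) { subsets[[si]] <- c(acc, b); placed <- TRUE; break }
          if (hasbb[ra] && hasbb[rb]) next      # backbone pair: never merge
          # only merge nodes representing the same locus: same-parent
          # pairs further than one backbone position apart arise through
          # deletion bypass edges and merging them is cycle-prone
          if (abs(rk[b] - rk[acc[1L]]) >= 1) next
          # a merge is only safe when no directed path connects the
          # candidates (else the path becomes a cycle); paths between
          # same-locus nodes stay inside a narrow rank window
          lo <- min(rk[acc], rk[b]) - 2
          hi <- max(rk[acc], rk[b]) + 2
          fw <- reach_set(succ, b, lo, hi)
          if (is.null(fw) || any(acc %in% fw)) next
          bw <- reach_set(pred, b, lo, hi)
          if (is.null(bw) || any(acc %in% bw)) next
          if (hasbb[rb] ||
              (!hasbb[ra] && (rk[rb] < rk[ra] ||
                              (rk[rb] == rk[ra] && ids[rb] < ids[ra])))) {
            tmp <- ra; ra <- rb; rb <- tmp
          }
          parent[rb] <- ra
          subsets[[si]] <- c(acc, b)
          n_union <- n_union + 1L
          placed <- TRUE
          break
        }
        if (!placed) subsets[[length(subsets) + 1L]] <- b
      }
    }
    list(parent = parent, n_union = n_union)
  }

  excluded <- rep(FALSE, length(groups))
  res <- attempt(excluded)
  if (res$n_union == 0L) return(NULL)
  root <- resolve_roots(res$parent)
  built <- rebuild_merged(graph, nodes, edges, fpos, tpos, root)
  if (!is.null(built)) return(built)

  # indirect cycle: locate the cyclic core of the rebuilt graph and retry
  # with the groups that touch it excluded (rare; repeats and cross-group
  # unions)
  for (pass in seq_len(20L)) {
    bad_roots <- cyclic_core_roots(nodes, edges, fpos, tpos, root)
    if (length(bad_roots) == 0L) bad_roots <- unique(root)
    touched <- vapply(groups, function(g) any(root[g] %in% bad_roots),
                      NA)
    new_excluded <- excluded | touched
    if (identical(new_excluded, excluded)) break
    excluded <- new_excluded
    res <- attempt(excluded)
    if (res$n_union == 0L) return(NULL)
    root <- resolve_roots(res$parent)
    built <- rebuild_merged(graph, nodes, edges, fpos, tpos, root)
    if (!is.null(built)) {
      warning(sum(excluded),
              " merge group(s) skipped to preserve acyclicity",
              call. = FALSE)
      return(built)
    }
  }
  stop("unable to simplify the graph without creating a cycle",
       call. = FALSE)
}

# combine duplicate (from, to) edge rows into one edge with summed weight
collapse_parallel_edges <- function(graph) {
  e <- graph$edges
  key <- paste0(e$from, "\r", e$to)
  if (!anyDuplicated(key)) return(graph)
  w <- rowsum(e$weight, key, reorder = FALSE)
  bb <- rowsum(as.numeric(e$is_backbone), key, reorder = FALSE)
  first <- !duplicated(key)
  graph$edges <- data.frame(from = e$from[first], to = e$to[first],
                            weight = as.numeric(w[, 1L]),
                            is_backbone = as.numeric(bb[, 1L]) > 0)
  graph
}

# roots (node positions in the pre-merge graph) belonging to the cyclic
# core of the graph implied by a node -> root mapping: self-loop roots
# plus everything Kahn peeling cannot remove
cyclic_core_roots <- function(nodes, edges, fpos, tpos, root) {
  f2 <- root[fpos]; t2 <- root[tpos]
  bad <- unique(f2[f2 == t2 & fpos != tpos])
  keep <- f2 != t2
  f2 <- f2[keep]; t2 <- t2[keep]
  np <- nrow(nodes)
  indeg <- tabulate(t2, np)
  adj <- unname(split(t2, factor(f2, levels = seq_len(np))))
  present <- rep(FALSE, np); present[unique(c(f2, t2, which(root == seq_len(np))))] <- TRUE
  alive <- sum(present)
  queue <- setdiff(which(indeg == 0L), which(!present))
  removed <- 0L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    removed <- removed + 1L
    ws <- adj[[v]]
    if (length(ws)) {
      indeg[ws] <- indeg[ws] - 1L
      queue <- c(queue, ws[indeg[ws] == 0L])
    }
  }
  core <- which(present & indeg > 0L)
  unique(c(bad, core))
}

# vectorized pointer-jumping to the union-find roots
resolve_roots <- function(parent) {
  root <- parent
  repeat {
    nxt <- parent[root]
    if (identical(nxt, root)) return(root)
    root <- nxt
  }
}

# apply a node->root mapping; returns the rebuilt graph, or NULL if the
# mapping creates a cycle
rebuild_merged <- function(graph, nodes, edges, fpos, tpos, root) {
  np <- nrow(nodes)
  keep <- which(root == seq_len(np))
  new_rank <- nodes$rank
  min_rank <- tapply(nodes$rank, root, min)
  idx <- as.integer(names(min_rank))
  nb <- is.na(nodes$backbone_index[idx])
  new_rank[idx[nb]] <- as.numeric(min_rank)[nb]  # backbone ranks are fixed
  nodes2 <- nodes[keep, , drop = FALSE]
  nodes2$rank <- new_rank[keep]

  f2 <- root[fpos]; t2 <- root[tpos]
  if (any(f2 == t2)) return(NULL)
  M <- as.numeric(np + 1L)
  key <- as.numeric(f2) * M + as.numeric(t2)
  w <- rowsum(edges$weight, key)
  bb <- rowsum(as.numeric(edges$is_backbone), key)
  k <- as.numeric(rownames(w))
  edges2 <- data.frame(from = nodes$id[as.integer(k %/% M)],
                       to = nodes$id[as.integer(k %% M)],
                       weight = as.numeric(w[, 1L]),
                       is_backbone = as.numeric(bb[, 1L]) > 0)
  g2 <- graph
  g2$nodes <- nodes2
  rownames(g2$nodes) <- NULL
  g2$edges <- edges2
  if (!validate_dag(g2)) return(NULL)
  g2
}

succ_list <- function(np, fpos, tpos) {
  unname(split(tpos, factor(fpos, levels = seq_len(np))))
}

# Kahn's algorithm on node positions; returns the order or NULL on a cycle.
# Deterministic: ready nodes seeded and successors visited in (rank, id)
# order.
topo_sort_positions <- function(nodes, edges) {
  np <- nrow(nodes)
  if (nrow(edges) == 0L)
    return(order(nodes$rank, nodes$id))
  fpos <- match(edges$from, nodes$id)
  tpos <- match(edges$to, nodes$id)
  eord <- order(fpos, nodes$rank[tpos], nodes$id[tpos])
  adj <- unname(split(tpos[eord], factor(fpos[eord], levels = seq_len(np))))
  indeg <- tabulate(tpos, np)
  ready <- which(indeg == 0L)
  ready <- ready[order(nodes$rank[ready], nodes$id[ready])]
  qv <- integer(np); qt <- length(ready)
  if (qt) qv[seq_len(qt)] <- ready
  qh <- 1L; cnt <- 0L; out <- integer(np)
  while (qh <= qt) {
    v <- qv[qh]; qh <- qh + 1L
    cnt <- cnt + 1L; out[cnt] <- v
    ws <- adj[[v]]
    if (length(ws)) {
      indeg[ws] <- indeg[ws] - 1L
      newly <- ws[indeg[ws] == 0L]
      if (length(newly)) {
        qv[qt + seq_along(newly)] <- newly
        qt <- qt + length(newly)
      }
    }
  }
  if (cnt < np) NULL else out
}

#' Validate acyclicity
#'
#' @param graph An `alignment_graph`.
#' @return TRUE if the graph has no directed cycle.
#' @export
validate_dag <- function(graph) {
  nodes <- graph$nodes; edges <- graph$edges
  if (nrow(edges) == 0L) return(TRUE)
  fpos <- match(edges$from, nodes$id)
  tpos <- match(edges$to, nodes$id)
  # fast path: all edges strictly forward in rank implies acyclicity
  if (all(nodes$rank[fpos] < nodes$rank[tpos])) return(TRUE)
  !is.null(topo_sort_positions(nodes, edges))
}

#' Export the graph as GFA1
#'
#' One segment per node (single-base sequences, `*` for the virtual
#' source/sink) and one link per edge with the supporting-read count in an
#' `RC` tag. Intended for debugging and visualisation (e.g. in Bandage).
#'
#' @param graph An `alignment_graph`.
#' @param path Output path.
#' @export
export_gfa <- function(graph, path) {
  nodes <- graph$nodes; edges <- graph$edges
  seg <- sprintf("S\t%d\t%s", nodes$id,
                 ifelse(nodes$label == "", "*", nodes$label))
  lnk <- sprintf("L\t%d\t+\t%d\t+\t0M\tRC:i:%d", edges$from, edges$to,
                 as.integer(edges$weight))
  writeLines(c("H\tVN:Z:1.0", seg, lnk), path)
  invisible(path)
}

#' Backbone node id for a backbone position
#' @param graph An `alignment_graph`.
#' @param index 0-based backbone position(s).
#' @return Node id(s).
#' @export
backbone_node_id <- function(graph, index) {
  graph$nodes$id[match(index, graph$nodes$backbone_index)]
}

#' Weight of one edge
#' @param graph An `alignment_graph`.
#' @param from,to Node ids.
#' @return The edge weight, or NA if the edge does not exist.
#' @export
edge_weight <- function(graph, from, to) {
  i <- which(graph$edges$from == from & graph$edges$to == to)
  if (length(i) == 0L) NA_real_ else sum(graph$edges$weight[i])
}

#' Total edge weight of the graph
#' @param graph An `alignment_graph`.
#' @return Sum of all edge weights.
#' @export
total_edge_weight <- function(graph) sum(graph$edges$weight)
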