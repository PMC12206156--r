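# Independent oracles and fixture builders. These stay deliberately naive
# (quadratic DP, exhaustive path enumeration) so they cannot share a bug
# with the implementation they check.

# plain quadratic Levenshtein DP
naive_edit_distance <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1L]]
  y <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(x); m <- length(y)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n
  d[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1L, j + 1L] <- min(d[i, j] + (x[i] != y[j]),
                               d[i, j + 1L] + 1L,
                               d[i + 1L, j] + 1L)
    }
  }
  d[n + 1L, m + 1L]
}

# build a bare graph object for consensus-module tests
make_test_graph <- function(labels, edges, ranks = seq_along(labels),
                            backbone_index = rep(NA_integer_,
                                                 length(labels))) {
  nodes <- data.frame(id = seq_along(labels), label = labels,
                      backbone_index = backbone_index, rank = ranks,
                      stringsAsFactors = FALSE)
  if (is.null(edges$is_backbone))
    edges$is_backbone <- rep(FALSE, nrow(edges))
  structure(list(nodes = nodes, edges = edges,
                 source_id = NA_integer_, sink_id = NA_integer_),
            class = "alignment_graph")
}

# exhaustive maximum path weight: paths may start at any node and have
# any length; weight is the sum of traversed edge weights
brute_force_max_weight <- function(graph) {
  nodes <- graph$nodes; edges <- graph$edges
  if (nrow(edges) == 0L) return(0)
  succ <- split(seq_len(nrow(edges)), match(edges$from, nodes$id))
  best <- 0
  walk <- function(node_pos, acc) {
    best <<- max(best, acc)
    es <- succ[[as.character(node_pos)]]
    for (e in es) {
      walk(match(edges$to[e], nodes$id), acc + edges$weight[e])
    }
  }
  for (v in seq_len(nrow(nodes))) walk(v, 0)
  best
}

# random DAG over <= max_nodes nodes with rank-forward edges
random_dag_fixture <- function(seed, max_nodes = 12L) {
  set.seed(seed)
  n <- sample(3:max_nodes, 1L)
  labels <- sample(c("A", "C", "G", "T", "N", ""), n, replace = TRUE)
  ranks <- sort(stats::runif(n))
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (stats::runif(1) < 0.3) { from <- c(from, i); to <- c(to, j) }
    }
  }
  if (length(from) == 0L) { from <- 1L; to <- 2L }
  edges <- data.frame(from = from, to = to,
                      weight = sample(0:5, length(from), replace = TRUE),
                      is_backbone = sample(c(TRUE, FALSE), length(from),
                                           replace = TRUE))
  make_test_graph(labels, edges, ranks)
}

# enumerate the label strings of all source-to-sink paths (small graphs)
enumerate_path_labels <- function(graph) {
  nodes <- graph$nodes; edges <- graph$edges
  succ <- split(edges$to, edges$from)
  labs <- stats::setNames(nodes$label, nodes$id)
  out <- character(0)
  walk <- function(id, acc) {
    acc <- paste0(acc, labs[[as.character(id)]])
    nxt <- succ[[as.character(id)]]
    if (id == graph$sink_id) {
      out <<- c(out, acc)
      return(invisible())
    }
    for (w in nxt) walk(w, acc)
  }
  walk(graph$source_id, "")
  out
}

# small simulated assembly scenario shared by several tests
small_scenario <- function(n = 2000L, coverage = 25, read_len = 500L,
                           divergence = 0.07, seed = 42L) {
  truth <- random_genome(n, seed = seed)
  backbone <- mutate_genome(truth, divergence, seed = seed + 1L)
  cfg <- sim_config(genome_length = n, backbone_divergence = divergence,
                    coverage = coverage, mean_read_length = read_len,
                    seed = seed + 2L)
  sim <- simulate_reads(truth, cfg)
  list(truth = truth, backbone = backbone, sim = sim, config = cfg)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
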