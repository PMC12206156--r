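#' Assembly configuration
#'
#' @param max_iterations Iteration cap for the refinement loop (>= 1).
#'   Convergence typically takes 3-4 iterations; 10 is a generous guard.
#' @param aligner `"builtin"` for the package's seed-and-extend banded
#'   aligner (no external binaries), or `"external"` to consume SAM from
#'   `sam_path` or from running `aligner_cmd`.
#' @param aligner_cmd Command template for external mode with placeholders
#'   `{ref}`, `{reads}`, `{sam}` (e.g.
#'   `"minimap2 -a {ref} {reads} > {sam}"`).
#' @param sam_path Precomputed SAM/BAM against the *initial* backbone.
#'   Only usable for a single pass: later iterations change the backbone,
#'   so iterative runs need `aligner_cmd` or the builtin aligner.
#' @param trim_unsupported_ends Trim leading/trailing consensus nodes
#'   joined only by zero-weight (read-unsupported) edges from the final
#'   genome. Off by default: untrimmed output mirrors the backbone at
#'   uncovered ends.
#' @param min_read_length Reads shorter than this are dropped.
#' @param seed Seed for any randomized component.
#' @param seed_kmer Seed k-mer size of the builtin aligner.
#' @param verbose Log per-iteration summaries to stderr.
#' @return An `assembly_config` object.
#' @export
assembly_config <- function(max_iterations = 10L,
                            aligner = c("builtin", "external"),
                            aligner_cmd = NULL,
                            sam_path = NULL,
                            trim_unsupported_ends = FALSE,
                            min_read_length = 0L,
                            seed = 1L,
                            seed_kmer = 13L,
                            verbose = FALSE) {
  aligner <- match.arg(aligner)
  if (max_iterations < 1L) stop("max_iterations must be >= 1", call. = FALSE)
  structure(list(max_iterations = as.integer(max_iterations),
                 aligner = aligner, aligner_cmd = aligner_cmd,
                 sam_path = sam_path,
                 trim_unsupported_ends = isTRUE(trim_unsupported_ends),
                 min_read_length = as.integer(min_read_length),
                 seed = as.integer(seed),
                 seed_kmer = as.integer(seed_kmer),
                 verbose = isTRUE(verbose)),
            class = "assembly_config")
}

#' Align reads to a backbone
#'
#' Builtin mode: exact k-mer seeds on both strands locate each read on the
#' backbone (densest diagonal cluster wins; falls back to shorter seeds
#' for divergent backbones), then a banded alignment with match +1,
#' mismatch -2, gap -2 and free end gaps on the backbone side produces the
#' CIGAR. External mode consumes SAM (see [assembly_config]). Reads that
#' cannot be seeded are dropped with a warning; zero aligned reads is an
#' error, since the method has no signal without alignments.
#'
#' @param reads List of [seq_record]s.
#' @param backbone A [seq_record].
#' @param config An [assembly_config].
#' @return List of [read_alignment]s.
#' @export
align_reads <- function(reads, backbone, config = assembly_config()) {
  stopifnot(inherits(backbone, "seq_record"))
  alns <- if (config$aligner == "external" && !is.null(config$sam_path)) {
    read_sam(config$sam_path, backbone$id)
  } else {
    if (length(reads) == 0L) stop("empty read set", call. = FALSE)
    keep <- vapply(reads, function(r) nchar(r$sequence), 0L) >=
      config$min_read_length
    reads <- reads[keep]
    if (length(reads) == 0L)
      stop("all reads shorter than min_read_length", call. = FALSE)
    if (config$aligner == "external")
      align_reads_external(reads, backbone, config)
    else
      align_reads_builtin(reads, backbone, config)
  }
  if (length(alns) == 0L)
    stop("zero reads aligned to the backbone; the alignment graph would ",
         "carry no signal", call. = FALSE)
  alns
}

align_reads_external <- function(reads, backbone, config) {
  if (!is.null(config$sam_path))
    return(read_sam(config$sam_path, backbone$id))
  if (is.null(config$aligner_cmd))
    stop("external aligner mode needs sam_path or aligner_cmd",
         call. = FALSE)
  exe <- strsplit(config$aligner_cmd, "\\s+")[[1L]][1L]
  if (!nzchar(Sys.which(exe)))
    stop("external aligner '", exe, "' not found on PATH; install it or ",
         "use aligner = \"builtin\"", call. = FALSE)
  ref <- tempfile(fileext = ".fasta")
  rds <- tempfile(fileext = ".fasta")
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(c(ref, rds, sam)))
  write_fasta(backbone, ref)
  write_fasta(reads, rds)
  cmd <- config$aligner_cmd
  cmd <- gsub("{ref}", ref, cmd, fixed = TRUE)
  cmd <- gsub("{reads}", rds, cmd, fixed = TRUE)
  cmd <- gsub("{sam}", sam, cmd, fixed = TRUE)
  status <- system(cmd)
  if (status != 0L)
    stop("external aligner exited with status ", status, call. = FALSE)
  read_sam(sam, backbone$id)
}

# seed hits of `seqs` k-mers (sampled every `stride` positions) against a
# backbone k-mer table; returns the densest diagonal cluster per sequence
seed_cluster <- function(seq, bkmers, k, stride) {
  len <- nchar(seq)
  if (len < k) return(NULL)
  ps <- seq.int(1L, len - k + 1L, by = stride)
  t <- match(substring(seq, ps, ps + k - 1L), bkmers)
  ok <- !is.na(t)
  if (!any(ok)) return(NULL)
  t <- t[ok]; p <- ps[ok]
  d <- t - p
  tol <- max(30L, round(0.05 * len))
  o <- order(d)
  sd <- d[o]
  hi <- findInterval(sd + 2L * tol, sd)
  size <- hi - seq_along(sd) + 1L
  best <- which.max(size)
  sel <- o[best:hi[best]]
  list(support = size[best], t = t[sel], p = p[sel])
}

align_reads_builtin <- function(reads, backbone, config) {
  bb <- backbone$sequence
  n <- nchar(bb)
  ks <- unique(pmin(c(config$seed_kmer, 11L, 9L), max(4L, n - 1L)))
  kindex <- lapply(ks, function(k) substring(bb, 1:(n - k + 1L),
                                             k:n))
  names(kindex) <- as.character(ks)
  out <- vector("list", length(reads))
  n_dropped <- 0L
  for (i in seq_along(reads)) {
    rd <- reads[[i]]
    fwd <- rd$sequence
    rev <- revcomp(fwd)
    hit <- NULL
    for (k in ks) {
      stride <- max(1L, k %/% 4L)
      cf <- seed_cluster(fwd, kindex[[as.character(k)]], k, stride)
      cr <- seed_cluster(rev, kindex[[as.character(k)]], k, stride)
      sf <- if (is.null(cf)) 0L else cf$support
      sr <- if (is.null(cr)) 0L else cr$support
      if (sf == 0L && sr == 0L) next
      if (sf >= 2L * sr) {
        hit <- list(one = list(strand = "+", cl = cf))
      } else if (sr >= 2L * sf) {
        hit <- list(one = list(strand = "-", cl = cr))
      } else {
        hit <- list(one = list(strand = "+", cl = cf),
                    two = list(strand = "-", cl = cr))
      }
      break
    }
    if (is.null(hit)) { n_dropped <- n_dropped + 1L; next }
    best <- NULL
    for (h in hit) {
      a <- banded_extend(if (h$strand == "+") fwd else rev, bb, h$cl)
      if (is.null(a)) next
      if (is.null(best) || a$score > best$score) {
        best <- a; best$strand <- h$strand
      }
    }
    if (is.null(best)) { n_dropped <- n_dropped + 1L; next }
    out[[i]] <- read_alignment(
      read_id = rd$id, target_start = best$target_start,
      strand = best$strand,
      cigar = list(ops = best$ops, lens = best$lens),
      read_sequence = if (best$strand == "+") fwd else rev,
      is_primary = TRUE)
  }
  if (n_dropped > 0L)
    warning(n_dropped, " read(s) could not be seeded on the backbone and ",
            "were dropped", call. = FALSE)
  Filter(Negate(is.null), out)
}

# Left-align indels against the local context (the canonical placement
# used across read mappers): a gap run shifts left over an equal flanking
# base without changing the alignment score. Consistent placement matters
# for the graph: reads sharing an indel must support the *same* bypass or
# insertion-chain edges, otherwise their weight scatters across repeat
# copies.
normalize_indels <- function(ops, lens, rchars, tchars) {
  colop <- rep.int(ops, lens)
  qcons <- colop %in% c("=", "X", "M", "I")
  tcons <- colop %in% c("=", "X", "M", "D")
  arow <- rep(NA_character_, length(colop))
  brow <- rep(NA_character_, length(colop))
  arow[qcons] <- rchars[seq_len(sum(qcons))]
  brow[tcons] <- tchars[seq_len(sum(tcons))]
  gap <- colop %in% c("I", "D")
  if (any(gap)) {
    r <- rle(gap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      s <- starts[k]; e <- ends[k]
      if (any(colop[s:e] != colop[s])) next   # mixed run: leave alone
      is_del <- colop[s] == "D"
      while (s > 1L && !is.na(arow[s - 1L]) && !is.na(brow[s - 1L])) {
        if (is_del) {
          if (brow[s - 1L] != brow[e]) break
          arow[(s - 1L):e] <- c(arow[s:e], arow[s - 1L])
        } else {
          if (arow[s - 1L] != arow[e]) break
          brow[(s - 1L):e] <- c(brow[s:e], brow[s - 1L])
        }
        s <- s - 1L; e <- e - 1L
      }
    }
  }
  newop <- ifelse(!is.na(arow) & !is.na(brow),
                  ifelse(arow == brow, "=", "X"),
                  ifelse(is.na(brow), "I", "D"))
  r <- rle(newop)
  list(ops = r$values, lens = r$lengths)
}

# banded glocal extension of a read within the seed-derived window;
# scoring: match +1, mismatch -2, gap -2 (linear)
banded_extend <- function(rseq, bb, cl) {
  len <- nchar(rseq)
  n <- nchar(bb)
  pad <- max(60L, round(0.1 * len))
  est <- cl$t - cl$p + 1L
  ws <- max(1L, min(est) - pad)
  we <- min(n, max(est) + len - 1L + pad)
  win <- substr(bb, ws, we)
  m <- nchar(win)
  drift <- max(60L, round(0.1 * len))
  res <- tryCatch(
    cpp_banded_align(rseq, win, 1L, -2L, -2L,
                     dlo = -drift, dhi = (m - len) + pad + drift,
                     free_b = TRUE, traceback = TRUE),
    error = function(e) NULL)
  if (is.null(res)) return(NULL)
  rchars <- strsplit(rseq, "", fixed = TRUE)[[1L]]
  tchars <- strsplit(substr(win, res$b_start, res$b_end), "",
                     fixed = TRUE)[[1L]]
  cig <- normalize_indels(res$ops, res$lens, rchars, tchars)
  list(score = res$score,
       target_start = ws - 1L + res$b_start - 1L,
       ops = cig$ops, lens = cig$lens)
}

#' One assembly pass
#'
#' Aligns the reads to the backbone, builds and simplifies the alignment
#' graph, and extracts the maximum-weight path as the refined genome.
#'
#' @param backbone A [seq_record].
#' @param reads List of [seq_record]s.
#' @param config An [assembly_config].
#' @param alignments Optional precomputed list of [read_alignment]s
#'   (skips the aligner).
#' @return List with `genome` ([seq_record]), `path` (`genome_path`),
#'   `graph` (the simplified `alignment_graph`) and `n_aligned`.
#' @export
assemble_once <- function(backbone, reads, config = assembly_config(),
                          alignments = NULL) {
  if (is.null(alignments))
    alignments <- align_reads(reads, backbone, config)
  graph <- init_backbone_graph(backbone)
  graph <- thread_alignments(graph, alignments)
  graph <- simplify_graph(graph)
  path <- max_weight_path(graph)
  genome <- path_sequence(path, id = "consensus")
  list(genome = genome, path = path, graph = graph,
       n_aligned = length(alignments))
}

#' Iterative reference-guided assembly
#'
#' Runs [assemble_once()] repeatedly, feeding each refined genome back as
#' the backbone. Iteration stops when the genome obtained from the current
#' iteration is identical to the genome from the previous iteration
#' (fixpoint), when a genome repeats a non-adjacent earlier iterate
#' (oscillation; the highest-weight iterate is returned), or at
#' `max_iterations`.
#'
#' @param backbone Initial backbone ([seq_record]): a related strain's
#'   genome or a de novo draft.
#' @param reads List of [seq_record]s.
#' @param config An [assembly_config].
#' @return An `assembly_result` with `final_genome`, per-iteration
#'   `iterations` (sequence, path weight, edit distance to the previous
#'   iterate), `converged`, `stop_reason` and `n_iterations`.
#' @export
assemble <- function(backbone, reads, config = assembly_config()) {
  stopifnot(inherits(backbone, "seq_record"))
  if (!is.null(config$sam_path) && config$max_iterations > 1L &&
      is.null(config$aligner_cmd) && config$aligner == "external")
    config$max_iterations <- 1L  # a fixed SAM cannot follow a new backbone
  prev <- backbone
  history <- list()
  seqs <- character(0)
  stop_reason <- "max_iterations"
  converged <- FALSE
  last <- NULL
  for (it in seq_len(config$max_iterations)) {
    last <- assemble_once(prev, reads, config)
    genome <- last$genome
    genome$id <- sprintf("iteration_%d", it)
    ed <- edit_distance(prev$sequence, genome$sequence)
    history[[it]] <- list(sequence = genome$sequence,
                          weight = last$path$total_weight,
                          edit_to_prev = ed,
                          n_nodes = nrow(last$graph$nodes),
                          n_edges = nrow(last$graph$edges))
    if (config$verbose)
      message(sprintf(
        "iteration %d: %d nodes, %d edges, path weight %d, %d bp, edit to previous %d",
        it, nrow(last$graph$nodes), nrow(last$graph$edges),
        as.integer(last$path$total_weight), nchar(genome$sequence), ed))
    seqs[it] <- genome$sequence
    if (it >= 2L && seqs[it] == seqs[it - 1L]) {
      stop_reason <- "fixpoint"; converged <- TRUE
      break
    }
    if (it >= 3L && genome$sequence %in% seqs[seq_len(it - 2L)]) {
      stop_reason <- "oscillation"
      break
    }
    prev <- genome
  }
  n_it <- length(history)
  final_seq <- if (stop_reason == "oscillation") {
    ws <- vapply(history, `[[`, 0, "weight")
    history[[which.max(ws)]]$sequence
  } else {
    history[[n_it]]$sequence
  }
  if (config$trim_unsupported_ends && final_seq == seqs[n_it])
    final_seq <- trim_zero_support(last$path, last$graph)
  structure(list(final_genome = seq_record("final", final_seq),
                 iterations = history,
                 converged = converged,
                 stop_reason = stop_reason,
                 n_iterations = n_it),
            class = "assembly_result")
}

# drop leading/trailing path nodes connected only through zero-weight edges
trim_zero_support <- function(path, graph) {
  ids <- path$node_ids
  if (length(ids) < 2L) return(path$sequence)
  w <- mapply(function(a, b) edge_weight(graph, a, b),
              ids[-length(ids)], ids[-1L])
  nz <- which(w > 0)
  if (length(nz) == 0L) return(path$sequence)
  keep <- ids[nz[1L]:(nz[length(nz)] + 1L)]
  labs <- graph$nodes$label[match(keep, graph$nodes$id)]
  paste(labs[labs != ""], collapse = "")
}

#' Polish a draft assembly
#'
#' Identical algorithm to [assemble()] with the draft as the initial
#' backbone — the polishing mode of the method; short accurate reads work
#' the same way as long reads.
#'
#' @inheritParams assemble
#' @param draft Draft genome to polish ([seq_record]).
#' @return An `assembly_result` (with `mode = "polish"`).
#' @export
polish <- function(draft, reads, config = assembly_config()) {
  res <- assemble(draft, reads, config)
  res$mode <- "polish"
  res
}

#' @export
print.assembly_result <- function(x, ...) {
  cat(sprintf("<assembly_result> %d bp after %d iteration(s); %s%s\n",
              nchar(x$final_genome$sequence), x$n_iterations,
              if (x$converged) "converged (fixpoint)" else
                paste0("stopped: ", x$stop_reason),
              if (!is.null(x$mode)) paste0(" [", x$mode, "]") else ""))
  for (i in seq_along(x$iterations)) {
    h <- x$iterations[[i]]
    cat(sprintf("  iteration %d: %d bp, path weight %d, edit to previous %d\n",
                i, nchar(h$sequence), as.integer(h$weight),
                h$edit_to_prev))
  }
  invisible(x)
}
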