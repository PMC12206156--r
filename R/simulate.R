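# evaluate an expression under a fixed RNG seed, restoring global RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Parameters of the seeded read simulator. Per-read identity is drawn
#' from a normal distribution truncated above at `identity_max` and below
#' at `2 * identity_mean - identity_max` (so the mean is preserved), and is
#' interpreted as `1 - edits / read length`. Read lengths are normal,
#' clipped to `[min_read_length, genome length]`.
#'
#' `placement` controls where reads come from on a linear genome:
#' `"overhang"` (default) samples fragment positions uniformly with
#' overhang beyond both genome ends, truncating at the boundary — the
#' terminal fragments of a fragmented linear molecule, which keeps
#' coverage near-uniform up to the very ends; `"contained"` restricts
#' reads to lie fully inside the genome, which leaves a coverage ramp of
#' roughly one read length at each end.
#'
#' @param genome_length Truth genome length in bases.
#' @param backbone_divergence Fraction of bases substituted to derive the
#'   backbone from the truth (e.g. 0.15).
#' @param coverage Target fold-coverage; reads are generated until total
#'   read bases reach `coverage * genome_length`.
#' @param mean_read_length,read_length_sd Read length distribution in
#'   bases; `read_length_sd` defaults to a quarter of the mean.
#' @param identity_mean,identity_max,identity_sd Percent identity
#'   distribution, e.g. `(95, 99, 2.5)`.
#' @param error_mix Proportions of substitution/insertion/deletion among
#'   errors; must sum to 1.
#' @param seed Integer seed; every simulator output is a pure function of
#'   its inputs and this seed.
#' @param placement `"overhang"` or `"contained"` (see Details).
#' @param min_read_length Smallest read (or visible truncated fragment)
#'   kept, in bases.
#' @return A `sim_config` object.
#' @export
sim_config <- function(genome_length = 10000L,
                       backbone_divergence = 0.07,
                       coverage = 50,
                       mean_read_length = 2000L,
                       read_length_sd = NULL,
                       identity_mean = 95,
                       identity_max = 99,
                       identity_sd = 2.5,
                       error_mix = c(substitution = 0.4,
                                     insertion = 0.2,
                                     deletion = 0.4),
                       seed = 1L,
                       placement = c("overhang", "contained"),
                       min_read_length = 200L) {
  placement <- match.arg(placement)
  if (is.null(read_length_sd)) read_length_sd <- mean_read_length / 4
  stopifnot(genome_length >= 1,
            backbone_divergence >= 0, backbone_divergence < 1,
            coverage > 0,
            identity_mean <= identity_max, identity_max <= 100,
            identity_sd >= 0, read_length_sd >= 0,
            length(error_mix) == 3L)
  if (abs(sum(error_mix) - 1) > 1e-8)
    stop("error_mix must sum to 1", call. = FALSE)
  if (mean_read_length < min_read_length)
    stop("mean_read_length must be >= min_read_length", call. = FALSE)
  structure(list(genome_length = as.integer(genome_length),
                 backbone_divergence = backbone_divergence,
                 coverage = coverage,
                 mean_read_length = as.integer(mean_read_length),
                 read_length_sd = read_length_sd,
                 identity_mean = identity_mean,
                 identity_max = identity_max,
                 identity_sd = identity_sd,
                 error_mix = unname(error_mix),
                 seed = as.integer(seed),
                 placement = placement,
                 min_read_length = as.integer(min_read_length)),
            class = "sim_config")
}

#' Random genome
#'
#' I.i.d. uniform A/C/G/T sequence, reproducible per seed. Stands in for a
#' real viral strain genome in desk-scale experiments.
#'
#' @param length Genome length (>= 1).
#' @param seed Integer seed.
#' @param id Record identifier.
#' @return A [seq_record].
#' @export
random_genome <- function(length, seed = 1L, id = "truth") {
  if (length < 1L) stop("genome length must be >= 1", call. = FALSE)
  with_seed(seed, {
    seq_record(id, paste(sample(DNA_BASES, length, replace = TRUE),
                         collapse = ""))
  })
}

#' Derive a divergent backbone by random substitution
#'
#' Substitutes exactly `round(divergence * n)` positions, chosen without
#' replacement, each to a different base — emulating backbones created by
#' randomly replacing a stated percentage of a genome. The edit log is
#' attached as attribute `"mutations"`.
#'
#' @param truth A [seq_record].
#' @param divergence Fraction of bases to substitute (0 <= d < 1).
#' @param seed Integer seed.
#' @return A [seq_record] with attribute `mutations` (data frame with
#'   1-based `pos`, `ref`, `alt`).
#' @export
mutate_genome <- function(truth, divergence, seed = 1L) {
  stopifnot(inherits(truth, "seq_record"),
            divergence >= 0, divergence < 1)
  n <- nchar(truth$sequence)
  k <- round(divergence * n)
  with_seed(seed, {
    chars <- seq_chars(truth)
    pos <- sort(sample.int(n, k))
    alt <- vapply(pos, function(p)
      sample(setdiff(DNA_BASES, chars[p]), 1L), "")
    log <- data.frame(pos = pos, ref = chars[pos], alt = alt,
                      stringsAsFactors = FALSE)
    chars[pos] <- alt
    out <- seq_record(paste0(truth$id, "_divergent"),
                      paste(chars, collapse = ""))
    attr(out, "mutations") <- log
    out
  })
}

# normal draw truncated to [lo, hi] by rejection (deterministic per seed)
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  stopifnot(lo <= hi)
  out <- stats::rnorm(n, mean, sd)
  for (i in seq_len(1000L)) {
    bad <- out < lo | out > hi
    if (!any(bad)) return(out)
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(out, lo), hi)
}

#' Simulate long reads
#'
#' Draws reads from a truth genome until total read bases reach
#' `coverage * genome length`. Each read has a normal length, a
#' truncated-normal percent identity realised as `round((1 - id) * len)`
#' uniformly placed errors typed by `error_mix`, and a fair-coin strand
#' (minus-strand reads are stored reverse-complemented, as sequenced).
#'
#' @param truth A [seq_record].
#' @param config A [sim_config].
#' @return A list with `reads` (list of [seq_record]), `placements` (data
#'   frame: `read_id`, `start`, `end` — 1-based inclusive truth interval —
#'   `strand`, `identity` (realised percent), `length`), and `edits` (per
#'   read, the edit operations applied to the plus-strand fragment; with
#'   `placements` this reconstructs every read exactly).
#' @export
simulate_reads <- function(truth, config = sim_config()) {
  stopifnot(inherits(truth, "seq_record"), inherits(config, "sim_config"))
  n <- nchar(truth$sequence)
  if (config$mean_read_length < 200L)
    stop("mean read length must be >= 200", call. = FALSE)
  if (n < config$min_read_length)
    stop("genome shorter than min_read_length", call. = FALSE)
  target <- config$coverage * n
  id_lo <- 2 * config$identity_mean - config$identity_max
  with_seed(config$seed, {
    reads <- list(); plc <- list(); edits <- list()
    total <- 0; i <- 0L
    while (total < target) {
      len <- as.integer(round(stats::rnorm(1, config$mean_read_length,
                                           config$read_length_sd)))
      len <- min(max(len, config$min_read_length), n)
      if (config$placement == "overhang") {
        fstart <- sample.int(n + len - 1L, 1L) - len + 1L
        start <- max(1L, fstart)
        end <- min(n, fstart + len - 1L)
        if (end - start + 1L < config$min_read_length) next
      } else {
        start <- sample.int(n - len + 1L, 1L)
        end <- start + len - 1L
      }
      i <- i + 1L
      frag <- substr(truth$sequence, start, end)
      identity <- rtrunc_norm(1, config$identity_mean, config$identity_sd,
                              id_lo, config$identity_max)
      mut <- mutate_fragment(frag, identity, config$error_mix)
      strand <- if (stats::runif(1) < 0.5) "-" else "+"
      seqstr <- if (strand == "-") revcomp(mut$sequence) else mut$sequence
      rid <- sprintf("read_%05d", i)
      reads[[i]] <- seq_record(rid, seqstr)
      plc[[i]] <- data.frame(read_id = rid, start = start, end = end,
                             strand = strand,
                             identity = mut$realized_identity,
                             length = nchar(seqstr),
                             stringsAsFactors = FALSE)
      edits[[rid]] <- mut$edits
      total <- total + nchar(seqstr)
    }
    list(reads = reads, placements = do.call(rbind, plc), edits = edits)
  })
}

# apply round((1 - identity/100) * len) random edits to a fragment
mutate_fragment <- function(frag, identity_pct, error_mix) {
  len <- nchar(frag)
  n_err <- min(round((1 - identity_pct / 100) * len), len)
  chars <- strsplit(frag, "", fixed = TRUE)[[1L]]
  if (n_err == 0L) {
    return(list(sequence = frag, realized_identity = 100,
                edits = data.frame(pos = integer(0), type = character(0),
                                   base = character(0),
                                   stringsAsFactors = FALSE)))
  }
  pos <- sample.int(len, n_err)
  type <- sample(c("substitution", "insertion", "deletion"), n_err,
                 replace = TRUE, prob = error_mix)
  base <- character(n_err)
  ord <- order(pos, decreasing = TRUE)
  for (j in ord) {
    p <- pos[j]
    if (type[j] == "substitution") {
      base[j] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
      chars[p] <- base[j]
    } else if (type[j] == "insertion") {
      base[j] <- sample(DNA_BASES, 1L)
      chars <- append(chars, base[j], after = p)
    } else {
      base[j] <- NA_character_
      chars <- chars[-p]
    }
  }
  list(sequence = paste(chars, collapse = ""),
       realized_identity = 100 * (1 - n_err / len),
       edits = data.frame(pos = pos, type = type, base = base,
                          stringsAsFactors = FALSE))
}

# reconstruct a read from the truth genome and its placement + edit log
# (round-trip audit used by the tests)
reconstruct_read <- function(truth, placement_row, edits) {
  frag <- substr(truth$sequence, placement_row$start, placement_row$end)
  chars <- strsplit(frag, "", fixed = TRUE)[[1L]]
  if (nrow(edits)) {
    ord <- order(edits$pos, decreasing = TRUE)
    for (j in ord) {
      p <- edits$pos[j]
      if (edits$type[j] == "substitution") chars[p] <- edits$base[j]
      else if (edits$type[j] == "insertion")
        chars <- append(chars, edits$base[j], after = p)
      else chars <- chars[-p]
    }
  }
  s <- paste(chars, collapse = "")
  if (placement_row$strand == "-") revcomp(s) else s
}

#' Simulate accurate short reads
#'
#' Uniform substrings in a stated length range with an optional
#' substitution error rate, both strands — the short-read regime used for
#' polishing drafts.
#'
#' @param truth A [seq_record].
#' @param coverage Target fold-coverage.
#' @param read_length_range Two integers, e.g. `c(200, 300)`.
#' @param seed Integer seed.
#' @param error_rate Per-base substitution probability (default 0).
#' @param placement `"overhang"` or `"contained"` (see [sim_config]).
#' @return As [simulate_reads()].
#' @export
simulate_short_reads <- function(truth, coverage,
                                 read_length_range = c(200L, 300L),
                                 seed = 1L, error_rate = 0,
                                 placement = c("overhang", "contained")) {
  placement <- match.arg(placement)
  stopifnot(inherits(truth, "seq_record"), coverage > 0,
            length(read_length_range) == 2L,
            read_length_range[1] <= read_length_range[2],
            error_rate >= 0, error_rate < 1)
  n <- nchar(truth$sequence)
  lo <- as.integer(read_length_range[1]); hi <- as.integer(read_length_range[2])
  if (n < lo) stop("genome shorter than the minimum read length", call. = FALSE)
  target <- coverage * n
  min_keep <- min(lo, 100L)
  with_seed(seed, {
    reads <- list(); plc <- list(); edits <- list()
    total <- 0; i <- 0L
    while (total < target) {
      len <- if (lo == hi) lo else sample(lo:hi, 1L)
      len <- min(len, n)
      if (placement == "overhang") {
        fstart <- sample.int(n + len - 1L, 1L) - len + 1L
        start <- max(1L, fstart)
        end <- min(n, fstart + len - 1L)
        if (end - start + 1L < min_keep) next
      } else {
        start <- sample.int(n - len + 1L, 1L)
        end <- start + len - 1L
      }
      i <- i + 1L
      frag <- substr(truth$sequence, start, end)
      chars <- strsplit(frag, "", fixed = TRUE)[[1L]]
      n_err <- stats::rbinom(1, length(chars), error_rate)
      ed <- data.frame(pos = integer(0), type = character(0),
                       base = character(0), stringsAsFactors = FALSE)
      if (n_err > 0L) {
        pos <- sample.int(length(chars), n_err)
        base <- vapply(pos, function(p)
          sample(setdiff(DNA_BASES, chars[p]), 1L), "")
        chars[pos] <- base
        ed <- data.frame(pos = pos, type = "substitution", base = base,
                         stringsAsFactors = FALSE)
      }
      strand <- if (stats::runif(1) < 0.5) "-" else "+"
      s <- paste(chars, collapse = "")
      if (strand == "-") s <- revcomp(s)
      rid <- sprintf("sread_%06d", i)
      reads[[i]] <- seq_record(rid, s)
      plc[[i]] <- data.frame(read_id = rid, start = start, end = end,
                             strand = strand,
                             identity = 100 * (1 - n_err / nchar(frag)),
                             length = nchar(s), stringsAsFactors = FALSE)
      edits[[rid]] <- ed
      total <- total + nchar(s)
    }
    list(reads = reads, placements = do.call(rbind, plc), edits = edits)
  })
}

#' Write a read placement log as TSV
#' @param placements Data frame from [simulate_reads()].
#' @param path Output path.
#' @export
write_placements <- function(placements, path) {
  utils::write.table(placements, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
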