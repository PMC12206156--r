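# ---- banded alignment wrappers -------------------------------------------
#
# Unit-cost (Levenshtein) alignments are computed in a diagonal band that
# is widened automatically until the optimum is provably inside it: if the
# banded distance d satisfies d <= w (the slack beyond the [0, m - n]
# diagonal corridor), any optimal path deviates at most d <= w diagonals
# from the corridor and the banded result is exact.

as_dna_string <- function(x) {
  if (inherits(x, "seq_record")) x$sequence
  else if (is.character(x) && length(x) == 1L) normalize_dna(x)
  else stop("expected a seq_record or a character scalar", call. = FALSE)
}

banded_unit_align <- function(a, b, free_b = FALSE, traceback = FALSE) {
  n <- nchar(a); m <- nchar(b)
  w <- 32L
  repeat {
    dlo <- min(0L, m - n) - w
    dhi <- max(0L, m - n) + w
    full <- dlo <= -n && dhi >= m
    res <- cpp_banded_align(a, b, 0L, -1L, -1L, dlo, dhi, free_b, traceback)
    if (-res$score <= w || full) return(res)
    w <- w * 4L
  }
}

#' Edit distance
#'
#' Exact Levenshtein distance (unit-cost substitutions, insertions and
#' deletions), computed with a banded dynamic program whose band widens
#' automatically until the optimum is provably inside it.
#'
#' @param a,b [seq_record]s or character scalars.
#' @return Integer distance.
#' @examples
#' edit_distance("ACGT", "AGT")  # 1
#' @export
edit_distance <- function(a, b) {
  a <- as_dna_string(a); b <- as_dna_string(b)
  if (identical(a, b)) return(0L)
  if (!nchar(a) || !nchar(b)) return(max(nchar(a), nchar(b)))
  as.integer(-banded_unit_align(a, b)$score)
}

#' Mismatch/indel breakdown of one optimal global alignment
#'
#' Computes one optimal unit-cost global alignment of assembly against
#' truth and reports substituted columns, indel events (maximal runs of
#' gap columns) and total gap columns. By unit-cost optimality,
#' `mismatches + indel_length == edit_distance` always holds for the
#' reported alignment.
#'
#' @param assembly,truth [seq_record]s or character scalars (non-empty).
#' @return List with `mismatches`, `indels`, `indel_length`; the alignment
#'   CIGAR (ops over `=`/`X`/`I`/`D`) and the edit distance are attached
#'   as attributes `cigar` and `edit_distance`.
#' @export
alignment_breakdown <- function(assembly, truth) {
  a <- as_dna_string(assembly); b <- as_dna_string(truth)
  if (!nchar(a) || !nchar(b))
    stop("cannot align an empty sequence", call. = FALSE)
  res <- banded_unit_align(a, b, free_b = FALSE, traceback = TRUE)
  ops <- res$ops; lens <- res$lens
  gap <- ops %in% c("I", "D")
  r <- rle(gap)
  out <- list(mismatches = sum(lens[ops == "X"]),
              indels = sum(r$values),
              indel_length = sum(lens[gap]))
  attr(out, "cigar") <- list(ops = ops, lens = lens)
  attr(out, "edit_distance") <- as.integer(-res$score)
  out
}

#' Genome fraction
#'
#' Percentage of truth-genome bases lying in matched (equal, non-gap)
#' columns of an alignment in which the assembly is aligned end to end and
#' end gaps on the truth side are free — so a truncated assembly loses
#' genome fraction instead of accumulating giant indels.
#'
#' @param assembly,truth [seq_record]s or character scalars.
#' @return Percent, rounded to 3 decimals.
#' @export
genome_fraction <- function(assembly, truth) {
  a <- as_dna_string(assembly); b <- as_dna_string(truth)
  if (!nchar(a) || !nchar(b))
    stop("cannot align an empty sequence", call. = FALSE)
  res <- banded_unit_align(a, b, free_b = TRUE, traceback = TRUE)
  matched <- sum(res$lens[res$ops == "="])
  round(100 * matched / nchar(b), 3)
}

#' Similarity to a ground-truth genome
#'
#' `100 * (1 - edit_distance / truth_length)`, floored at 0.
#'
#' @param a Assembly ([seq_record] or character).
#' @param truth Ground-truth genome.
#' @return Percent.
#' @export
similarity <- function(a, truth) {
  t <- as_dna_string(truth)
  max(0, 100 * (1 - edit_distance(a, truth) / nchar(t)))
}

#' Mismatches and indels restricted to the genome interior
#'
#' Counts substituted columns and indel events of the optimal global
#' assembly-to-truth alignment whose truth coordinate lies more than
#' `trim` bases from either genome end; indel events are counted when the
#' whole gap run lies inside the interior (runs touching the trimmed ends
#' are attributed to the ends).
#'
#' @param assembly,truth [seq_record]s or character scalars.
#' @param trim Bases excluded at each truth end (default 50).
#' @return List with `mismatches`, `indels`, `indel_length`.
#' @export
interior_breakdown <- function(assembly, truth, trim = 50L) {
  b <- as_dna_string(truth)
  m <- nchar(b)
  if (m <= 2L * trim) stop("truth shorter than twice the trim", call. = FALSE)
  bd <- alignment_breakdown(assembly, truth)
  cig <- attr(bd, "cigar")
  col_op <- rep(cig$ops, cig$lens)
  tpos <- cumsum(col_op %in% c("=", "X", "D"))
  sel <- tpos > trim & tpos <= (m - trim)
  gap <- col_op %in% c("I", "D")
  r <- rle(gap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  inside <- r$values & sel[starts] & sel[ends]
  list(mismatches = sum(col_op == "X" & sel),
       indels = sum(inside),
       indel_length = sum(gap & sel))
}

#' Assembly evaluation report
#'
#' The full metric suite against a ground-truth genome: genome fraction,
#' assembly length, mismatches, indel events, indel length, edit distance
#' and similarity.
#'
#' @param assembly,truth [seq_record]s or character scalars.
#' @return An `eval_report` object.
#' @export
report <- function(assembly, truth) {
  a <- as_dna_string(assembly); b <- as_dna_string(truth)
  bd <- alignment_breakdown(a, b)
  ed <- attr(bd, "edit_distance")
  structure(list(genome_fraction = genome_fraction(a, b),
                 assembly_length = nchar(a),
                 mismatches = bd$mismatches,
                 indels = bd$indels,
                 indel_length = bd$indel_length,
                 edit_distance = ed,
                 similarity = max(0, 100 * (1 - ed / nchar(b)))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  genome fraction : %.3f%%\n", x$genome_fraction))
  cat(sprintf("  assembly length : %d\n", x$assembly_length))
  cat(sprintf("  mismatches      : %d\n", x$mismatches))
  cat(sprintf("  indels (events) : %d\n", x$indels))
  cat(sprintf("  indel length    : %d\n", x$indel_length))
  cat(sprintf("  edit distance   : %d\n", x$edit_distance))
  cat(sprintf("  similarity      : %.2f%%\n", x$similarity))
  invisible(x)
}

#' Write an evaluation report
#'
#' TSV (one header + one row) or JSON with columns `genome_fraction`,
#' `genome_length`, `mismatch`, `indels`, `indel_length`, `edit_distance`.
#'
#' @param x An `eval_report`.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_eval_report <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "eval_report"))
  row <- list(genome_fraction = x$genome_fraction,
              genome_length = x$assembly_length,
              mismatch = x$mismatches,
              indels = x$indels,
              indel_length = x$indel_length,
              edit_distance = x$edit_distance)
  if (format == "tsv") {
    utils::write.table(as.data.frame(row), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(row, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
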