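#' Sequence record
#'
#' Lightweight container for a named DNA sequence over the alphabet
#' `{A, C, G, T, N}`. All readers funnel into this constructor, which
#' uppercases the sequence and maps any other IUPAC code to `N`.
#'
#' @param id Character scalar identifier.
#' @param sequence Character scalar DNA sequence; must be non-empty.
#' @return An object of class `seq_record` with fields `id` and `sequence`.
#' @examples
#' seq_record("x", "acgt")
#' @export
seq_record <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) == 1L)
  sequence <- normalize_dna(sequence)
  if (!nzchar(sequence)) stop("sequence must be non-empty", call. = FALSE)
  structure(list(id = id, sequence = sequence), class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  n <- nchar(x$sequence)
  head <- substr(x$sequence, 1L, 60L)
  cat(sprintf("<seq_record> %s (%d bp)\n  %s%s\n", x$id, n, head,
              if (n > 60L) "..." else ""))
  invisible(x)
}

# uppercase and restrict to {A,C,G,T,N}; other IUPAC codes become N
normalize_dna <- function(x) {
  x <- toupper(x)
  gsub("[^ACGTN]", "N", x)
}

seq_chars <- function(record) strsplit(record$sequence, "", fixed = TRUE)[[1L]]

#' Reverse-complement a DNA string
#'
#' @param x Character scalar over `{A,C,G,T,N}`.
#' @return The reverse complement (N maps to N).
#' @export
revcomp <- function(x) {
  chars <- rev(strsplit(chartr("ACGTN", "TGCAN", toupper(x)), "",
                        fixed = TRUE)[[1L]])
  paste(chars, collapse = "")
}

#' Read a FASTA file
#'
#' Sequences are uppercased and IUPAC codes outside `{A,C,G,T,N}` are
#' mapped to `N`. Plain or gzip-compressed input is accepted.
#'
#' @param path Path to a FASTA file.
#' @return A list of [seq_record] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                  error = function(e)
                    stop("malformed FASTA in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (length(set) == 0L)
    stop("no FASTA records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  mapply(function(id, s) seq_record(id, s), ids, as.character(set),
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Read a FASTQ file
#'
#' Strict four-line-per-record parser; quality strings are validated
#' against the sequence length and then discarded (the assembler weighs
#' reads by count, not by base quality). gzip input is accepted.
#'
#' @param path Path to a FASTQ file (optionally gzipped).
#' @return A list of [seq_record] objects.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) == 0L) stop("empty FASTQ file: ", path, call. = FALSE)
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ record in ", path, call. = FALSE)
  i <- seq(1L, length(lines), by = 4L)
  headers <- lines[i]
  seqs <- lines[i + 1L]
  plus <- lines[i + 2L]
  quals <- lines[i + 3L]
  if (any(substr(headers, 1L, 1L) != "@"))
    stop("FASTQ header not starting with '@' in ", path, call. = FALSE)
  if (any(substr(plus, 1L, 1L) != "+"))
    stop("FASTQ separator line not starting with '+' in ", path,
         call. = FALSE)
  if (any(nchar(quals) != nchar(seqs)))
    stop("FASTQ quality string length differs from sequence length in ",
         path, call. = FALSE)
  ids <- sub("\\s.*$", "", substring(headers, 2L))
  mapply(seq_record, ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Read sequences from FASTA or FASTQ
#'
#' Dispatches on file content (first non-empty character).
#'
#' @param path Path to a FASTA or FASTQ file (optionally gzipped).
#' @return A list of [seq_record] objects.
#' @export
read_seqs <- function(path) {
  con <- gzfile(path, open = "rt")
  first <- readLines(con, n = 1L)
  close(con)
  if (length(first) && startsWith(first, "@")) read_fastq(path)
  else read_fasta(path)
}

#' Write FASTA
#'
#' @param records A list of [seq_record] objects (or a single one).
#' @param path Output path.
#' @param line_width Sequence line width.
#' @export
write_fasta <- function(records, path, line_width = 70L) {
  if (inherits(records, "seq_record")) records <- list(records)
  if (length(records) == 0L)
    stop("no records to write", call. = FALSE)
  set <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "sequence"))
  names(set) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path, width = as.integer(line_width))
  invisible(path)
}

# ---- read alignments ------------------------------------------------------

#' Read-to-backbone alignment record
#'
#' Normalized carrier for one read's placement on the backbone. The stored
#' `read_sequence` is in the aligned orientation (already reverse
#' complemented for minus-strand placements), matching SAM conventions.
#'
#' @param read_id Read identifier.
#' @param target_start 0-based offset of the first aligned base on the
#'   backbone.
#' @param strand `"+"` or `"-"`.
#' @param cigar CIGAR as a string (e.g. `"10M1I5M"`) or a list with `ops`
#'   and `lens`. Allowed ops: `M`, `=`, `X`, `I`, `D`, `S`, `H`.
#' @param read_sequence Read sequence in aligned orientation.
#' @param is_primary Primary-alignment flag.
#' @return An object of class `read_alignment`.
#' @export
read_alignment <- function(read_id, target_start, strand, cigar,
                           read_sequence, is_primary = TRUE) {
  if (is.character(cigar)) cigar <- parse_cigar(cigar)
  stopifnot(is.list(cigar), all(c("ops", "lens") %in% names(cigar)))
  if (!all(cigar$ops %in% c("M", "=", "X", "I", "D", "S", "H")))
    stop("unsupported CIGAR operation: ",
         paste(setdiff(cigar$ops, c("M", "=", "X", "I", "D", "S", "H")),
               collapse = ","), call. = FALSE)
  if (any(cigar$lens < 1L)) stop("CIGAR lengths must be >= 1", call. = FALSE)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  if (target_start < 0L) stop("target_start must be >= 0", call. = FALSE)
  read_sequence <- normalize_dna(read_sequence)
  qlen <- sum(cigar$lens[cigar$ops %in% c("M", "=", "X", "I", "S")])
  if (qlen != nchar(read_sequence))
    stop(sprintf(paste0("CIGAR consumes %d read bases but read_sequence ",
                        "has %d"), qlen, nchar(read_sequence)), call. = FALSE)
  structure(list(read_id = read_id,
                 target_start = as.integer(target_start),
                 strand = strand, cigar = cigar,
                 read_sequence = read_sequence,
                 is_primary = isTRUE(is_primary)),
            class = "read_alignment")
}

#' Parse a CIGAR string
#' @param x CIGAR string.
#' @return List with `ops` (character) and `lens` (integer).
#' @export
parse_cigar <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (x == "*" || !nzchar(x)) stop("missing CIGAR", call. = FALSE)
  toks <- regmatches(x, gregexpr("[0-9]+[MIDNSHP=X]", x))[[1L]]
  if (sum(nchar(toks)) != nchar(x))
    stop("malformed CIGAR: ", x, call. = FALSE)
  list(ops = substring(toks, nchar(toks)),
       lens = as.integer(substring(toks, 1L, nchar(toks) - 1L)))
}

#' Format a CIGAR
#' @param cigar List with `ops` and `lens`.
#' @return CIGAR string.
#' @export
cigar_string <- function(cigar) paste0(cigar$lens, cigar$ops, collapse = "")

# number of backbone bases consumed by the alignment
target_span <- function(aln) {
  sum(aln$cigar$lens[aln$cigar$ops %in% c("M", "=", "X", "D")])
}

# number of aligned (graph-visible) read bases: M/=/X/I
aligned_length <- function(aln) {
  sum(aln$cigar$lens[aln$cigar$ops %in% c("M", "=", "X", "I")])
}

#' Import read alignments from SAM/BAM
#'
#' Keeps primary mapped records aligned to `backbone_id` only; secondary,
#' supplementary and unmapped records are dropped. Records without a CIGAR
#' are skipped with a warning. SAM text input is converted with
#' [Rsamtools::asBam()] on the fly.
#'
#' @param path SAM or BAM file.
#' @param backbone_id Reference name the alignments must match.
#' @return A list of [read_alignment] objects (possibly empty).
#' @export
read_sam <- function(path, backbone_id) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flags,
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "strand"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1L]]
  keep <- !is.na(rec$rname) & as.character(rec$rname) == backbone_id
  if (!any(keep)) return(list())
  no_cigar <- keep & (is.na(rec$cigar) | rec$cigar == "*")
  if (any(no_cigar)) {
    warning(sum(no_cigar), " record(s) without CIGAR skipped",
            call. = FALSE)
    keep <- keep & !no_cigar
  }
  idx <- which(keep)
  lapply(idx, function(i) {
    read_alignment(read_id = rec$qname[i],
                   target_start = rec$pos[i] - 1L,
                   strand = if (as.character(rec$strand[i]) == "-") "-"
                            else "+",
                   cigar = rec$cigar[i],
                   read_sequence = as.character(rec$seq[i]),
                   is_primary = TRUE)
  })
}
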