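test_that("builtin aligner recovers exact and reverse-complement placements", {
  bb <- seq_record("ref", random_dna(2000, seed = 41))
  cfg <- assembly_config()

  rd <- seq_record("fwd", substr(bb$sequence, 501, 900))
  a <- align_reads(list(rd), bb, cfg)[[1]]
  expect_equal(a$target_start, 500L)
  expect_equal(a$strand, "+")
  expect_equal(a$cigar$ops, "=")
  expect_equal(a$cigar$lens, 400L)

  rc <- seq_record("rev", revcomp(substr(bb$sequence, 501, 900)))
  a2 <- align_reads(list(rc), bb, cfg)[[1]]
  expect_equal(a2$strand, "-")
  expect_equal(a2$target_start, 500L)
  # stored in aligned orientation
  expect_equal(a2$read_sequence, substr(bb$sequence, 501, 900))
})

test_that("noisy reads align back to their true intervals", {
  truth <- random_genome(3000, seed = 43)
  cfg <- sim_config(genome_length = 3000, coverage = 4,
                    mean_read_length = 500, identity_mean = 95,
                    identity_max = 99, identity_sd = 2.5, seed = 44)
  sim <- simulate_reads(truth, cfg)
  alns <- align_reads(sim$reads, truth, assembly_config())
  ids <- vapply(alns, `[[`, "", "read_id")
  ok <- 0L
  for (i in seq_along(alns)) {
    p <- sim$placements[sim$placements$read_id == ids[i], ]
    span <- sum(alns[[i]]$cigar$lens[alns[[i]]$cigar$ops %in%
                                       c("M", "=", "X", "D")])
    a0 <- alns[[i]]$target_start
    ovl <- min(a0 + span, p$end) - max(a0, p$start - 1L)
    if (alns[[i]]$strand == p$strand && ovl >= 0.9 * (p$end - p$start + 1L))
      ok <- ok + 1L
  }
  expect_gte(ok / length(alns), 0.9)
})

test_that("aligner edge cases: dropped short reads and unalignable sets", {
  bb <- seq_record("ref", random_dna(1000, seed = 45))
  reads <- list(seq_record("long", substr(bb$sequence, 101, 400)),
                seq_record("tiny", "ACGTAC"))
  cfg <- assembly_config(min_read_length = 50L)
  alns <- align_reads(reads, bb, cfg)
  expect_length(alns, 1L)
  # nothing alignable at all -> error, with a warning about seeding
  unseedable <- list(seq_record("t1", "ACGTAC"), seq_record("t2", "GGTTAA"))
  expect_error(
    suppressWarnings(align_reads(unseedable, bb, assembly_config())),
    "zero reads aligned")
  expect_error(align_reads(list(), bb, cfg), "empty read set")
})

test_that("one pass reproduces the backbone from perfect tiling reads", {
  bb <- seq_record("ref", random_dna(1200, seed = 46))
  reads <- lapply(seq(1, 1000, by = 100), function(s)
    seq_record(paste0("r", s), substr(bb$sequence, s, s + 199)))
  st <- assemble_once(bb, reads, assembly_config())
  expect_identical(st$genome$sequence, bb$sequence)
})

test_that("deep read support overrides a backbone allele; gaps follow the backbone", {
  # 50 bp fixture written out by hand from the threading rules: the reads
  # all carry C at position 25 where the backbone has A; coverage 30x
  truth <- random_genome(400, seed = 47)
  chars <- strsplit(truth$sequence, "")[[1]]
  pos <- 200L
  other <- setdiff(c("A", "C", "G", "T"), chars[pos])[1]
  bchars <- chars; bchars[pos] <- other
  bb <- seq_record("bb", paste(bchars, collapse = ""))
  reads <- lapply(1:30, function(i)
    seq_record(paste0("r", i), substr(truth$sequence, 101, 300)))
  st <- assemble_once(bb, reads, assembly_config())
  out <- strsplit(st$genome$sequence, "")[[1]]
  expect_equal(out[pos], chars[pos])   # read allele, not backbone allele
  # positions without any read coverage keep the backbone
  expect_equal(substr(st$genome$sequence, 1, 100),
               substr(bb$sequence, 1, 100))
  expect_equal(substr(st$genome$sequence, 301, 400),
               substr(bb$sequence, 301, 400))
})

test_that("assembly converges and the fixpoint is sound", {
  sc <- small_scenario(n = 2000L, coverage = 25, read_len = 500L, seed = 48L)
  res <- assemble(sc$backbone, sc$sim$reads, assembly_config())
  expect_true(res$converged)
  expect_equal(res$stop_reason, "fixpoint")
  expect_lte(res$n_iterations, 4L)
  # fixpoint soundness: one more pass reproduces the final genome
  st <- assemble_once(res$final_genome, sc$sim$reads, assembly_config())
  expect_identical(st$genome$sequence, res$final_genome$sequence)
  # path weight never decreased across iterations
  w <- vapply(res$iterations, `[[`, 0, "weight")
  expect_true(all(diff(w) >= 0))
  # the two stopping iterates are identical by definition of convergence
  n <- res$n_iterations
  expect_identical(res$iterations[[n]]$sequence,
                   res$iterations[[n - 1L]]$sequence)
})

test_that("a backbone equal to the read consensus is confirmed in two passes", {
  bb <- seq_record("ref", random_dna(900, seed = 49))
  reads <- lapply(seq(1, 700, by = 50), function(s)
    seq_record(paste0("r", s), substr(bb$sequence, s, s + 199)))
  res <- assemble(bb, reads, assembly_config())
  expect_true(res$converged)
  expect_equal(res$n_iterations, 2L)  # one productive + one confirming pass
  expect_identical(res$final_genome$sequence, bb$sequence)
})

test_that("polishing corrects known draft errors with short accurate reads", {
  truth <- random_genome(1500, seed = 50)
  chars <- strsplit(truth$sequence, "")[[1]]
  errs <- c(301L, 802L, 1203L)
  draft <- chars
  for (p in errs) draft[p] <- setdiff(c("A", "C", "G", "T"), draft[p])[1]
  draft <- seq_record("draft", paste(draft, collapse = ""))
  sim <- simulate_short_reads(truth, coverage = 25,
                              read_length_range = c(200, 300), seed = 51)
  res <- polish(draft, sim$reads, assembly_config())
  expect_identical(res$final_genome$sequence, truth$sequence)
  expect_equal(res$mode, "polish")

  # an already-correct draft is left unchanged
  res2 <- polish(truth, sim$reads, assembly_config())
  expect_identical(res2$final_genome$sequence, truth$sequence)
})

test_that("iteration always terminates with a declared stop reason", {
  sc <- small_scenario(n = 600L, coverage = 10, read_len = 250L, seed = 52L)
  res <- assemble(sc$backbone, sc$sim$reads,
                  assembly_config(max_iterations = 3L))
  expect_true(res$stop_reason %in% c("fixpoint", "oscillation",
                                     "max_iterations"))
  expect_lte(res$n_iterations, 3L)
})

test_that("unsupported-end trimming cuts back to the read-covered region", {
  truth <- random_genome(1500, seed = 54)
  backbone <- mutate_genome(truth, 0.05, seed = 55)
  cfg <- sim_config(genome_length = 1500, coverage = 20,
                    mean_read_length = 300, seed = 56,
                    placement = "contained")  # leaves uncovered end ramps
  sim <- simulate_reads(truth, cfg)
  res_keep <- assemble(backbone, sim$reads, assembly_config())
  res_trim <- assemble(backbone, sim$reads,
                       assembly_config(trim_unsupported_ends = TRUE))
  expect_lt(nchar(res_trim$final_genome$sequence),
            nchar(res_keep$final_genome$sequence))
  # the trimmed genome is a substring of the untrimmed one
  expect_true(grepl(res_trim$final_genome$sequence,
                    res_keep$final_genome$sequence, fixed = TRUE))
})

test_that("a missing external aligner gives an actionable error", {
  bb <- seq_record("ref", random_dna(300, seed = 57))
  reads <- list(seq_record("r", substr(bb$sequence, 50, 200)))
  cfg <- assembly_config(aligner = "external",
                         aligner_cmd = "no-such-aligner -a {ref} {reads} > {sam}")
  expect_error(align_reads(reads, bb, cfg), "not found on PATH")
})

test_that("precomputed SAM alignments feed a single assembly pass", {
  bb <- seq_record("ref", random_dna(500, seed = 53))
  sam <- withr::local_tempfile(fileext = ".sam")
  seg <- substr(bb$sequence, 101, 300)
  writeLines(c("@HD\tVN:1.6",
               "@SQ\tSN:ref\tLN:500",
               paste("r1", 0, "ref", 101, 60, "200M", "*", 0, 0, seg,
                     strrep("I", 200), sep = "\t")), sam)
  cfg <- assembly_config(aligner = "external", sam_path = sam)
  res <- assemble(bb, list(), cfg)
  expect_identical(res$final_genome$sequence, bb$sequence)
})
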