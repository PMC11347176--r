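test_that("FASTQ and FASTA writers round-trip through the readers", {
  reads <- tibble::tibble(id = c("r1", "r2"),
                          sequence = c("ACGTACGT", "TTGCAATC"),
                          quality = c("IIIIIIII", "ABCDEFGH"))
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  expect_identical(read_fastq(fq), reads)

  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(reads, fa)
  expect_identical(read_fasta(fa), reads[, c("id", "sequence")])

  empty <- withr::local_tempfile()
  file.create(empty)
  expect_identical(nrow(read_fastq(empty)), 0L)
})

test_that("malformed FASTQ records raise parse errors naming the line", {
  bad <- withr::local_tempfile()
  writeLines(c("@r1", "ACGT", "+", "III"), bad)  # quality too short
  expect_error(read_fastq(bad), "line 4")

  bad2 <- withr::local_tempfile()
  writeLines(c("@r1", "ACGT", "III", "IIII"), bad2)  # missing separator
  expect_error(read_fastq(bad2), "separator at line 3")

  bad3 <- withr::local_tempfile()
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), bad3)
  expect_error(read_fastq(bad3), "line 5")
})

test_that("phred scores decode Phred+33", {
  expect_equal(phred_scores("!I5")[[1]], c(0L, 40L, 20L))
})

test_that("clip_and_orient recovers the insert in both orientations", {
  fwd <- "ACGTACGTAC"
  rev <- "TGCATGCATG"
  insert <- "GGGAAATTTCCC"
  read <- paste0(fwd, insert, revcomp(rev))
  reads <- tibble::tibble(id = c("f", "r"),
                          sequence = c(read, revcomp(read)))
  out <- clip_and_orient(reads, fwd, rev, max_mismatch = 0)
  expect_equal(out$status, c("ok", "ok"))
  expect_equal(out$sequence, c(insert, insert))
  expect_equal(out$orientation, c("forward", "reverse"))
})

test_that("primer matching is a Hamming-distance test, checked by enumeration", {
  fwd <- "ACGTACGTAC"
  rev <- "TGCATGCATG"
  insert <- "GGGAAATTTCCC"
  # every single substitution in the forward primer passes at max_mismatch=1
  # and fails at 0
  for (pos in seq_len(nchar(fwd))) {
    orig <- substr(fwd, pos, pos)
    alt <- setdiff(c("A", "C", "G", "T"), orig)[[1]]
    read <- paste0(substitute_base(fwd, pos, alt), insert, revcomp(rev))
    r <- tibble::tibble(id = "x", sequence = read)
    expect_equal(clip_and_orient(r, fwd, rev, max_mismatch = 1)$sequence,
                 insert)
    expect_equal(clip_and_orient(r, fwd, rev, max_mismatch = 0)$status,
                 "no_fwd_primer")
  }
  # a primer longer than the read rejects rather than errors
  short <- tibble::tibble(id = "s", sequence = "ACGT")
  expect_equal(clip_and_orient(short, fwd, rev)$status,
               "primer_longer_than_read")
})

test_that("clipping its own output rejects (primers are gone)", {
  fwd <- "ACGTACGTAC"
  rev <- "TGCATGCATG"
  insert <- "GGGAAATTTCCCGGGAAATTTCCCGGG"  # longer than both primers
  read <- tibble::tibble(id = "x", sequence = paste0(fwd, insert,
                                                     revcomp(rev)))
  once <- clip_and_orient(read, fwd, rev, max_mismatch = 0)
  again <- clip_and_orient(once[once$status == "ok", ], fwd, rev,
                           max_mismatch = 0)
  expect_equal(again$status, "no_fwd_primer")
})

test_that("merge_pairs merges exact overlaps with the expected arithmetic", {
  r1 <- list(sequence = "AAAACCCCGGGGTTTTACGTACGTACGT")  # 28 nt
  ov <- 20L
  suffix <- substr(r1$sequence, nchar(r1$sequence) - ov + 1L,
                   nchar(r1$sequence))
  r2 <- list(sequence = revcomp(paste0(suffix, "GATTACA")))  # 27 nt
  m <- merge_pairs(r1, r2, min_overlap = 10)
  expect_equal(m$status, "ok")
  expect_equal(nchar(m$sequence), 28L + 27L - 20L)
  expect_equal(m$overlap, 20L)

  # full-overlap self pair returns r1 exactly
  self <- merge_pairs(r1, list(sequence = revcomp(r1$sequence)),
                      min_overlap = 5)
  expect_equal(self$sequence, r1$sequence)

  # disjoint reads are rejected
  far <- merge_pairs(list(sequence = "AAAAAAAAAAAA"),
                     list(sequence = "CCCCCCCCCCCC"), min_overlap = 6)
  expect_equal(far$status, "no_overlap")
})

test_that("merge_pairs resolves overlap disagreements by quality", {
  # 12-nt reads, full 12-nt overlap, one disagreement at position 6
  s1 <- "ACGTACGTACGT"
  s2 <- revcomp(substitute_base(s1, 6, "G"))  # r2 says G at position 6
  q_low <- paste(rep("#", 12), collapse = "")   # Phred 2
  q_high <- paste(rep("I", 12), collapse = "")  # Phred 40
  m <- merge_pairs(list(sequence = s1, quality = q_low),
                   list(sequence = s2, quality = q_high),
                   min_overlap = 12, max_mismatch_frac = 0.2)
  expect_equal(substr(m$sequence, 6, 6), "G")
  m2 <- merge_pairs(list(sequence = s1, quality = q_high),
                    list(sequence = s2, quality = q_low),
                    min_overlap = 12, max_mismatch_frac = 0.2)
  expect_equal(substr(m2$sequence, 6, 6), "C")
})

test_that("filter_and_count counts, drops N, and keeps the modal length", {
  tab <- filter_and_count(c("ACGT", "ACGT", "ACGA"), 4, 4)
  expect_equal(tab$sequence, c("ACGT", "ACGA"))
  expect_equal(tab$count, c(2L, 1L))
  expect_equal(attr(tab, "total_reads"), 3L)

  withN <- filter_and_count(c("ACGT", "ACNT"), 4, 4)
  expect_equal(attr(withN, "total_reads"), 1L)

  mixed <- c(rep("ACGTA", 90), rep("ACGT", 10))
  tabm <- filter_and_count(mixed, 4, 5)
  expect_equal(attr(tabm, "seq_length"), 5L)
  expect_equal(sum(tabm$count), 90L)
  # read conservation: kept + rejected = input
  expect_equal(attr(tabm, "total_reads") + attr(tabm, "n_rejected"), 100L)

  expect_warning(out <- filter_and_count(c("NNNN"), 4, 4), "filtered")
  expect_equal(nrow(out), 0L)
})

test_that("sequence tables round-trip through TSV with provenance comments", {
  tab <- tibble::tibble(sequence = c("ACGT", "AAAA"), count = c(5L, 2L))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_seq_table(tab, p, comments = c("demo", "seed: 1"))
  back <- read_seq_table(p)
  expect_equal(back$sequence, tab$sequence)
  expect_equal(back$count, tab$count)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("not\ta_table", bad)
  expect_error(read_seq_table(bad), "not a sequence-count table")
})
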