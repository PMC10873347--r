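test_that("anchor extraction returns the exact insert or a typed rejection", {
  a <- DEFAULT_ANCHORS
  ok <- paste0(a[1], "GCTAGCGGTGTT", a[2])
  res <- extract_variable_region(c(ok,
                                   paste0("TTTT", "GCTAGCGGTGTT", a[2]),
                                   paste0(a[1], "GCTAGCGGTGT", a[2]),
                                   paste0(a[1], "GCTAGCGGTGTTA", a[2])))
  expect_equal(res$outcome,
               c("insert", "anchor_fail", "frame_fail", "frame_fail"))
  expect_equal(res$insert[1], "GCTAGCGGTGTT")
  # insert recovered with flanking context around the read
  res2 <- extract_variable_region(paste0("ACGT", ok, "ACGT"))
  expect_equal(res2$insert, "GCTAGCGGTGTT")
  expect_error(extract_variable_region("A", anchors = c("", "T")),
               "non-empty")
})

test_that("handcrafted reads tally to manual counts with a full QC partition", {
  a <- DEFAULT_ANCHORS
  reads <- c(rep(paste0(a[1], encode_variant("ASGV"), a[2]), 3),
             paste0(a[1], encode_variant("ATGV"), a[2]),
             paste0("GGGG", encode_variant("ASGV"), a[2]))  # missing anchor
  seqs <- Biostrings::DNAStringSet(reads)
  names(seqs) <- paste0("r", seq_along(reads))
  fq <- withr::local_tempfile(fileext = ".fastq")
  Biostrings::writeXStringSet(seqs, fq, format = "fastq",
                              qualities = Biostrings::BStringSet(
                                strrep("I", nchar(reads))))
  cm <- tally_counts(c(s1 = fq))
  expect_equal(unname(cm$counts["ASGV", "s1"]), 3L)
  expect_equal(unname(cm$counts["ATGV", "s1"]), 1L)
  expect_equal(cm$qc$valid, 4L)
  expect_equal(cm$qc$anchor_fail, 1L)
  expect_equal(cm$qc$total, 5L)
  expect_equal(sum(cm$counts[, "s1"]), 4)
})

test_that("QC categories partition every read", {
  a <- DEFAULT_ANCHORS
  reads <- c(paste0(a[1], encode_variant("ASGV"), a[2]),      # valid
             paste0("AAAA", encode_variant("ASGV"), a[2]),    # anchor_fail
             paste0(a[1], "GCTAGCGGTGT", a[2]),               # frame_fail
             paste0(a[1], "GCTTAAGGTGTT", a[2]),              # codon_fail
             paste0(a[1], "GCTTCTGGTGTT", a[2]))              # off_design
  dec <- decode_reads(reads)
  expect_equal(dec$outcome, c("variant", "anchor_fail", "frame_fail",
                              "codon_fail", "off_design"))
  expect_equal(sum(table(dec$outcome)), length(reads))
})

test_that("read order never changes the count matrix", {
  scr <- small_screen()
  cm <- scr$sim$counts
  sub <- cm
  sub$counts <- cm$counts[, 1:2]
  sub$samples <- cm$samples[1:2, ]
  dir1 <- withr::local_tempdir()
  paths <- emit_amplicon_fastq(sub, dir1, error_rate = 0, seed = 1,
                               gzip = FALSE)
  t1 <- tally_counts(paths)
  # rewrite sample 1 with its 4-line records in reverse order
  lines <- readLines(paths[1])
  blocks <- rev(split(lines, rep(seq_len(length(lines) / 4), each = 4)))
  writeLines(unlist(blocks), paths[1])
  t2 <- tally_counts(paths)
  expect_identical(t1$counts, t2$counts)
})

test_that("error-free FASTQ emission round-trips to the exact counts", {
  fm <- build_fitness_map("empirical", seed = 4)
  d <- screen_design(replicates = 1, depth = 3000)
  sim <- simulate_screen(fm, d, seed = 21)
  dir <- withr::local_tempdir()
  paths <- emit_amplicon_fastq(sim$counts, dir, error_rate = 0, seed = 2)
  cm <- tally_counts(paths, samples = d$samples)
  expect_identical(unname(cm$counts[, colnames(sim$counts$counts)]),
                   unname(sim$counts$counts))
  expect_true(all(cm$qc$valid == cm$qc$total))
})

test_that("substitution errors populate the QC rejection classes", {
  fm <- build_fitness_map("empirical", seed = 4)
  d <- screen_design(replicates = 1, cycles = 1, depth = 2000)
  sim <- simulate_screen(fm, d, seed = 22)
  dir <- withr::local_tempdir()
  paths <- emit_amplicon_fastq(sim$counts, dir, error_rate = 0.01,
                               seed = 3, gzip = FALSE)
  cm <- tally_counts(paths, samples = d$samples)
  expect_true(all(cm$qc$valid + cm$qc$anchor_fail + cm$qc$frame_fail +
                    cm$qc$codon_fail + cm$qc$off_design == cm$qc$total))
  expect_gt(sum(cm$qc$anchor_fail), 0)
  expect_lt(sum(cm$qc$valid), sum(cm$qc$total))
})

test_that("every emitted read keeps an ACC or AGC codon at position 3", {
  fm <- build_fitness_map("empirical", seed = 4)
  d <- screen_design(replicates = 1, cycles = 1, depth = 500)
  sim <- simulate_screen(fm, d, seed = 23)
  dir <- withr::local_tempdir()
  paths <- emit_amplicon_fastq(sim$counts, dir, error_rate = 0, seed = 4,
                               gzip = FALSE)
  reads <- as.character(Biostrings::readDNAStringSet(paths[1],
                                                     format = "fastq"))
  ins <- extract_variable_region(unname(reads))$insert
  expect_true(all(substr(ins, 4, 6) %in% c("ACC", "AGC")))
})

test_that("count matrices round-trip through TSV", {
  scr <- small_screen()
  cm <- scr$sim$counts
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_tsv(cm, path)
  back <- read_count_tsv(path)
  expect_identical(back$counts, cm$counts)
})
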