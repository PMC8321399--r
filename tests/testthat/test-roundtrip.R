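# moderate-scale end-to-end round trips; the full study-condition runs live
# in test-acceptance.R

pair_strings <- function(rs) {
  paste(rs$sequences[seq_len(rs$n1)], rs$sequences[rs$n1 + seq_len(rs$n2)])
}

test_that("single-end archives round-trip in both modes with duplicates and rc", {
  sim <- simulate_reads(genome_length = 1000, coverage = 25, read_length = 100,
                        substitution_rate = 0.01, duplicate_rate = 0.15,
                        rc_probability = 0.5, seed = 81)
  f <- withr::local_tempfile(fileext = ".mstc")
  st <- compress_reads(sim$reads, f)
  out <- decompress_reads(f)
  expect_equal(sort(out$sequences), sort(sim$reads$sequences))
  expect_equal(out$origin_count, sim$reads$origin_count)
  st2 <- compress_reads(sim$reads, f, order_preserving = TRUE)
  out2 <- decompress_reads(f)
  expect_identical(out2$sequences, sim$reads$sequences)
  # the order stream costs extra space
  expect_gte(st2$archive_bytes, st$archive_bytes)
})

test_that("paired-end archives reconnect every mate pair", {
  sim <- simulate_reads(genome_length = 1200, coverage = 20,
                        read_length = 100, paired = TRUE,
                        substitution_rate = 0.01, duplicate_rate = 0.1,
                        seed = 82)
  f <- withr::local_tempfile(fileext = ".mstc")
  compress_reads(sim$reads, f)
  out <- decompress_reads(f)
  expect_equal(sort(pair_strings(out)), sort(pair_strings(sim$reads)))
  compress_reads(sim$reads, f, order_preserving = TRUE)
  out2 <- decompress_reads(f)
  expect_identical(out2$sequences, sim$reads$sequences)
})

test_that("mixed-length paired-end archives remain lossless", {
  sim <- simulate_reads(genome_length = 1200, coverage = 20,
                        read_length = c(100, 80), paired = TRUE,
                        substitution_rate = 0.01, seed = 83)
  f <- withr::local_tempfile(fileext = ".mstc")
  compress_reads(sim$reads, f)
  out <- decompress_reads(f)
  expect_equal(out$read_length, c(100L, 80L))
  expect_equal(sort(pair_strings(out)), sort(pair_strings(sim$reads)))
  compress_reads(sim$reads, f, order_preserving = TRUE)
  expect_identical(decompress_reads(f)$sequences, sim$reads$sequences)
})

test_that("reads containing N survive compression", {
  set.seed(84)
  base <- replicate(40, random_read(60))
  withN <- unname(vapply(base[1:10], function(s) mutate_at(s, sample(60, 1), "N"), ""))
  allN <- strrep("N", 60)
  seqs <- sample(c(base, withN, allN, allN))
  f <- withr::local_tempfile(fileext = ".mstc")
  compress_reads(read_set(seqs), f)
  expect_equal(sort(decompress_reads(f)$sequences), sort(seqs))
  compress_reads(read_set(seqs), f, order_preserving = TRUE)
  expect_identical(decompress_reads(f)$sequences, seqs)
})

test_that("FASTQ-to-FASTQ compression round-trips through the file interface", {
  dir <- withr::local_tempdir()
  sim <- simulate_reads(genome_length = 800, coverage = 15, read_length = 100,
                        substitution_rate = 0.01, paired = TRUE, seed = 85,
                        output_prefix = file.path(dir, "in"))
  ar <- file.path(dir, "out.mstc")
  compress_fastq(sim$paths[1], ar, input2 = sim$paths[2],
                 order_preserving = TRUE)
  outs <- decompress_fastq(ar, file.path(dir, "back"))
  expect_identical(read_fastq(outs[1])$sequences,
                   read_fastq(sim$paths[1])$sequences)
  expect_identical(read_fastq(outs[2])$sequences,
                   read_fastq(sim$paths[2])$sequences)
})

test_that("the speedy configuration stays lossless", {
  sim <- simulate_reads(genome_length = 900, coverage = 20, read_length = 100,
                        substitution_rate = 0.01, seed = 86)
  f <- withr::local_tempfile(fileext = ".mstc")
  st <- compress_reads(sim$reads, f,
                       rounds = round_config(use_maximizers = FALSE))
  expect_equal(sort(decompress_reads(f)$sequences), sort(sim$reads$sequences))
})

test_that("the command-line interface runs compress/decompress/theory", {
  dir <- withr::local_tempdir()
  sim <- simulate_reads(genome_length = 600, coverage = 10, read_length = 80,
                        substitution_rate = 0.01, seed = 87,
                        output_prefix = file.path(dir, "cli"))
  ar <- file.path(dir, "cli.mstc")
  expect_equal(suppressMessages(has_main(c("compress", sim$paths, ar))), 0L)
  expect_equal(suppressMessages(has_main(c("decompress", ar,
                                           file.path(dir, "cliout")))), 0L)
  expect_equal(sort(read_fastq(file.path(dir, "cliout.fastq"))$sequences),
               sort(sim$reads$sequences))
  out <- capture.output(code <- has_main(c("theory", "--n", "20", "--p", "0.15")))
  expect_equal(code, 0L)
  expect_match(out, "0.961", all = FALSE)
  # corrupt archive -> data error exit code
  writeBin(as.raw(1:10), ar)
  expect_equal(suppressMessages(has_main(c("decompress", ar,
                                           file.path(dir, "bad")))), 2L)
  usage <- capture.output(code0 <- has_main(character(0)), type = "message")
  expect_equal(code0, 1L)
  expect_match(usage, "usage", all = FALSE)
})
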