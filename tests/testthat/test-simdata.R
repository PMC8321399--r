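test_that("simulated read counts follow coverage and seeds are reproducible", {
  sim <- simulate_reads(genome_length = 10000, coverage = 30, read_length = 100,
                        substitution_rate = 0, seed = 71)
  expect_equal(sim$reads$origin_count, 3000L)
  sim2 <- simulate_reads(genome_length = 10000, coverage = 30, read_length = 100,
                         substitution_rate = 0, seed = 71)
  expect_identical(sim$reads$sequences, sim2$reads$sequences)
  expect_identical(sim$genome, sim2$genome)
  sim3 <- simulate_reads(genome_length = 10000, coverage = 30, read_length = 100,
                         substitution_rate = 0, seed = 72)
  expect_false(identical(sim$reads$sequences, sim3$reads$sequences))
})

test_that("the truth record reproduces error-free reads from the genome", {
  sim <- simulate_reads(genome_length = 3000, coverage = 10, read_length = 80,
                        substitution_rate = 0, duplicate_rate = 0, seed = 73)
  for (i in sample(sim$reads$origin_count, 50)) {
    frag <- substr(sim$genome, sim$truth$position[i], sim$truth$position[i] + 79)
    expected <- if (sim$truth$strand[i] == "-")
      as.character(reverse_complement(frag)) else frag
    expect_identical(sim$reads$sequences[i], expected)
  }
  # with errors, the truth error counts match the Hamming distance to the origin
  simE <- simulate_reads(genome_length = 3000, coverage = 5, read_length = 80,
                         substitution_rate = 0.02, seed = 74)
  for (i in sample(simE$reads$origin_count, 30)) {
    frag <- substr(simE$genome, simE$truth$position[i], simE$truth$position[i] + 79)
    r <- simE$reads$sequences[i]
    if (simE$truth$strand[i] == "-") r <- as.character(reverse_complement(r))
    expect_equal(sum(charToRaw(r) != charToRaw(frag)), simE$truth$n_errors[i])
  }
})

test_that("the duplicate rate is honoured within binomial tolerance", {
  sim <- simulate_reads(genome_length = 50000, coverage = 4, read_length = 100,
                        substitution_rate = 0.02, duplicate_rate = 0.2,
                        seed = 75)
  n_base <- round(4 * 50000 / 100)
  expect_equal(sim$reads$origin_count, n_base + round(0.2 * n_base))
  dd <- find_duplicates(sim$reads)
  n_dup <- sim$reads$origin_count - dd$distinct$origin_count
  # at least the planted duplicates are found (coincidental ones possible)
  expect_gte(n_dup, round(0.2 * n_base))
  expect_lt(n_dup, round(0.2 * n_base) + 0.02 * n_base)
})

test_that("paired simulation keeps mate geometry and lengths", {
  sim <- simulate_reads(genome_length = 8000, coverage = 10,
                        read_length = c(100, 90), paired = TRUE,
                        substitution_rate = 0, insert_mean = 250,
                        insert_sd = 15, seed = 76)
  rs <- sim$reads
  expect_true(rs$paired)
  expect_equal(rs$read_length, c(100L, 90L))
  expect_equal(rs$n1, rs$n2)
  expect_true(all(nchar(rs$sequences[seq_len(rs$n1)]) == 100L))
  expect_true(all(nchar(rs$sequences[rs$n1 + seq_len(rs$n2)]) == 90L))
  # error-free mates map back to the genome at the recorded positions
  for (i in sample(rs$n1, 25)) {
    r1 <- rs$sequences[i]
    p1 <- sim$truth$position[i]
    frag <- substr(sim$genome, p1, p1 + 99)
    expect_true(r1 == frag || r1 == as.character(reverse_complement(frag)))
  }
})

test_that("FASTQ output files are written when a prefix is given", {
  dir <- withr::local_tempdir()
  sim <- simulate_reads(genome_length = 1000, coverage = 5, read_length = 50,
                        seed = 77, output_prefix = file.path(dir, "sim"))
  expect_true(file.exists(sim$paths))
  expect_equal(read_fastq(sim$paths)$sequences, sim$reads$sequences)
  simP <- simulate_reads(genome_length = 1000, coverage = 5, read_length = 50,
                         paired = TRUE, seed = 78,
                         output_prefix = file.path(dir, "simp"))
  expect_true(all(file.exists(simP$paths)))
  expect_equal(concat_paired(simP$paths[1], simP$paths[2])$sequences,
               simP$reads$sequences)
})
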