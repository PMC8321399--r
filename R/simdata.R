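# ---- synthetic read simulator ----------------------------------------------

#' Simulate short reads with the structure the compressor exploits
#'
#' Draws a uniform random genome, samples reads at uniform random positions
#' to reach the requested coverage, applies per-base substitution errors
#' (to a uniformly chosen different base), reverse-complements reads (or
#' flips pairs) with a fixed probability, and emits a fraction of reads (or
#' pairs) twice to create exact duplicates. The defaults emulate a small
#' high-coverage Illumina-like experiment: 100-bp reads at 30x coverage with
#' a 1\% substitution rate. No indels are generated — the graph models
#' substitutions and shifts only.
#'
#' @param genome_length genome size in bases.
#' @param coverage mean sequencing depth.
#' @param read_length read length, or `c(L1, L2)` for paired-end reads of
#'   different lengths.
#' @param substitution_rate per-base substitution probability.
#' @param rc_probability per-read (or per-pair) probability of sequencing
#'   from the reverse strand.
#' @param duplicate_rate fraction of reads (pairs) emitted twice.
#' @param paired generate paired-end reads.
#' @param insert_mean,insert_sd insert size distribution (paired-end only).
#' @param seed RNG seed (mandatory; the output is byte-identical under the
#'   same seed).
#' @param output_prefix when given, FASTQ file(s) are written to
#'   `<prefix>.fastq` (single-end) or `<prefix>_1.fastq` / `<prefix>_2.fastq`.
#' @return list with `reads` (a [read_set]), `truth` (data frame: `read_id`,
#'   `position` 1-based on the genome, `strand`, `n_errors`), `genome`, and
#'   `paths` when files were written.
#' @export
simulate_reads <- function(genome_length = 10000L, coverage = 30,
                           read_length = 100L, substitution_rate = 0.01,
                           rc_probability = 0.5, duplicate_rate = 0,
                           paired = FALSE, insert_mean = 300, insert_sd = 20,
                           seed, output_prefix = NULL) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            rc_probability >= 0, rc_probability <= 1,
            duplicate_rate >= 0, duplicate_rate <= 1,
            genome_length >= max(read_length))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  genome <- paste0(sample(bases, genome_length, replace = TRUE), collapse = "")
  mutate <- function(seqs) {
    n_err <- integer(length(seqs))
    L <- nchar(seqs)
    for (i in seq_along(seqs)) {
      hit <- which(runif(L[i]) < substitution_rate)
      if (length(hit)) {
        ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
        ch[hit] <- bases[(match(ch[hit], bases) - 1L +
                            sample(1:3, length(hit), replace = TRUE)) %% 4L + 1L]
        seqs[i] <- paste0(ch, collapse = "")
        n_err[i] <- length(hit)
      }
    }
    list(seqs = seqs, n_err = n_err)
  }
  if (!paired) {
    L <- read_length[1L]
    n_reads <- max(1L, round(coverage * genome_length / L))
    pos <- sample.int(genome_length - L + 1L, n_reads, replace = TRUE)
    seqs <- substring(genome, pos, pos + L - 1L)
    mu <- mutate(seqs)
    rc <- runif(n_reads) < rc_probability
    seqs <- mu$seqs
    seqs[rc] <- cpp_revcomp(seqs[rc])
    truth <- data.frame(read_id = seq_len(n_reads), position = pos,
                        strand = ifelse(rc, "-", "+"), n_errors = mu$n_err)
    n_dup <- round(duplicate_rate * n_reads)
    if (n_dup > 0L) {
      which_dup <- sample.int(n_reads, n_dup)
      seqs <- c(seqs, seqs[which_dup])
      truth <- rbind(truth, transform(truth[which_dup, ],
                                      read_id = n_reads + seq_len(n_dup)))
    }
    ord <- sample.int(length(seqs))
    seqs <- seqs[ord]
    truth <- truth[ord, ]
    truth$read_id <- seq_along(seqs)
    rownames(truth) <- NULL
    reads <- read_set(seqs)
    paths <- NULL
    if (!is.null(output_prefix)) {
      paths <- paste0(output_prefix, ".fastq")
      write_fastq(reads, paths)
      utils::write.table(truth, paste0(output_prefix, ".truth.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    return(list(reads = reads, truth = truth, genome = genome, paths = paths))
  }
  # paired-end
  if (length(read_length) == 1L) read_length <- c(read_length, read_length)
  L1 <- read_length[1L]; L2 <- read_length[2L]
  n_pairs <- max(1L, round(coverage * genome_length / (L1 + L2)))
  ins <- pmax(max(L1, L2), round(rnorm(n_pairs, insert_mean, insert_sd)))
  ins <- pmin(ins, genome_length)
  start <- vapply(ins, function(I) sample.int(genome_length - I + 1L, 1L), 0L)
  flip <- runif(n_pairs) < rc_probability
  r1 <- character(n_pairs); r2 <- character(n_pairs)
  p1 <- integer(n_pairs); p2 <- integer(n_pairs)
  for (i in seq_len(n_pairs)) {
    I <- ins[i]; s <- start[i]
    if (!flip[i]) {
      p1[i] <- s
      p2[i] <- s + I - L2
      r1[i] <- substr(genome, s, s + L1 - 1L)
      r2[i] <- as.character(cpp_revcomp(substr(genome, s + I - L2, s + I - 1L)))
    } else {
      p1[i] <- s + I - L1
      p2[i] <- s
      r1[i] <- as.character(cpp_revcomp(substr(genome, s + I - L1, s + I - 1L)))
      r2[i] <- substr(genome, s, s + L2 - 1L)
    }
  }
  m1 <- mutate(r1); m2 <- mutate(r2)
  r1 <- m1$seqs; r2 <- m2$seqs
  n_dup <- round(duplicate_rate * n_pairs)
  if (n_dup > 0L) {
    wd <- sample.int(n_pairs, n_dup)
    r1 <- c(r1, r1[wd]); r2 <- c(r2, r2[wd])
    p1 <- c(p1, p1[wd]); p2 <- c(p2, p2[wd])
    flip <- c(flip, flip[wd])
    m1$n_err <- c(m1$n_err, m1$n_err[wd])
    m2$n_err <- c(m2$n_err, m2$n_err[wd])
  }
  ord <- sample.int(length(r1))
  r1 <- r1[ord]; r2 <- r2[ord]
  truth <- data.frame(read_id = seq_along(r1),
                      position = p1[ord], mate_position = p2[ord],
                      strand = ifelse(flip[ord], "-", "+"),
                      n_errors = (m1$n_err + m2$n_err)[ord])
  reads <- read_set(c(r1, r2), paired = TRUE, n1 = length(r1),
                    n2 = length(r2), read_length = c(L1, L2))
  paths <- NULL
  if (!is.null(output_prefix)) {
    paths <- paste0(output_prefix, c("_1.fastq", "_2.fastq"))
    write_fastq(r1, paths[1L])
    write_fastq(r2, paths[2L])
    utils::write.table(truth, paste0(output_prefix, ".truth.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(reads = reads, truth = truth, genome = genome, paths = paths)
}
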