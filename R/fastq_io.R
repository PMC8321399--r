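#' Construct a read set
#'
#' A `read_set` is the in-memory container for the sequence lines of one
#' FASTQ file (single-end) or of two vertically concatenated FASTQ files
#' (paired-end). Only sequences are kept; headers and qualities are out of
#' scope of the compressor.
#'
#' @param sequences character vector of uppercase reads over `{A,C,G,T,N}`.
#' @param paired logical; `TRUE` when the set is the concatenation of the two
#'   mate files.
#' @param n1,n2 record counts of the first and second file (`n2 = 0` for
#'   single-end input).
#' @param read_length integer length of the reads in file 1, or `c(L1, L2)`
#'   for paired-end input. Defaults to the observed lengths.
#' @return an object of class `read_set` with fields `sequences`,
#'   `read_length` (length-1 or length-2 integer), `origin_count`, `paired`,
#'   `n1`, `n2`.
#' @export
read_set <- function(sequences, paired = FALSE, n1 = length(sequences),
                     n2 = if (paired) length(sequences) - n1 else 0L,
                     read_length = NULL) {
  sequences <- as.character(sequences)
  if (is.null(read_length)) {
    if (paired) {
      read_length <- c(
        if (n1 > 0) nchar(sequences[1L]) else 0L,
        if (n2 > 0) nchar(sequences[n1 + 1L]) else 0L
      )
    } else {
      read_length <- if (length(sequences)) nchar(sequences[1L]) else 0L
    }
  }
  structure(
    list(sequences = sequences,
         read_length = as.integer(read_length),
         origin_count = length(sequences),
         paired = isTRUE(paired),
         n1 = as.integer(n1), n2 = as.integer(n2)),
    class = "read_set"
  )
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads%s, length %s\n", x$origin_count,
              if (x$paired) sprintf(" (paired, %d + %d)", x$n1, x$n2) else "",
              paste(x$read_length, collapse = "/")))
  invisible(x)
}

.validate_seqs <- function(seqs, what = "read") {
  bad <- grep("[^ACGTN]", seqs)
  if (length(bad)) {
    stop(sprintf("%s %d contains characters outside {A,C,G,T,N}", what, bad[1L]),
         call. = FALSE)
  }
  invisible(TRUE)
}

.fastq_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read the sequence lines of a FASTQ file
#'
#' Parses a 4-line-per-record FASTQ file (plain or gzip-compressed, sniffed
#' by the `.gz` extension), uppercases the sequences and checks that all
#' reads have the same length. Headers and quality strings are discarded.
#'
#' @param path path to a FASTQ file.
#' @return a [read_set].
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- .fastq_connection(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("malformed FASTQ '%s': %d lines; record %d is incomplete",
                 path, length(lines), length(lines) %/% 4L + 1L), call. = FALSE)
  }
  if (!length(lines)) return(read_set(character(0)))
  seqs <- toupper(lines[seq(2L, length(lines), by = 4L)])
  .validate_seqs(seqs, "record")
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    off <- which(lens != lens[1L])[1L]
    stop(sprintf("inconsistent read length in '%s': record %d has length %d, expected %d",
                 path, off, lens[off], lens[1L]), call. = FALSE)
  }
  read_set(seqs)
}

#' Vertically concatenate two paired-end FASTQ files
#'
#' The reads of file 1 are followed by the reads of file 2; pair `i` consists
#' of records `i` and `n1 + i` of the combined set. The two files may have
#' different (but internally constant) read lengths.
#'
#' @param path1,path2 paths to the two mate FASTQ files.
#' @return a paired [read_set] with `read_length = c(L1, L2)`.
#' @export
concat_paired <- function(path1, path2) {
  r1 <- read_fastq(path1)
  r2 <- read_fastq(path2)
  if (r1$origin_count != r2$origin_count) {
    stop(sprintf("pairing error: %d records in '%s' but %d in '%s'",
                 r1$origin_count, path1, r2$origin_count, path2), call. = FALSE)
  }
  read_set(c(r1$sequences, r2$sequences), paired = TRUE,
           n1 = r1$origin_count, n2 = r2$origin_count,
           read_length = c(r1$read_length, r2$read_length))
}

#' Pairing map of a paired read set
#'
#' @param reads a paired [read_set].
#' @return integer matrix with one row per pair and the 0-less indices of the
#'   two mates in the concatenated set.
#' @export
pairing_map <- function(reads) {
  stopifnot(inherits(reads, "read_set"), reads$paired)
  cbind(mate1 = seq_len(reads$n1), mate2 = reads$n1 + seq_len(reads$n2))
}

#' Write a read set as FASTQ
#'
#' Emits 4-line records with synthetic headers (`@read_<i>`) and constant
#' placeholder qualities; the original headers and qualities are not part of
#' the compressed representation.
#'
#' @param reads a [read_set] (or character vector of sequences).
#' @param path output path; a `.gz` extension triggers gzip compression.
#' @export
write_fastq <- function(reads, path) {
  seqs <- if (inherits(reads, "read_set")) reads$sequences else as.character(reads)
  con <- .fastq_connection(path, "wt")
  on.exit(close(con))
  if (!length(seqs)) return(invisible(path))
  rec <- rbind(paste0("@read_", seq_along(seqs)),
               seqs,
               "+",
               vapply(nchar(seqs), function(L) strrep("I", L), ""))
  writeLines(as.vector(rec), con)
  invisible(path)
}
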