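#' Configuration of the multi-round minimizer/maximizer indexing
#'
#' Candidate edges are searched over `n_rounds` independent rounds of
#' read indexing with a strictly decreasing panel of k-mer sizes
#' `k1, k1 - 1, ...`; by default the same panel is re-used with k-maximizers,
#' doubling the number of rounds. Dropping the maximizer rounds (`speedy`)
#' roughly halves the work at a small cost in edge quality.
#'
#' @param n_rounds number of k settings (default 20).
#' @param k1 largest k of the panel (default 29, at most 31).
#' @param use_maximizers also run every k with the k-maximizer (default TRUE).
#' @param ordering k-mer ordering: `"lexicographic"` or `"hashed"` (an
#'   invertible 64-bit mix of the 2-bit packed k-mer, which approximates a
#'   uniform random ordering).
#' @param hash_seed seed of the hashed ordering (ignored for lexicographic).
#' @return an object of class `round_config` with the panel in `k_values`.
#' @export
round_config <- function(n_rounds = 20L, k1 = 29L, use_maximizers = TRUE,
                         ordering = c("lexicographic", "hashed"),
                         hash_seed = 17L) {
  ordering <- match.arg(ordering)
  n_rounds <- as.integer(n_rounds); k1 <- as.integer(k1)
  stopifnot(n_rounds >= 1L, k1 <= 31L)
  k_values <- k1 - (seq_len(n_rounds) - 1L)
  if (min(k_values) < 4L) {
    stop("k panel reaches below 4; reduce n_rounds or raise k1", call. = FALSE)
  }
  structure(list(k_values = k_values, use_maximizers = isTRUE(use_maximizers),
                 ordering = ordering, hash_seed = as.integer(hash_seed)),
            class = "round_config")
}

.scan_hits <- function(seqs, rcs, k, maximizer, ordering, hash_seed,
                       both_strands = TRUE) {
  cpp_scan_minimizers(seqs, rcs, as.integer(k), isTRUE(maximizer),
                      isTRUE(both_strands), identical(ordering, "hashed"),
                      as.double(hash_seed))
}

.one_hit <- function(seq, k, maximizer, ordering, hash_seed, both_strands) {
  stopifnot(nchar(seq) >= k)
  h <- .scan_hits(seq, cpp_revcomp(seq), k, maximizer, ordering, hash_seed,
                  both_strands)
  if (h$pos[1L] < 0L) {
    return(list(kmer = NA_character_, position = NA_integer_, strand = NA_character_))
  }
  list(kmer = as.character(h$kmer[1L]), position = h$pos[1L],
       strand = c("forward", "rc")[h$strand[1L] + 1L])
}

#' k-minimizer of a read
#'
#' The smallest k-mer of the read under a fixed ordering; with
#' `both_strands = TRUE` the reverse-complement strand competes as well.
#' Windows containing `N` are ineligible; ties are broken by the leftmost
#' occurrence, preferring the forward strand. The reported position is
#' 0-based within the strand that yielded the k-mer.
#'
#' @param seq a single read.
#' @param k k-mer size.
#' @param ordering,hash_seed see [round_config()].
#' @param both_strands also scan the reverse complement (default FALSE).
#' @return list with `kmer`, `position`, `strand` (`NA`s when no window is
#'   eligible).
#' @export
k_minimizer <- function(seq, k, ordering = c("lexicographic", "hashed"),
                        both_strands = FALSE, hash_seed = 17L) {
  ordering <- match.arg(ordering)
  .one_hit(seq, k, FALSE, ordering, hash_seed, both_strands)
}

#' k-maximizer of a read
#'
#' The largest k-mer under the ordering; otherwise identical to
#' [k_minimizer()].
#'
#' @inheritParams k_minimizer
#' @return list with `kmer`, `position`, `strand`.
#' @export
k_maximizer <- function(seq, k, ordering = c("lexicographic", "hashed"),
                        both_strands = FALSE, hash_seed = 17L) {
  ordering <- match.arg(ordering)
  .one_hit(seq, k, TRUE, ordering, hash_seed, both_strands)
}

# flat block arrays for one round: members of multi-read blocks sorted by
# in-strand anchor position (ties by read index), plus block boundaries
.block_arrays <- function(seqs, rcs, k, maximizer, ordering, hash_seed,
                          keep_singletons = FALSE) {
  h <- .scan_hits(seqs, rcs, k, maximizer, ordering, hash_seed)
  ok <- which(h$pos >= 0L)
  if (!length(ok)) {
    return(list(read = integer(0), pos = integer(0), strand = integer(0),
                start = integer(0), len = integer(0), key = character(0)))
  }
  key <- as.character(h$kmer[ok])
  ord <- ok[order(key, h$pos[ok], ok, method = "radix")]
  skey <- as.character(h$kmer[ord])
  r <- rle(skey)
  len <- r$lengths
  start <- cumsum(c(0L, len[-length(len)]))
  if (!keep_singletons) {
    big <- len > 1L
    if (!all(big)) {
      sel <- rep.int(big, len)
      ord <- ord[sel]
      start <- cumsum(c(0L, len[big][-sum(big)]))
      if (!sum(big)) start <- integer(0)
      len <- len[big]
      r$values <- r$values[big]
    }
  }
  list(read = ord, pos = h$pos[ord], strand = h$strand[ord],
       start = as.integer(start), len = as.integer(len), key = r$values)
}

#' Partition distinct reads into minimizer (or maximizer) blocks
#'
#' One indexing round: reads sharing the same selected k-mer fall into the
#' same block, and block members are sorted by the anchor position within
#' their oriented strand in ascending order. Reads without any eligible
#' window are omitted from the round.
#'
#' @param distinct a [read_set] of deduplicated reads.
#' @param k k-mer size of the round.
#' @param mode `"minimizer"` or `"maximizer"`.
#' @param ordering,hash_seed see [round_config()].
#' @return list of blocks; each block has `key` (the k-mer) and `members`, a
#'   data frame with `read` (distinct-read index), `pos` (0-based anchor
#'   position in the oriented strand) and `strand` (0 forward, 1 rc).
#' @export
build_blocks <- function(distinct, k, mode = c("minimizer", "maximizer"),
                         ordering = c("lexicographic", "hashed"),
                         hash_seed = 17L) {
  mode <- match.arg(mode)
  ordering <- match.arg(ordering)
  stopifnot(inherits(distinct, "read_set"))
  seqs <- distinct$sequences
  ba <- .block_arrays(seqs, cpp_revcomp(seqs), k, mode == "maximizer",
                      ordering, hash_seed, keep_singletons = TRUE)
  lapply(seq_along(ba$len), function(b) {
    idx <- ba$start[b] + seq_len(ba$len[b])
    list(key = ba$key[b],
         members = data.frame(read = ba$read[idx], pos = ba$pos[idx],
                              strand = ba$strand[idx]))
  })
}
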