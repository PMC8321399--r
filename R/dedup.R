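#' Reverse complement of nucleotide sequences
#'
#' @param seq character vector over `{A,C,G,T,N}`; `N` maps to `N`.
#' @return character vector of reverse-complemented sequences.
#' @export
reverse_complement <- function(seq) {
  .validate_seqs(seq, "sequence")
  cpp_revcomp(seq)
}

#' Detect duplicate reads before graph construction
#'
#' Reads are clustered into blocks keyed by their canonical 31-minimizer and
#' its position (the key is invariant under reverse complement), and full
#' string equality is verified within each block. Two duplicate types are
#' distinguished: copies on the original strand and copies equal to the
#' reverse complement of an earlier read. The representative of a duplicate
#' class is its first occurrence in file order; a read equal to its own
#' reverse complement counts extra copies as normal duplicates.
#'
#' @param reads a [read_set].
#' @return a list with
#'   \describe{
#'     \item{distinct}{[read_set] of distinct reads in first-occurrence order.}
#'     \item{records}{data frame with one row per distinct read:
#'       `representative_index` (index into the distinct set), `normal_count`,
#'       `rc_count`.}
#'     \item{members}{list of original-file index vectors per distinct read
#'       (representative first, then normal copies, then rc copies).}
#'     \item{map}{data frame mapping every original index to its
#'       `distinct` index and its `type` (0 representative, 1 normal
#'       duplicate, 2 rc duplicate).}
#'   }
#' @export
find_duplicates <- function(reads) {
  stopifnot(inherits(reads, "read_set"))
  seqs <- reads$sequences
  m <- length(seqs)
  if (!m) {
    return(list(distinct = read_set(character(0)),
                records = data.frame(representative_index = integer(0),
                                     normal_count = integer(0),
                                     rc_count = integer(0)),
                members = list(),
                map = data.frame(distinct = integer(0), type = integer(0))))
  }
  rcs <- cpp_revcomp(seqs)
  keys <- cpp_dedup_keys(seqs, rcs, 31L)
  canon <- ifelse(keys$orient == 0L, seqs, rcs)
  # block key + full-string verification in one composite key: reads can only
  # collapse when they share the minimizer block AND the canonical string
  full_key <- paste0(keys$key, "\r", canon)
  rep_orig <- match(full_key, full_key)       # first occurrence = representative
  is_rep <- rep_orig == seq_len(m)
  distinct_id <- cumsum(is_rep)               # id valid at representative rows
  dmap <- distinct_id[rep_orig]               # distinct index of every original
  type <- integer(m)
  dup <- !is_rep
  # normal duplicate if byte-identical to the representative, else rc duplicate
  type[dup] <- ifelse(seqs[dup] == seqs[rep_orig[dup]], 1L, 2L)
  if (any(type == 2L & seqs != rcs[rep_orig])) {
    stop("internal error: rc duplicate fails verification")
  }
  M <- sum(is_rep)
  normal_count <- tabulate(dmap[type == 1L], nbins = M)
  rc_count <- tabulate(dmap[type == 2L], nbins = M)
  ord <- order(dmap, type, seq_len(m))
  members <- unname(split(ord, dmap[ord]))
  list(distinct = read_set(seqs[is_rep]),
       records = data.frame(representative_index = seq_len(M),
                            normal_count = normal_count,
                            rc_count = rc_count),
       members = members,
       map = data.frame(distinct = dmap, type = type))
}
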