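#' Candidate-edge search configuration
#'
#' @param max_weight maximum accepted edge weight `3*mb + ob`; `NULL` means
#'   the read length (an edge whose label costs about as much as the raw read
#'   is useless for compression).
#' @param search_limit number of preceding block members each read is
#'   compared with (default 32); use `Inf` for an exhaustive within-block
#'   search.
#' @return an object of class `graph_config`.
#' @export
graph_config <- function(max_weight = NULL, search_limit = 32L) {
  stopifnot(is.null(max_weight) || max_weight > 0, search_limit >= 1)
  structure(list(max_weight = max_weight, search_limit = search_limit),
            class = "graph_config")
}

#' Edge weight of the Hamming-shifting graph
#'
#' `w = 3 * mb + ob` where `mb` is the number of mismatching bases in the
#' overlap and `ob` the shifting offset. A mismatch is costed three times an
#' offset base because its encoded form (position digits plus the base)
#' is about three characters long, while each offset base contributes one.
#'
#' @param mb number of mismatching bases (>= 0).
#' @param ob shifting offset in bases (>= 0).
#' @return integer weight.
#' @export
edge_weight <- function(mb, ob) {
  stopifnot(all(mb >= 0), all(ob >= 0))
  if (any(mb + ob == 0)) {
    stop("mb and ob are both zero: identical reads must be deduplicated first",
         call. = FALSE)
  }
  as.integer(3L * mb + ob)
}

#' Align two reads at a shared minimizer anchor
#'
#' Given the minimizer hits of two reads with the same k-mer key, the anchor
#' fixes a unique overlap layout. When the hit strands differ, the second
#' read is aligned as its reverse complement (hit positions are already
#' expressed within the oriented strand, see [k_minimizer()]).
#'
#' @param ru,rv the two reads (character scalars).
#' @param hit_u,hit_v their minimizer hits, as returned by [k_minimizer()].
#' @return list with `offset` (non-negative shifting bases), `direction`
#'   (`"none"`, `"u_ahead"` or `"v_ahead"`: whose prefix hangs off the
#'   overlap) and `strand` (`"same"` or `"rc"`).
#' @export
align_by_anchor <- function(ru, rv, hit_u, hit_v) {
  norm <- function(seq, hit) {
    if (identical(hit$strand, "rc")) {
      list(seq = cpp_revcomp(seq), pos = hit$position, rc = TRUE)
    } else {
      list(seq = seq, pos = hit$position, rc = FALSE)
    }
  }
  # normalize so that u is on its forward strand
  if (identical(hit_u$strand, "rc")) {
    k <- nchar(hit_u$kmer)
    hit_u <- list(kmer = cpp_revcomp(hit_u$kmer),
                  position = nchar(ru) - k - hit_u$position, strand = "forward")
    hit_v <- list(kmer = cpp_revcomp(hit_v$kmer),
                  position = nchar(rv) - k - hit_v$position,
                  strand = if (identical(hit_v$strand, "rc")) "forward" else "rc")
  }
  nu <- norm(ru, hit_u); nv <- norm(rv, hit_v)
  k <- nchar(hit_u$kmer)
  if (substr(nu$seq, nu$pos + 1L, nu$pos + k) !=
      substr(nv$seq, nv$pos + 1L, nv$pos + k)) {
    stop("anchor k-mers differ after strand normalization", call. = FALSE)
  }
  off <- nu$pos - nv$pos
  list(offset = abs(off),
       direction = if (off == 0L) "none" else if (off > 0L) "u_ahead" else "v_ahead",
       strand = if (nv$rc) "rc" else "same")
}

#' Mismatching distance between two overlapping reads
#'
#' The Hamming distance of the overlap plus the (non-zero) shifting offset;
#' with offset 0 this is the plain Hamming distance.
#'
#' @param ru,rv the two reads.
#' @param offset non-negative shifting offset of the layout.
#' @param direction `"none"`, `"u_ahead"` or `"v_ahead"` (see
#'   [align_by_anchor()]).
#' @param strand `"same"` or `"rc"` (align `rv` as its reverse complement).
#' @return list with `mb` (mismatching bases in the overlap) and `distance`
#'   (`mb + offset`).
#' @export
mismatching_distance <- function(ru, rv, offset,
                                 direction = c("none", "u_ahead", "v_ahead"),
                                 strand = c("same", "rc")) {
  direction <- match.arg(direction)
  strand <- match.arg(strand)
  offset <- as.integer(offset)
  if (offset == 0L && direction != "none") {
    stop("offset 0 requires direction 'none'", call. = FALSE)
  }
  ve <- if (strand == "rc") cpp_revcomp(rv) else rv
  Lu <- nchar(ru); Lv <- nchar(ve)
  if (offset >= min(Lu, Lv)) stop("no overlap at this offset", call. = FALSE)
  sv <- switch(direction, none = 0L, u_ahead = offset, v_ahead = -offset)
  lo <- max(0L, sv); hi <- min(Lu, sv + Lv)
  if (hi - lo < 1L) stop("no overlap at this offset", call. = FALSE)
  a <- charToRaw(substr(ru, lo + 1L, hi))
  b <- charToRaw(substr(ve, lo - sv + 1L, hi - sv))
  mb <- sum(a != b)
  list(mb = as.integer(mb), distance = as.integer(mb + offset))
}

.edges_df <- function() {
  data.frame(u = integer(0), v = integer(0), rc = integer(0), rel = integer(0),
             mb = integer(0), ob = integer(0), weight = integer(0))
}

.dedup_edges <- function(e, n_nodes, per_layout = FALSE) {
  if (!nrow(e)) return(e)
  ord <- order(e$weight, seq_len(nrow(e)))
  e <- e[ord, , drop = FALSE]
  key <- e$u * (n_nodes + 1) + e$v
  if (per_layout) key <- paste(key, e$rel, e$rc)
  e <- e[!duplicated(key), , drop = FALSE]
  rownames(e) <- NULL
  e
}

#' Candidate edges of one indexing round
#'
#' Each block member is aligned (at the shared anchor) against up to
#' `search_limit` preceding members of its block; layouts are admitted when
#' the overlap is non-empty, the weight is within `max_weight`, and — for
#' reads of unequal length — each read overhangs the other on exactly one
#' side, which keeps the shifting offset recoverable at decoding time
#' (offset-0 layouts between unequal-length reads are always rejected).
#' Edges are canonicalized to `u < v` with `u` on its forward strand; `rel`
#' is the signed start of `v`'s oriented sequence relative to `u`.
#'
#' @param blocks list of blocks from [build_blocks()].
#' @param distinct the distinct [read_set] the blocks refer to.
#' @param cfg a [graph_config()].
#' @return data frame of edges (`u`, `v`, `rc`, `rel`, `mb`, `ob`, `weight`),
#'   deduplicated per layout keeping the lightest.
#' @export
find_candidate_edges <- function(blocks, distinct, cfg = graph_config()) {
  stopifnot(inherits(distinct, "read_set"))
  seqs <- distinct$sequences
  if (!length(blocks)) return(.edges_df())
  lens <- nchar(seqs)
  read <- unlist(lapply(blocks, function(b) b$members$read), use.names = FALSE)
  pos <- unlist(lapply(blocks, function(b) b$members$pos), use.names = FALSE)
  strand <- unlist(lapply(blocks, function(b) b$members$strand), use.names = FALSE)
  len <- vapply(blocks, function(b) nrow(b$members), 0L)
  start <- cumsum(c(0L, len[-length(len)]))
  mw <- if (is.null(cfg$max_weight)) max(lens) else as.integer(cfg$max_weight)
  sl <- if (is.infinite(cfg$search_limit)) .Machine$integer.max else
    as.integer(cfg$search_limit)
  e <- cpp_scan_block_edges(seqs, cpp_revcomp(seqs), lens,
                            read - 1L, pos, strand, start, len, sl, mw)
  e$u <- as.integer(e$u); e$v <- as.integer(e$v)
  .dedup_edges(e, length(seqs), per_layout = TRUE)
}

# internal fast path shared by collect_rounds: flat arrays, no list-of-blocks
.round_edges <- function(seqs, rcs, lens, k, maximizer, rounds, cfg, mw, sl) {
  ba <- .block_arrays(seqs, rcs, k, maximizer, rounds$ordering, rounds$hash_seed)
  if (!length(ba$read)) return(.edges_df())
  cpp_scan_block_edges(seqs, rcs, lens, ba$read - 1L, ba$pos, ba$strand,
                       ba$start, ba$len, sl, mw)
}

#' Collect candidate edges across all indexing rounds
#'
#' Runs every k of the round panel with the k-minimizer and (unless
#' `rounds$use_maximizers` is off) with the k-maximizer, pools the per-round
#' edges, keeps the lightest edge per unordered read pair and returns the
#' stream sorted by nondecreasing weight.
#'
#' @param distinct distinct [read_set].
#' @param rounds a [round_config()].
#' @param cfg a [graph_config()].
#' @return weight-sorted edge data frame (see [find_candidate_edges()]).
#' @export
collect_rounds <- function(distinct, rounds = round_config(),
                           cfg = graph_config()) {
  stopifnot(inherits(distinct, "read_set"), inherits(rounds, "round_config"))
  seqs <- distinct$sequences
  if (length(seqs) < 2L) return(.edges_df())
  rcs <- cpp_revcomp(seqs)
  lens <- nchar(seqs)
  mw <- if (is.null(cfg$max_weight)) max(lens) else as.integer(cfg$max_weight)
  sl <- if (is.infinite(cfg$search_limit)) .Machine$integer.max else
    as.integer(cfg$search_limit)
  passes <- data.frame(k = rounds$k_values, maximizer = FALSE)
  if (rounds$use_maximizers) {
    passes <- rbind(passes, data.frame(k = rounds$k_values, maximizer = TRUE))
  }
  passes <- passes[passes$k <= max(lens), , drop = FALSE]
  out <- vector("list", nrow(passes))
  for (i in seq_len(nrow(passes))) {
    out[[i]] <- .round_edges(seqs, rcs, lens, passes$k[i], passes$maximizer[i],
                             rounds, cfg, mw, sl)
  }
  e <- do.call(rbind, out)
  e <- .dedup_edges(e, length(seqs))
  rownames(e) <- NULL
  e
}
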