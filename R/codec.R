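# ---- child-vs-parent delta encoding ---------------------------------------
#
# The encoded string of a non-root read is the shifting substring (the child
# bases not covered by the parent; empty at offset 0) followed by the
# mismatch items, each item being the 0-based mismatch position in child
# coordinates (first absolute, then as gaps from the previous mismatch) and
# the child base. A direction bit records whether the child starts before
# ("left") or after ("right") the parent in the overlap layout, and an rc bit
# whether the child is encoded on its reverse-complement strand.

# orientation of a canonical edge (u < v, u forward, v_eff starting at `rel`)
# for a chosen child: returns the parent node, the child start relative to
# the parent (parent always on its forward strand) and the rc flag.
.orient_edge <- function(u, v, rc, rel, Lu, Lv, child) {
  if (child == v) {
    list(parent = u, rel_c = rel, rc = rc)
  } else if (child == u) {
    if (!rc) list(parent = v, rel_c = -rel, rc = FALSE)
    else list(parent = v, rel_c = rel + Lv - Lu, rc = TRUE)
  } else stop("child is not an endpoint of the edge", call. = FALSE)
}

# core encoder on raw layouts: child_eff aligned to parent with child start
# at rel_c (parent starts at 0); single uncovered flank guaranteed upstream
.encode_core <- function(parent, child_eff, rel_c) {
  Lp <- nchar(parent); Lc <- nchar(child_eff)
  if (rel_c > 0L) {                      # child starts after the parent
    tail_len <- rel_c + Lc - Lp
    if (tail_len <= 0L) stop("encoding bug: contained child layout", call. = FALSE)
    ov <- Lc - tail_len
    S <- substr(child_eff, ov + 1L, Lc)
    pov <- charToRaw(substr(parent, rel_c + 1L, rel_c + ov))
    cov <- charToRaw(substr(child_eff, 1L, ov))
    mm <- which(pov != cov) - 1L
  } else if (rel_c < 0L) {               # child starts before the parent
    o <- -rel_c
    if (Lc - o > Lp) stop("encoding bug: double-flank layout", call. = FALSE)
    ov <- Lc - o
    S <- substr(child_eff, 1L, o)
    pov <- charToRaw(substr(parent, 1L, ov))
    cov <- charToRaw(substr(child_eff, o + 1L, Lc))
    mm <- which(pov != cov) - 1L + o
  } else {
    if (Lc != Lp) stop("encoding bug: offset 0 with unequal lengths", call. = FALSE)
    S <- ""
    pov <- charToRaw(parent); cov <- charToRaw(child_eff)
    mm <- which(pov != cov) - 1L
  }
  items <- ""
  if (length(mm)) {
    deltas <- c(mm[1L], diff(mm))
    bases <- substring(child_eff, mm + 1L, mm + 1L)
    items <- paste0(deltas, bases, collapse = "")
  }
  text <- paste0(S, items)
  if (!nzchar(text)) stop("encoding bug: empty code for a non-root read", call. = FALSE)
  text
}

#' Encode a read against its parent
#'
#' Produces the encoded string of a child read relative to a parent read in
#' a given overlap layout, e.g. child `"ATGCAT"` against parent `"GCATCC"`
#' at shift offset 2 encodes as `"AT2G"`: shifting substring `"AT"` (the
#' child tail not covered by the parent) followed by one mismatch item
#' (position 2, base `G`).
#'
#' @param child,parent the two reads (character scalars).
#' @param offset non-negative shifting offset of the layout.
#' @param direction `"right"` when the child starts after the parent (its
#'   tail is the shifting substring), `"left"` when it starts before (its
#'   head is); ignored at offset 0.
#' @param rc encode the child on its reverse-complement strand.
#' @return list with `text` (the encoded string), `direction_bit` (TRUE =
#'   left shift) and `rc_bit`. The encoding is checked by decoding before it
#'   is returned.
#' @export
encode_child <- function(child, parent, offset, direction = c("right", "left"),
                         rc = FALSE) {
  direction <- match.arg(direction)
  offset <- as.integer(offset)
  stopifnot(offset >= 0L)
  rel_c <- if (offset == 0L) 0L else if (direction == "right") offset else -offset
  child_eff <- if (rc) cpp_revcomp(child) else child
  text <- .encode_core(parent, child_eff, rel_c)
  out <- list(text = text, direction_bit = rel_c < 0L, rc_bit = isTRUE(rc))
  back <- decode_child(parent, text, out$direction_bit, out$rc_bit, nchar(child))
  if (!identical(back, as.character(child))) {
    stop("encoding bug: decode check failed", call. = FALSE)
  }
  out
}

.parse_encoded <- function(text) {
  S <- sub("^([ACGTN]*).*$", "\\1", text)
  rest <- substr(text, nchar(S) + 1L, nchar(text))
  if (!nzchar(rest)) return(list(S = S, pos = integer(0), base = character(0)))
  m <- gregexpr("[0-9]+[ACGTN]", rest)[[1L]]
  items <- regmatches(rest, list(m))[[1L]]
  if (m[1L] == -1L || sum(attr(m, "match.length")) != nchar(rest)) {
    stop("corrupt archive: malformed encoded string '", text, "'", call. = FALSE)
  }
  k <- nchar(items)
  list(S = S,
       pos = as.integer(substr(items, 1L, k - 1L)),
       base = substr(items, k, k))
}

#' Decode a read from its parent and encoded string
#'
#' Exact inverse of [encode_child()]: the shifting offset is recovered from
#' the length of the shifting substring together with the two read lengths
#' and the direction bit.
#'
#' @param parent the parent read.
#' @param text the encoded string.
#' @param direction_bit TRUE for a left shift (child starts before parent).
#' @param rc_bit TRUE when the child was encoded on its rc strand.
#' @param child_length length of the child read.
#' @return the decoded child read.
#' @export
decode_child <- function(parent, text, direction_bit = FALSE, rc_bit = FALSE,
                         child_length = nchar(parent)) {
  Lc <- as.integer(child_length)
  Lp <- nchar(parent)
  p <- .parse_encoded(text)
  nS <- nchar(p$S)
  if (nS == 0L) {
    if (Lc != Lp) stop("corrupt archive: offset-0 code with unequal lengths",
                       call. = FALSE)
    base <- parent
  } else if (!direction_bit) {           # right shift: S is the child tail
    o <- nS + Lp - Lc
    if (o <= 0L || o >= Lp) stop("corrupt archive: bad shifting substring",
                                 call. = FALSE)
    base <- paste0(substr(parent, o + 1L, Lp), p$S)
  } else {                               # left shift: S is the child head
    o <- nS
    if (Lc - o > Lp || Lc - o < 1L) stop("corrupt archive: bad shifting substring",
                                         call. = FALSE)
    base <- paste0(p$S, substr(parent, 1L, Lc - o))
  }
  if (nchar(base) != Lc) stop("corrupt archive: decoded length mismatch",
                              call. = FALSE)
  if (length(p$pos)) {
    at <- cumsum(p$pos)
    if (any(at >= Lc)) stop("corrupt archive: mismatch position out of range",
                            call. = FALSE)
    r <- charToRaw(base)
    r[at + 1L] <- charToRaw(paste0(p$base, collapse = ""))
    base <- rawToChar(r)
  }
  if (rc_bit) base <- as.character(cpp_revcomp(base)) else base <- as.character(base)
  base
}

# encode one forest child given the selected edge row; returns text/dir/rc
.encode_node <- function(forest, seqs, lens, child) {
  er <- forest$edges[forest$edge_of[child], ]
  o <- .orient_edge(er$u, er$v, er$rc == 1L, er$rel, lens[er$u], lens[er$v], child)
  child_eff <- if (o$rc) cpp_revcomp(seqs[child]) else seqs[child]
  text <- .encode_core(seqs[o$parent], child_eff, o$rel_c)
  list(text = text, dir = o$rel_c < 0L, rc = o$rc, parent = o$parent)
}

# ---- depth-first stream encoding (order-free mode) -------------------------

#' Encode a spanning forest into the data streams (order-free mode)
#'
#' Emits the trees in root-index order. Stream 1 holds, per tree, the raw
#' root read followed by each child's encoded string in depth-first preorder
#' with siblings visited in ascending index order; when the traversal has to
#' backtrack before the next descent, the number of consecutive upward steps
#' is stored as a digits-only line (trailing pops at the end of a tree are
#' omitted, and trees are separated by an empty line). Streams 2 and 3 carry
#' the direction and rc bits of the children; stream 4 flags nodes with
#' duplicates and stream 5 stores their (normal, rc) duplicate counts.
#'
#' @param forest a [kruskal_msf()] forest over the distinct reads.
#' @param distinct the distinct [read_set].
#' @param dups the duplicate bookkeeping from [find_duplicates()].
#' @return list with `s1` (character lines), `dir_bits`, `rc_bits` (per
#'   non-root node in emission order), `dup_bits` (per node), `dup_counts`
#'   (interleaved normal/rc pairs) and `emit_nodes` (distinct indices in
#'   emission order).
#' @export
dfs_encode <- function(forest, distinct, dups = NULL) {
  seqs <- distinct$sequences
  lens <- nchar(seqs)
  n <- forest$num_nodes
  kids <- vector("list", n)
  ch <- which(!is.na(forest$parent_of))
  if (length(ch)) {
    sp <- split(ch, forest$parent_of[ch])
    kids[as.integer(names(sp))] <- lapply(sp, sort)
  }
  lines <- character(2L * n + length(forest$roots))
  nl <- 0L
  put <- function(x) { nl <<- nl + 1L; lines[nl] <<- x }
  dir_bits <- logical(0); rc_bits <- logical(0)
  emit <- integer(n); ne <- 0L
  depth <- integer(n)
  first_tree <- TRUE
  prev_node <- NA_integer_; prev_depth <- 0L
  for (r in forest$roots) {
    if (!first_tree) put("")
    first_tree <- FALSE
    stack <- integer(0)
    stack <- c(r)
    depth[r] <- 0L
    while (length(stack)) {
      x <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (is.na(forest$parent_of[x])) {
        put(seqs[x])
      } else {
        px <- forest$parent_of[x]
        if (!identical(prev_node, px)) {
          pops <- prev_depth - (depth[x] - 1L)
          stopifnot(pops >= 1L)
          put(as.character(pops))
        }
        enc <- .encode_node(forest, seqs, lens, x)
        put(enc$text)
        dir_bits <- c(dir_bits, enc$dir)
        rc_bits <- c(rc_bits, enc$rc)
      }
      ne <- ne + 1L; emit[ne] <- x
      prev_node <- x; prev_depth <- depth[x]
      kx <- kids[[x]]
      if (length(kx)) {
        depth[kx] <- depth[x] + 1L
        stack <- c(stack, rev(kx))
      }
    }
    prev_node <- NA_integer_
  }
  out <- list(s1 = lines[seq_len(nl)], dir_bits = dir_bits, rc_bits = rc_bits,
              emit_nodes = emit[seq_len(ne)])
  if (!is.null(dups)) {
    nc <- dups$records$normal_count[out$emit_nodes]
    rcn <- dups$records$rc_count[out$emit_nodes]
    has <- nc + rcn > 0L
    out$dup_bits <- has
    out$dup_counts <- as.integer(rbind(nc[has], rcn[has]))
  }
  out
}

# ---- order-preserving mode -------------------------------------------------

#' Renumber read IDs after dropping duplicates and singletons
#'
#' Duplicate copies and singleton reads (reads isolated in the forest with
#' no duplicates) can never be parents, so parent references use IDs
#' renumbered over the remaining reads in original order: with seven reads
#' where reads 3 and 6 are duplicates and read 2 is a singleton, reads
#' 1, 4, 5, 7 receive IDs 1, 2, 3, 4.
#'
#' @param n number of reads.
#' @param is_duplicate,is_singleton logical vectors of length `n`.
#' @return integer vector of IDs with `NA` at removed reads.
#' @export
renumber_ids <- function(n, is_duplicate, is_singleton) {
  keep <- !(is_duplicate | is_singleton)
  ids <- cumsum(keep)
  ids[!keep] <- NA_integer_
  as.integer(ids)
}

# singleton = distinct read that is a root with no children and no duplicates
.singleton_nodes <- function(forest, dups) {
  has_child <- tabulate(forest$parent_of[!is.na(forest$parent_of)],
                        nbins = forest$num_nodes) > 0L
  is_root <- is.na(forest$parent_of)
  no_dups <- dups$records$normal_count + dups$records$rc_count == 0L
  is_root & !has_child & no_dups
}

#' Encode in original read order (order-preserving single-end mode)
#'
#' Stream 1 holds one line per original read: the raw read at tree roots,
#' the encoded string at non-root distinct reads, and an empty line at
#' duplicate copies. The tree structure is recovered from a parent-ID
#' stream holding, for every encoded read, the ID of its parent, and for
#' every duplicate copy the ID of the read it duplicates; IDs are
#' renumbered after removing duplicates and singletons ([renumber_ids()]).
#' An extra bit per root line marks singletons so the decoder can rebuild
#' the same ID space. Duplicate streams 4 and 5 are not needed.
#'
#' @inheritParams dfs_encode
#' @return list with `s1`, `parent_ids`, `dir_bits`, `rc_bits`,
#'   `singleton_bits` and the renumbered `ids`.
#' @export
order_preserving_encode <- function(forest, distinct, dups) {
  seqs <- distinct$sequences
  lens <- nchar(seqs)
  m <- nrow(dups$map)
  singleton_d <- .singleton_nodes(forest, dups)
  is_dup <- dups$map$type > 0L
  is_single <- dups$map$type == 0L & singleton_d[dups$map$distinct]
  ids <- renumber_ids(m, is_dup, is_single)
  rep_orig <- vapply(dups$members, `[`, 0L, 1L)  # original index of each representative
  s1 <- character(m)
  parent_ids <- integer(0)
  dir_bits <- logical(0)
  rc_bits <- logical(0)
  singleton_bits <- logical(0)
  enc_cache <- vector("list", forest$num_nodes)
  for (i in seq_len(m)) {
    d <- dups$map$distinct[i]
    ty <- dups$map$type[i]
    if (ty > 0L) {                         # duplicate copy: empty line
      s1[i] <- ""
      parent_ids <- c(parent_ids, ids[rep_orig[d]])
      rc_bits <- c(rc_bits, ty == 2L)
    } else if (is.na(forest$parent_of[d])) {   # root: raw read
      s1[i] <- seqs[d]
      singleton_bits <- c(singleton_bits, is_single[i])
    } else {
      enc <- enc_cache[[d]]
      if (is.null(enc)) enc <- enc_cache[[d]] <- .encode_node(forest, seqs, lens, d)
      s1[i] <- enc$text
      parent_ids <- c(parent_ids, ids[rep_orig[enc$parent]])
      dir_bits <- c(dir_bits, enc$dir)
      rc_bits <- c(rc_bits, enc$rc)
    }
  }
  if (anyNA(parent_ids)) stop("encoding bug: reference to a removed read ID",
                              call. = FALSE)
  list(s1 = s1, parent_ids = parent_ids, dir_bits = dir_bits,
       rc_bits = rc_bits, singleton_bits = singleton_bits, ids = ids)
}

# ---- paired-end pairing streams --------------------------------------------

#' Pair distance stream over the visiting order
#'
#' Pairs are processed by their first-seen member in the visiting order; for
#' each pair the number of not-yet-processed reads strictly between the two
#' mates' visiting ranks is stored (maintained with a Fenwick tree over a
#' 0/1 presence array), both mates are then marked processed, and an order
#' bit records whether the earlier-visited mate belongs to the first file.
#'
#' @param visit_orig integer vector: original read indices (in the
#'   concatenated paired set) in visiting order.
#' @param n1 number of reads in the first file; read `i` pairs with
#'   `i + n1` (or `i - n1`).
#' @return list with `distances`, `order_bits` and `pair_ids` (the original
#'   pair index of each processed pair, used by the order-preserving mode).
#' @export
pair_distance_stream <- function(visit_orig, n1) {
  m <- length(visit_orig)
  n1 <- as.integer(n1)
  rank_of <- integer(m)
  rank_of[visit_orig] <- seq_len(m)
  if (anyNA(rank_of) || any(rank_of == 0L)) {
    stop("pairing error: visiting order is not a permutation", call. = FALSE)
  }
  fen <- fenwick_create(m, ones = TRUE)
  processed <- logical(m)
  distances <- integer(0); order_bits <- logical(0); pair_ids <- integer(0)
  for (r in seq_len(m)) {
    i <- visit_orig[r]
    if (processed[i]) next
    j <- if (i <= n1) i + n1 else i - n1
    if (j > m) stop("pairing error: unpaired read index ", i, call. = FALSE)
    rj <- rank_of[j]
    lo <- min(r, rj); hi <- max(r, rj)
    d <- fenwick_prefix(fen, hi - 1L) - fenwick_prefix(fen, lo)
    distances <- c(distances, as.integer(d))
    order_bits <- c(order_bits, i <= n1)
    pair_ids <- c(pair_ids, if (i <= n1) i else j)
    processed[c(i, j)] <- TRUE
    fenwick_add(fen, r, -1)
    fenwick_add(fen, rj, -1)
  }
  list(distances = distances, order_bits = order_bits, pair_ids = pair_ids)
}

# inverse: from distances/order bits and the number of reads, recover for
# each processed pair the visiting ranks of (file-1 mate, file-2 mate)
.pair_decode <- function(m, distances, order_bits) {
  fen <- fenwick_create(m, ones = TRUE)
  processed <- logical(m)
  out1 <- integer(length(distances)); out2 <- integer(length(distances))
  pi <- 0L
  for (r in seq_len(m)) {
    if (processed[r]) next
    pi <- pi + 1L
    if (pi > length(distances)) stop("corrupt archive: missing pair distance",
                                     call. = FALSE)
    d <- distances[pi]
    before <- fenwick_prefix(fen, r)     # unprocessed up to and including r
    mate <- fenwick_select(fen, before + d + 1L)
    if (mate > m) stop("corrupt archive: pair distance out of range", call. = FALSE)
    if (order_bits[pi]) { out1[pi] <- r; out2[pi] <- mate }
    else { out1[pi] <- mate; out2[pi] <- r }
    processed[c(r, mate)] <- TRUE
    fenwick_add(fen, r, -1)
    fenwick_add(fen, mate, -1)
  }
  if (pi != length(distances)) stop("corrupt archive: excess pair distances",
                                    call. = FALSE)
  list(rank1 = out1, rank2 = out2)
}
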