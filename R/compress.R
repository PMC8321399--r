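# ---- end-to-end compression and decompression -----------------------------

# materialized emission order: each distinct node in DFS order followed by
# its duplicate copies (normal copies first, then rc copies); returns the
# original read indices in that order
.materialized_order <- function(emit_nodes, dups) {
  unlist(dups$members[emit_nodes], use.names = FALSE)
}

#' Compress a read set
#'
#' Runs the full pipeline: duplicate detection, multi-round candidate-edge
#' search, minimum spanning forest extraction and stream encoding, then
#' writes a self-describing archive. Order-free mode stores the reads in
#' depth-first order (smaller archives); order-preserving mode restores the
#' exact original read order. Paired-end sets additionally store the pair
#' distance stream over the visiting order.
#'
#' @param reads a [read_set] (single-end, or paired from [concat_paired()]).
#' @param path output archive path.
#' @param order_preserving restore exact original order on decompression.
#' @param rounds a [round_config()].
#' @param cfg a [graph_config()].
#' @param dump_edges optional path: write the candidate edge table
#'   (u, v, offset, direction, strand, mb, weight) as TSV for debugging.
#' @return (invisibly) a list of summary statistics: node/edge/tree counts,
#'   archive bytes and bits per base.
#' @export
compress_reads <- function(reads, path, order_preserving = FALSE,
                           rounds = round_config(), cfg = graph_config(),
                           dump_edges = NULL) {
  stopifnot(inherits(reads, "read_set"))
  t0 <- proc.time()[["elapsed"]]
  dd <- find_duplicates(reads)
  M <- dd$distinct$origin_count
  edges <- collect_rounds(dd$distinct, rounds, cfg)
  if (!is.null(dump_edges)) {
    dump <- data.frame(u = edges$u, v = edges$v, offset = edges$ob,
                       direction = ifelse(edges$rel == 0L, "none",
                                          ifelse(edges$rel < 0L, "v_ahead",
                                                 "u_ahead")),
                       strand = ifelse(edges$rc == 1L, "rc", "same"),
                       mb = edges$mb, weight = edges$weight)
    utils::write.table(dump, dump_edges, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  forest <- kruskal_msf(M, edges)
  L1 <- if (reads$paired) reads$read_length[1L] else reads$read_length
  L2 <- if (reads$paired) reads$read_length[2L] else 0L
  header <- list(paired = reads$paired, order_preserving = order_preserving,
                 L1 = L1, L2 = L2, n1 = reads$n1, n2 = reads$n2)
  streams <- list()
  if (order_preserving && !reads$paired) {
    b <- order_preserving_encode(forest, dd$distinct, dd)
    streams$s1 <- charToRaw(paste(b$s1, collapse = "\n"))
    streams$pid <- ints_serialize(b$parent_ids)
    streams$dir <- bits_serialize(b$dir_bits)
    streams$rc <- bits_serialize(b$rc_bits)
    streams$sing <- bits_serialize(b$singleton_bits)
  } else {
    b <- dfs_encode(forest, dd$distinct, dd)
    streams$s1 <- charToRaw(paste(b$s1, collapse = "\n"))
    streams$dir <- bits_serialize(b$dir_bits)
    streams$rc <- bits_serialize(b$rc_bits)
    streams$dup <- bits_serialize(b$dup_bits)
    streams$dupcnt <- ints_serialize(b$dup_counts)
    if (reads$paired) {
      if (L1 != L2) {
        lens <- nchar(dd$distinct$sequences)
        streams$lenclass <- bits_serialize(lens[b$emit_nodes] == L2)
      }
      vo <- .materialized_order(b$emit_nodes, dd)
      ps <- pair_distance_stream(vo, reads$n1)
      streams$pdist <- ints_serialize(ps$distances)
      streams$pbit <- bits_serialize(ps$order_bits)
      if (order_preserving) streams$porder <- ints_serialize(ps$pair_ids)
    }
  }
  archive_write(path, header, streams)
  bytes <- file.size(path)
  bases <- sum(nchar(reads$sequences))
  stats <- list(reads = reads$origin_count, distinct = M,
                candidate_edges = nrow(edges), forest_edges = nrow(forest$edges),
                trees = length(forest$roots),
                total_weight = forest$total_weight,
                archive_bytes = bytes,
                bpb = if (bases > 0) 8 * bytes / bases else NA_real_,
                seconds = proc.time()[["elapsed"]] - t0)
  invisible(stats)
}

# split the stream-1 text back into lines ("" when empty input)
.s1_lines <- function(raw_s1) {
  if (!length(raw_s1)) return(character(0))
  strsplit(rawToChar(raw_s1), "\n", fixed = TRUE)[[1L]]
}

.is_digits <- function(x) grepl("^[0-9]+$", x)

# decode an order-free stream 1 into distinct reads (emission order) plus
# per-node duplicate materialization; returns the emitted sequences
.decode_order_free <- function(ar) {
  lines <- .s1_lines(ar$streams$s1)
  dir_bits <- bits_deserialize(ar$streams$dir)
  rc_bits <- bits_deserialize(ar$streams$rc)
  dup_bits <- bits_deserialize(ar$streams$dup)
  dup_counts <- ints_deserialize(ar$streams$dupcnt)
  lenclass <- if (!is.null(ar$streams$lenclass))
    bits_deserialize(ar$streams$lenclass) else NULL
  node_seqs <- character(length(lines))
  nn <- 0L
  out <- character(ar$n1 + ar$n2)
  no <- 0L
  stack <- integer(0)
  ci <- 0L  # child counter (dir/rc bits)
  di <- 0L  # dup-count pair counter
  for (line in lines) {
    if (!nzchar(line)) { stack <- integer(0); next }
    if (.is_digits(line)) {
      pops <- as.integer(line)
      if (pops > length(stack)) stop("corrupt archive: backtracking underflow",
                                     call. = FALSE)
      stack <- stack[seq_len(length(stack) - pops)]
      next
    }
    nn <- nn + 1L
    if (!length(stack)) {
      seq <- line
      if (grepl("[0-9]", seq)) stop("corrupt archive: malformed root line",
                                    call. = FALSE)
    } else {
      ci <- ci + 1L
      if (ci > length(dir_bits)) stop("corrupt archive: missing direction bit",
                                      call. = FALSE)
      Lc <- if (!is.null(lenclass)) {
        if (lenclass[nn]) ar$L2 else ar$L1
      } else ar$L1
      seq <- decode_child(node_seqs[stack[length(stack)]], line,
                          dir_bits[ci], rc_bits[ci], Lc)
    }
    node_seqs[nn] <- seq
    stack <- c(stack, nn)
    # materialize the node and its duplicates
    if (nn > length(dup_bits)) stop("corrupt archive: missing duplicate flag",
                                    call. = FALSE)
    nrm <- 0L; nrc <- 0L
    if (dup_bits[nn]) {
      di <- di + 1L
      nrm <- dup_counts[2L * di - 1L]
      nrc <- dup_counts[2L * di]
    }
    reps <- 1L + nrm
    out[no + seq_len(reps)] <- seq
    no <- no + reps
    if (nrc > 0L) {
      out[no + seq_len(nrc)] <- cpp_revcomp(seq)
      no <- no + nrc
    }
  }
  if (no != ar$n1 + ar$n2) stop("corrupt archive: read count mismatch",
                                call. = FALSE)
  out
}

.decode_order_preserving_se <- function(ar) {
  lines <- .s1_lines(ar$streams$s1)
  m <- ar$n1
  # strsplit drops trailing empty lines (duplicates at the end of the file)
  if (length(lines) < m) lines <- c(lines, rep("", m - length(lines)))
  if (length(lines) != m) {
    stop("corrupt archive: line count mismatch", call. = FALSE)
  }
  parent_ids <- ints_deserialize(ar$streams$pid)
  dir_bits <- bits_deserialize(ar$streams$dir)
  rc_bits <- bits_deserialize(ar$streams$rc)
  singleton_bits <- bits_deserialize(ar$streams$sing)
  L <- ar$L1
  is_dup <- !nzchar(lines)
  is_root <- !is_dup & !grepl("[0-9]", lines) & nchar(lines) == L
  # rebuild the renumbered ID space: duplicates never get an ID; roots get
  # one unless flagged singleton; every encoded read gets one
  si <- 0L
  removed <- logical(m)
  removed[is_dup] <- TRUE
  for (i in which(is_root)) {
    si <- si + 1L
    if (si > length(singleton_bits)) stop("corrupt archive: missing singleton flag",
                                          call. = FALSE)
    removed[i] <- singleton_bits[si]
  }
  ids <- cumsum(!removed)
  id2orig <- which(!removed)
  # per-line parent references and bits, in original order
  ref <- rep(NA_integer_, m)
  pi <- 0L; ci <- 0L; ri <- 0L
  dirb <- rep(FALSE, m); rcb <- rep(FALSE, m)
  for (i in seq_len(m)) {
    if (is_root[i]) next
    pi <- pi + 1L
    if (pi > length(parent_ids)) stop("corrupt archive: missing parent ID",
                                      call. = FALSE)
    id <- parent_ids[pi]
    if (id < 1L || id > length(id2orig)) {
      stop("corrupt archive: parent ID out of range", call. = FALSE)
    }
    ref[i] <- id2orig[id]
    ri <- ri + 1L
    rcb[i] <- rc_bits[ri]
    if (!is_dup[i]) { ci <- ci + 1L; dirb[i] <- dir_bits[ci] }
  }
  # topological decode: roots first, then any read whose reference is ready
  seqs <- character(m)
  done <- logical(m)
  seqs[is_root] <- lines[is_root]
  done[is_root] <- TRUE
  waiting <- split(which(!is_root), ref[!is_root])
  queue <- which(is_root)
  while (length(queue)) {
    p <- queue[[1L]]; queue <- queue[-1L]
    ws <- waiting[[as.character(p)]]
    if (is.null(ws)) next
    for (w in ws) {
      if (is_dup[w]) {
        seqs[w] <- if (rcb[w]) cpp_revcomp(seqs[p]) else seqs[p]
      } else {
        seqs[w] <- decode_child(seqs[p], lines[w], dirb[w], rcb[w], L)
      }
      done[w] <- TRUE
    }
    queue <- c(queue, ws)
  }
  if (!all(done)) stop("corrupt archive: unresolved parent references",
                       call. = FALSE)
  seqs
}

#' Decompress an archive back to reads
#'
#' @param path archive written by [compress_reads()].
#' @return a [read_set]; in order-preserving mode the sequences are in the
#'   exact original order, in order-free mode in the depth-first emission
#'   order (single-end) or in recovered-pair order (paired-end).
#' @export
decompress_reads <- function(path) {
  ar <- archive_read(path)
  if (!ar$paired) {
    seqs <- if (ar$order_preserving) .decode_order_preserving_se(ar)
    else .decode_order_free(ar)
    if (length(seqs) && any(nchar(seqs) != ar$L1)) {
      stop("corrupt archive: decoded read length mismatch", call. = FALSE)
    }
    return(read_set(seqs, read_length = ar$L1))
  }
  # paired: decode the emitted reads, then re-link mates via the distances
  emitted <- .decode_order_free(ar)
  m <- length(emitted)
  distances <- ints_deserialize(ar$streams$pdist)
  order_bits <- bits_deserialize(ar$streams$pbit)
  if (length(distances) * 2L != m) {
    stop("corrupt archive: pair stream count mismatch", call. = FALSE)
  }
  pd <- .pair_decode(m, distances, order_bits)
  s1 <- emitted[pd$rank1]
  s2 <- emitted[pd$rank2]
  if (any(nchar(s1) != ar$L1) || any(nchar(s2) != ar$L2)) {
    stop("corrupt archive: mate length mismatch", call. = FALSE)
  }
  if (ar$order_preserving) {
    pair_ids <- ints_deserialize(ar$streams$porder)
    if (length(pair_ids) != length(s1) ||
        (length(pair_ids) && !setequal(pair_ids, seq_len(ar$n1)))) {
      stop("corrupt archive: bad pair order stream", call. = FALSE)
    }
    s1[pair_ids] <- s1
    s2[pair_ids] <- s2
  }
  read_set(c(s1, s2), paired = TRUE, n1 = ar$n1, n2 = ar$n2,
           read_length = c(ar$L1, ar$L2))
}

#' Compress FASTQ file(s) to an archive
#'
#' @param input path to a FASTQ file (single-end), or the first mate file.
#' @param output archive output path.
#' @param input2 optional second mate file (paired-end).
#' @inheritParams compress_reads
#' @return (invisibly) the statistics of [compress_reads()].
#' @export
compress_fastq <- function(input, output, input2 = NULL,
                           order_preserving = FALSE, rounds = round_config(),
                           cfg = graph_config(), ...) {
  reads <- if (is.null(input2)) read_fastq(input) else concat_paired(input, input2)
  compress_reads(reads, output, order_preserving = order_preserving,
                 rounds = rounds, cfg = cfg, ...)
}

#' Decompress an archive to FASTQ file(s)
#'
#' @param path archive path.
#' @param prefix output prefix; single-end archives produce `<prefix>.fastq`,
#'   paired-end `<prefix>_1.fastq` and `<prefix>_2.fastq`.
#' @return character vector of the written paths.
#' @export
decompress_fastq <- function(path, prefix) {
  rs <- decompress_reads(path)
  if (!rs$paired) {
    out <- paste0(prefix, ".fastq")
    write_fastq(rs, out)
    return(invisible(out))
  }
  out <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  write_fastq(rs$sequences[seq_len(rs$n1)], out[1L])
  write_fastq(rs$sequences[rs$n1 + seq_len(rs$n2)], out[2L])
  invisible(out)
}
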