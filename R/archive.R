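# ---- on-disk archive container --------------------------------------------
#
# Layout (all integers little-endian):
#   magic "MSTC" (4 bytes) | version (1 byte) | flags (1 byte:
#   bit0 = paired, bit1 = order-preserving) | L1, L2, n1, n2 (int32) |
#   stream count (1 byte) | per stream: name length (1 byte), name,
#   backend id (1 byte), raw length (int32), compressed length (int32),
#   checksum (int32, byte sum of the raw stream), payload.
# The archive is self-describing: the decoder needs no side information.

.ARCHIVE_MAGIC <- charToRaw("MSTC")
.ARCHIVE_VERSION <- 1L

.checksum <- function(r) {
  if (!length(r)) return(0L)
  as.integer(sum(as.double(r)) %% 2147483647)
}

archive_write <- function(path, header, streams) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.ARCHIVE_MAGIC, con)
  writeBin(as.raw(.ARCHIVE_VERSION), con)
  flags <- as.integer(isTRUE(header$paired)) +
    2L * as.integer(isTRUE(header$order_preserving))
  writeBin(as.raw(flags), con)
  writeBin(as.integer(c(header$L1, header$L2, header$n1, header$n2)), con,
           size = 4L, endian = "little")
  writeBin(as.raw(length(streams)), con)
  for (nm in names(streams)) {
    raw_stream <- streams[[nm]]
    backend <- if (identical(nm, "pdist")) "xz" else "bzip2"
    comp <- backend_compress(raw_stream, backend)
    writeBin(as.raw(nchar(nm)), con)
    writeBin(charToRaw(nm), con)
    writeBin(as.raw(comp$id), con)
    writeBin(as.integer(c(length(raw_stream), length(comp$payload),
                          .checksum(raw_stream))), con,
             size = 4L, endian = "little")
    if (length(comp$payload)) writeBin(comp$payload, con)
  }
  invisible(path)
}

.read_exact <- function(con, what, n, size = NA_integer_) {
  x <- if (identical(what, "raw")) readBin(con, "raw", n = n)
  else readBin(con, "integer", n = n, size = size, endian = "little")
  if (length(x) != n) stop("corrupt archive: truncated file", call. = FALSE)
  x
}

archive_read <- function(path) {
  if (!file.exists(path)) stop("no such archive: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- .read_exact(con, "raw", 4L)
  if (!identical(magic, .ARCHIVE_MAGIC)) {
    stop("not a valid archive (bad magic)", call. = FALSE)
  }
  version <- as.integer(.read_exact(con, "raw", 1L))
  if (version != .ARCHIVE_VERSION) {
    stop("unsupported archive version ", version, call. = FALSE)
  }
  flags <- as.integer(.read_exact(con, "raw", 1L))
  hdr <- .read_exact(con, "integer", 4L, size = 4L)
  ns <- as.integer(.read_exact(con, "raw", 1L))
  streams <- list()
  for (i in seq_len(ns)) {
    nl <- as.integer(.read_exact(con, "raw", 1L))
    nm <- rawToChar(.read_exact(con, "raw", nl))
    backend <- as.integer(.read_exact(con, "raw", 1L))
    meta <- .read_exact(con, "integer", 3L, size = 4L)
    payload <- .read_exact(con, "raw", meta[2L])
    raw_stream <- backend_decompress(payload, backend)
    if (length(raw_stream) != meta[1L] || .checksum(raw_stream) != meta[3L]) {
      stop("corrupt archive: checksum mismatch in stream '", nm, "'",
           call. = FALSE)
    }
    streams[[nm]] <- raw_stream
  }
  list(paired = bitwAnd(flags, 1L) > 0L,
       order_preserving = bitwAnd(flags, 2L) > 0L,
       L1 = hdr[1L], L2 = hdr[2L], n1 = hdr[3L], n2 = hdr[4L],
       streams = streams)
}
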