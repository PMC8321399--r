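# --- variable-length integers (LEB128), bit packing, Fenwick tree, backends -

# encode non-negative integers as LEB128 varints
varint_encode <- function(x) {
  if (!length(x)) return(raw(0))
  x <- as.numeric(x)
  stopifnot(all(x >= 0), all(x < 2^53))
  out <- vector("list", length(x))
  for (i in seq_along(x)) {
    v <- x[i]
    bytes <- integer(0)
    repeat {
      b <- v %% 128
      v <- (v - b) / 128
      if (v > 0) bytes <- c(bytes, b + 128) else { bytes <- c(bytes, b); break }
    }
    out[[i]] <- as.raw(bytes)
  }
  do.call(c, out)
}

# decode all varints of a raw vector
varint_decode <- function(r) {
  vals <- numeric(0)
  v <- 0; mult <- 1
  n <- 0L
  if (length(r)) {
    ints <- as.integer(r)
    acc <- numeric(length(r)); k <- 0L
    for (b in ints) {
      v <- v + (b %% 128L) * mult
      if (b < 128L) { k <- k + 1L; acc[k] <- v; v <- 0; mult <- 1 }
      else mult <- mult * 128
    }
    if (mult != 1) stop("corrupt archive: truncated varint", call. = FALSE)
    vals <- acc[seq_len(k)]
  }
  vals
}

# logical vector -> varint(count) + packed bits (little-endian within byte)
bits_serialize <- function(bits) {
  bits <- as.logical(bits)
  n <- length(bits)
  pad <- (8L - n %% 8L) %% 8L
  c(varint_encode(n), packBits(c(bits, rep(FALSE, pad))))
}

bits_deserialize <- function(r) {
  if (!length(r)) return(logical(0))
  hdr <- .varint_read1(r)
  n <- hdr$value
  bits <- as.logical(rawToBits(hdr$rest))
  if (length(bits) < n) stop("corrupt archive: short bit stream", call. = FALSE)
  bits[seq_len(n)]
}

# integer vector -> varint(count) + varints
ints_serialize <- function(x) {
  c(varint_encode(length(x)), varint_encode(x))
}

ints_deserialize <- function(r) {
  if (!length(r)) return(numeric(0))
  vals <- varint_decode(r)
  n <- vals[1L]
  if (length(vals) != n + 1) stop("corrupt archive: bad integer stream", call. = FALSE)
  vals[-1L]
}

.varint_read1 <- function(r) {
  v <- 0; mult <- 1
  for (i in seq_along(r)) {
    b <- as.integer(r[i])
    v <- v + (b %% 128L) * mult
    if (b < 128L) return(list(value = v, rest = r[-seq_len(i)]))
    mult <- mult * 128
  }
  stop("corrupt archive: truncated varint", call. = FALSE)
}

# --- Fenwick (binary indexed) tree over 1..n, environment-backed -----------

fenwick_create <- function(n, ones = FALSE) {
  env <- new.env(parent = emptyenv())
  env$n <- as.integer(n)
  env$tree <- numeric(n)
  if (ones && n > 0) {
    tree <- rep(1, n)
    for (i in seq_len(n)) {
      j <- i + bitwAnd(i, -i)
      if (j <= n) tree[j] <- tree[j] + tree[i]
    }
    env$tree <- tree
  }
  env
}

fenwick_add <- function(f, i, delta) {
  i <- as.integer(i)
  while (i <= f$n) {
    f$tree[i] <- f$tree[i] + delta
    i <- i + bitwAnd(i, -i)
  }
  invisible(f)
}

fenwick_prefix <- function(f, i) {
  i <- as.integer(i)
  s <- 0
  while (i > 0L) {
    s <- s + f$tree[i]
    i <- i - bitwAnd(i, -i)
  }
  s
}

# smallest index with prefix sum >= k (all stored values are 0/1 here)
fenwick_select <- function(f, k) {
  pos <- 0L
  bit <- 1L
  while (bit * 2L <= f$n) bit <- bit * 2L
  rem <- k
  while (bit > 0L) {
    nxt <- pos + bit
    if (nxt <= f$n && f$tree[nxt] < rem) {
      pos <- nxt
      rem <- rem - f$tree[nxt]
    }
    bit <- bit %/% 2L
  }
  pos + 1L
}

# --- backend (entropy) compressors -----------------------------------------

.BACKENDS <- c(none = 0L, gzip = 1L, bzip2 = 2L, xz = 3L)

backend_compress <- function(r, method = "bzip2") {
  stopifnot(method %in% names(.BACKENDS))
  if (!length(r) || method == "none") return(list(payload = r, id = .BACKENDS[["none"]]))
  list(payload = memCompress(r, type = method), id = .BACKENDS[[method]])
}

backend_decompress <- function(payload, id) {
  method <- names(.BACKENDS)[match(id, .BACKENDS)]
  if (is.na(method)) stop("corrupt archive: unknown backend id ", id, call. = FALSE)
  if (method == "none") return(payload)
  memDecompress(payload, type = method)
}
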