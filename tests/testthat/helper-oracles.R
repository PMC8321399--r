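# independent reference implementations used to cross-check the package

random_read <- function(L, bases = c("A", "C", "G", "T")) {
  paste0(sample(bases, L, replace = TRUE), collapse = "")
}

mutate_at <- function(seq, pos1, base) {
  substr(seq, pos1, pos1) <- base
  seq
}

# brute-force duplicate scan: first matching earlier read (plain or rc) wins;
# a read equal to both (palindrome) counts as a normal duplicate
brute_dups <- function(seqs) {
  rcs <- as.character(reverse_complement(seqs))
  m <- length(seqs)
  rep_of <- seq_len(m)
  type <- integer(m)
  for (i in seq_len(m)) {
    for (j in seq_len(i - 1L)) {
      if (type[j] > 0L) next  # representatives only
      if (seqs[i] == seqs[j]) { rep_of[i] <- j; type[i] <- 1L; break }
      if (seqs[i] == rcs[j]) { rep_of[i] <- j; type[i] <- 2L; break }
    }
  }
  list(rep_of = rep_of, type = type)
}

# naive minimizer/maximizer: enumerate windows, C-locale sort
naive_extremizer <- function(seq, k, maximizer = FALSE) {
  L <- nchar(seq)
  if (L < k) return(NULL)
  ws <- substring(seq, 1:(L - k + 1), k:L)
  ok <- !grepl("N", ws, fixed = TRUE)
  if (!any(ok)) return(NULL)
  idx <- which(ok)
  o <- order(ws[idx], idx, method = "radix", decreasing = c(maximizer, FALSE))
  list(kmer = ws[idx][o[1L]], pos = idx[o[1L]] - 1L)
}

# pure-R exhaustive best alignment of one pair under the package's
# admissibility rules (single uncovered flank per read unless same span)
r_best_pair <- function(a, b, max_weight = max(nchar(a), nchar(b))) {
  La <- nchar(a); Lb <- nchar(b)
  best <- NULL
  for (rc in c(FALSE, TRUE)) {
    bb <- if (rc) as.character(reverse_complement(b)) else b
    for (rel in (-(Lb - 1L)):(La - 1L)) {
      lo <- max(0L, rel); hi <- min(La, rel + Lb)
      if (hi - lo < 1L) next
      h_a <- max(0L, rel); t_a <- max(0L, La - (rel + Lb))
      h_b <- max(0L, -rel); t_b <- max(0L, (rel + Lb) - La)
      same_span <- h_a + t_a + h_b + t_b == 0L
      if (!same_span) {
        if ((h_a > 0) + (t_a > 0) != 1L) next
        if ((h_b > 0) + (t_b > 0) != 1L) next
      }
      sa <- charToRaw(substr(a, lo + 1L, hi))
      sb <- charToRaw(substr(bb, lo - rel + 1L, hi - rel))
      mb <- sum(sa != sb)
      if (mb == 0L && same_span) next
      w <- 3L * mb + abs(rel)
      if (w <= max_weight && (is.null(best) || w < best$weight)) {
        best <- list(weight = w, rel = rel, rc = rc, mb = mb)
      }
    }
  }
  best
}

# independent MST total weight (Prim's algorithm, dense)
prim_total_weight <- function(n, edges) {
  w <- matrix(Inf, n, n)
  for (i in seq_len(nrow(edges))) {
    u <- edges$u[i]; v <- edges$v[i]
    w[u, v] <- min(w[u, v], edges$weight[i])
    w[v, u] <- w[u, v]
  }
  total <- 0
  visited <- logical(n)
  for (start in seq_len(n)) {
    if (visited[start]) next
    visited[start] <- TRUE
    key <- w[start, ]
    repeat {
      key[visited] <- Inf
      nxt <- which.min(key)
      if (!is.finite(key[nxt])) break
      total <- total + key[nxt]
      visited[nxt] <- TRUE
      key <- pmin(key, w[nxt, ])
    }
  }
  total
}

# enumerate all spanning forests matching the component structure of a small
# candidate graph: returns a list of edge-row index vectors
enumerate_spanning_forests <- function(n, edges) {
  ne <- nrow(edges)
  comp <- seq_len(n)
  for (i in seq_len(ne)) {
    cu <- comp[edges$u[i]]; cv <- comp[edges$v[i]]
    if (cu != cv) comp[comp == cv] <- cu
  }
  need <- n - length(unique(comp))
  if (need == 0L) return(list(integer(0)))
  out <- list()
  for (sel in utils::combn(ne, need, simplify = FALSE)) {
    cc <- seq_len(n)
    ok <- TRUE
    for (i in sel) {
      cu <- cc[edges$u[i]]; cv <- cc[edges$v[i]]
      if (cu == cv) { ok <- FALSE; break }
      cc[cc == cv] <- cu
    }
    if (ok) out[[length(out) + 1L]] <- sel
  }
  out
}

# build a has_forest-compatible object from chosen edge rows (for comparing
# encodings across enumerated spanning trees)
forest_from_edges <- function(n, edges, rows) {
  sel <- edges[rows, , drop = FALSE]
  rownames(sel) <- NULL
  parent_of <- rep(NA_integer_, n)
  edge_of <- rep(NA_integer_, n)
  comp <- seq_len(n)
  for (i in seq_len(nrow(sel))) {
    cu <- comp[sel$u[i]]; cv <- comp[sel$v[i]]
    comp[comp == cv] <- cu
  }
  roots <- as.integer(tapply(seq_len(n), comp, min))
  visited <- logical(n)
  adj <- lapply(seq_len(n), function(x)
    which(sel$u == x | sel$v == x))
  for (r in sort(roots)) {
    queue <- r; visited[r] <- TRUE
    while (length(queue)) {
      x <- queue[[1L]]; queue <- queue[-1L]
      for (ei in adj[[x]]) {
        y <- if (sel$u[ei] == x) sel$v[ei] else sel$u[ei]
        if (!visited[y]) {
          visited[y] <- TRUE
          parent_of[y] <- x
          edge_of[y] <- ei
          queue <- c(queue, y)
        }
      }
    }
  }
  structure(list(parent_of = parent_of, edge_of = edge_of, edges = sel,
                 roots = sort(roots), total_weight = sum(sel$weight),
                 num_nodes = n),
            class = "has_forest")
}

# simulated single-end set with the study-condition defaults scaled by n
sim_se <- function(n_reads, seed, error = 0.01, dup = 0, L = 100L,
                   coverage = 30) {
  simulate_reads(genome_length = round(n_reads * L / coverage),
                 coverage = coverage, read_length = L,
                 substitution_rate = error, duplicate_rate = dup, seed = seed)
}
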