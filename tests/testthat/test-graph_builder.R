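test_that("edge_weight applies w = 3*mb + ob and rejects the degenerate case", {
  expect_equal(edge_weight(1, 0), 3L)
  expect_equal(edge_weight(0, 1), 1L)
  expect_equal(edge_weight(2, 3), 9L)
  expect_error(edge_weight(0, 0), "dedup")
})

test_that("align_by_anchor recovers offset, direction and strand", {
  set.seed(21)
  u <- random_read(60)
  v <- paste0(substr(u, 2, 60), "A")  # v starts one base into u
  k <- 12
  hu <- k_minimizer(u, k)
  hv <- k_minimizer(v, k)
  al <- align_by_anchor(u, v, hu, hv)
  expect_equal(al$offset, 1L)
  expect_equal(al$direction, "u_ahead")
  expect_equal(al$strand, "same")
  # identical reads anchor with no shift
  al0 <- align_by_anchor(u, u, hu, hu)
  expect_equal(al0$offset, 0L)
  expect_equal(al0$direction, "none")
  # rc-strand anchoring: explicit reverse complementation gives the same layout
  w <- as.character(reverse_complement(v))
  hw <- k_minimizer(w, k, both_strands = TRUE)
  expect_equal(hw$strand, "rc")  # its minimizer lives on the rc strand
  alrc <- align_by_anchor(u, w, hu, hw)
  expect_equal(alrc$strand, "rc")
  expect_equal(alrc$offset, 1L)
  # mismatching anchors are a consistency error
  expect_error(align_by_anchor(u, v, hu, list(kmer = hv$kmer, position = 0L,
                                              strand = "forward")),
               "anchor")
})

test_that("mismatching_distance is Hamming at offset 0 and adds the offset", {
  set.seed(22)
  a <- random_read(100)
  expect_equal(mismatching_distance(a, a, 0), list(mb = 0L, distance = 0L))
  b <- mutate_at(a, 25, setdiff(c("A", "C", "G", "T"),
                                substr(a, 25, 25))[1])
  expect_equal(mismatching_distance(a, b, 0), list(mb = 1L, distance = 1L))
  # one-base shift with perfect 99-bp overlap
  c_ <- paste0(substr(a, 2, 100), "A")
  d <- mismatching_distance(a, c_, 1, direction = "u_ahead")
  expect_equal(d$mb + as.integer(substr(a, 1, 1) == "A") * 0L, d$mb)
  expect_equal(d$distance, d$mb + 1L)
  expect_equal(d$mb, 0L)
  # symmetry under the mirrored layout
  d2 <- mismatching_distance(c_, a, 1, direction = "v_ahead")
  expect_equal(d2$distance, d$distance)
  expect_error(mismatching_distance(a, b, 100), "overlap")
})

test_that("three colinear one-shifted reads yield the expected block edges", {
  set.seed(23)
  g <- random_read(62)
  r <- substring(g, 1:3, 60:62)  # three reads shifted by 1
  rs <- read_set(r)
  blocks <- build_blocks(rs, 10)
  e <- find_candidate_edges(blocks, rs, graph_config(search_limit = Inf))
  key <- paste(e$u, e$v)
  expect_true(all(c("1 2", "2 3", "1 3") %in% key))
  expect_equal(e$weight[match(c("1 2", "2 3", "1 3"), key)], c(1L, 1L, 2L))
  # a block of one read yields no edges
  single <- build_blocks(read_set(r[1]), 10)
  expect_equal(nrow(find_candidate_edges(single, read_set(r[1]))), 0L)
})

test_that("the exhaustive C++ aligner agrees with a pure-R scan on small pairs", {
  set.seed(24)
  for (trial in 1:6) {
    La <- sample(20:40, 1); Lb <- if (trial <= 3) La else sample(20:40, 1)
    a <- random_read(La)
    b <- if (trial %% 2 == 0) {
      # correlated pair: shifted + mutated copy
      s <- sample(0:5, 1)
      bb <- substr(paste0(a, random_read(10)), s + 1, s + Lb)
      mutate_at(bb, sample(Lb, 1), sample(c("A", "C", "G", "T"), 1))
    } else random_read(Lb)
    oracle <- r_best_pair(a, b)
    got <- hasgraph:::cpp_brute_best(c(a, b),
                                     as.character(reverse_complement(c(a, b))),
                                     c(La, Lb), max(La, Lb))
    if (is.null(oracle)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(nrow(got), 1L)
      expect_equal(got$weight, oracle$weight)
    }
  }
})

test_that("heuristic edges match the brute-force oracle weights when co-blocked", {
  set.seed(25)
  sim <- sim_se(150, seed = 250)
  dd <- find_duplicates(sim$reads)
  distinct <- dd$distinct
  seqs <- distinct$sequences
  M <- length(seqs)
  cfg <- graph_config(search_limit = Inf)
  edges <- collect_rounds(distinct, round_config(), cfg)
  # every emitted edge must be self-consistent: decoding the child from the
  # parent via the edge layout reproduces the read exactly (both orientations)
  lens <- nchar(seqs)
  idx <- sample(nrow(edges), min(300, nrow(edges)))
  for (i in idx) {
    er <- edges[i, ]
    for (child in c(er$u, er$v)) {
      o <- hasgraph:::.orient_edge(er$u, er$v, er$rc == 1, er$rel,
                                   lens[er$u], lens[er$v], child)
      ce <- if (o$rc) as.character(reverse_complement(seqs[child])) else seqs[child]
      text <- hasgraph:::.encode_core(seqs[o$parent], ce, o$rel_c)
      expect_equal(decode_child(seqs[o$parent], text, o$rel_c < 0, o$rc,
                                lens[child]),
                   seqs[child])
    }
  }
  # edge weights equal the exhaustive minimum for the found pairs
  brute <- hasgraph:::cpp_brute_best(seqs, as.character(reverse_complement(seqs)),
                                     lens, max(lens))
  bkey <- paste(brute$u, brute$v)
  ekey <- paste(edges$u, edges$v)
  expect_true(all(ekey %in% bkey))  # heuristic finds no pair the oracle lacks
  expect_true(all(edges$weight >= brute$weight[match(ekey, bkey)]))
  expect_gt(mean(edges$weight == brute$weight[match(ekey, bkey)]), 0.95)
})

test_that("speedy (minimizer-only) edges are a subset of full-mode pairs", {
  set.seed(26)
  sim <- sim_se(100, seed = 260)
  dd <- find_duplicates(sim$reads)
  full <- collect_rounds(dd$distinct, round_config(use_maximizers = TRUE))
  speedy <- collect_rounds(dd$distinct, round_config(use_maximizers = FALSE))
  expect_true(all(paste(speedy$u, speedy$v) %in% paste(full$u, full$v)))
  expect_false(is.unsorted(full$weight))
  expect_false(is.unsorted(speedy$weight))
})

test_that("offset-only rule holds for unequal-length pairs", {
  set.seed(27)
  g <- random_read(300)
  r1 <- substring(g, c(1, 51, 101), c(100, 150, 200))       # length 100
  r2 <- substring(g, c(11, 61, 111), c(100, 150, 200))      # length 90, offset 10
  rs <- read_set(c(r1, r2), paired = TRUE, n1 = 3, n2 = 3,
                 read_length = c(100L, 90L))
  dd <- find_duplicates(rs)
  e <- collect_rounds(dd$distinct, round_config(),
                      graph_config(search_limit = Inf))
  lens <- nchar(dd$distinct$sequences)
  mixed <- lens[e$u] != lens[e$v]
  expect_true(any(mixed))
  expect_true(all(e$ob[mixed] > 0L))
})
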