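test_that("the shifted worked example encodes as AT2G and decodes back", {
  enc <- encode_child("ATGCAT", "GCATCC", offset = 2, direction = "right")
  expect_equal(enc$text, "AT2G")
  expect_false(enc$direction_bit)
  expect_equal(decode_child("GCATCC", "AT2G", direction_bit = FALSE,
                            child_length = 6), "ATGCAT")
})

test_that("a single substitution at position 24 encodes as 24T", {
  set.seed(41)
  r1 <- random_read(100)
  r1 <- mutate_at(r1, 25, "C")
  r2 <- mutate_at(r1, 25, "T")
  enc <- encode_child(r2, r1, offset = 0)
  expect_equal(enc$text, "24T")
  expect_equal(decode_child(r1, "24T"), r2)
})

test_that("a pure one-base shift encodes as the new tail base", {
  set.seed(42)
  r4 <- random_read(100)
  r5 <- paste0(substr(r4, 2, 100), "A")
  enc <- encode_child(r5, r4, offset = 1, direction = "right")
  expect_equal(enc$text, "A")
  expect_false(enc$direction_bit)
  expect_equal(decode_child(r4, "A", FALSE, FALSE, 100), r5)
})

test_that("delta-encoded mismatch positions and rc encoding round-trip", {
  set.seed(43)
  p <- random_read(80)
  c1 <- mutate_at(mutate_at(p, 10, "N"), 50, "N")
  enc <- encode_child(c1, p, 0)
  # first position absolute, second as gap
  expect_match(enc$text, "^9N40N$")
  expect_equal(decode_child(p, enc$text), c1)
  # rc child
  crc <- as.character(reverse_complement(mutate_at(p, 30, "N")))
  enc2 <- encode_child(crc, p, 0, rc = TRUE)
  expect_true(enc2$rc_bit)
  expect_equal(decode_child(p, enc2$text, FALSE, TRUE, 80), crc)
})

test_that("decode(encode(...)) holds over random parent/shift/mutation triples", {
  set.seed(44)
  bases <- c("A", "C", "G", "T")
  n_ok <- 0L
  for (i in 1:4000) {
    Lp <- sample(20:60, 1)
    p <- random_read(Lp)
    o <- sample(0:(Lp - 2), 1)
    dirn <- sample(c("left", "right"), 1)
    # equal-length layout: the uncovered flank has exactly `o` bases
    ov <- Lp - o
    child <- if (o == 0) p
             else if (dirn == "right") paste0(substr(p, o + 1, Lp), random_read(o))
             else paste0(random_read(o), substr(p, 1, ov))
    nmut <- sample(0:3, 1)
    if (o == 0 && nmut == 0) nmut <- 1
    mpos <- if (dirn == "right") sample(ov, min(nmut, ov)) else
      o + sample(ov, min(nmut, ov))
    for (mp in mpos) {
      child <- mutate_at(child, mp, sample(setdiff(bases, substr(child, mp, mp)), 1))
    }
    rc <- runif(1) < 0.3
    child_in <- if (rc) as.character(reverse_complement(child)) else child
    enc <- encode_child(child_in, p, o, dirn, rc = rc)
    expect_identical(decode_child(p, enc$text, enc$direction_bit, rc, Lp),
                     child_in)
    n_ok <- n_ok + 1L
  }
  expect_equal(n_ok, 4000L)
  # unequal lengths: the offset is recovered from the substring length and
  # the two read lengths
  for (i in 1:200) {
    Lp <- sample(30:50, 1)
    Lc <- sample(20:(Lp - 5), 1)
    p <- random_read(Lp)
    # right shift: child tail must overhang, so o > Lp - Lc
    o <- sample((Lp - Lc + 1):(Lp - 2), 1)
    child <- paste0(substr(p, o + 1, Lp), random_read(o + Lc - Lp))
    enc <- encode_child(child, p, o, "right")
    expect_identical(decode_child(p, enc$text, FALSE, FALSE, Lc), child)
    # left shift: child head overhangs by o
    o2 <- sample(1:5, 1)
    child2 <- paste0(random_read(o2), substr(p, 1, Lc - o2))
    enc2 <- encode_child(child2, p, o2, "left")
    expect_identical(decode_child(p, enc2$text, TRUE, FALSE, Lc), child2)
  }
})

test_that("malformed encoded strings raise corruption errors", {
  expect_error(decode_child("ACGT", "2", child_length = 4), "malformed")
  expect_error(decode_child("ACGT", "A5", child_length = 4), "malformed")
  expect_error(decode_child("ACGT", "9T", child_length = 4), "out of range")
})

test_that("DFS stream emits backtracking counts between siblings", {
  set.seed(45)
  r1 <- random_read(40)
  r2 <- mutate_at(r1, 5, setdiff(c("A", "C", "G", "T"), substr(r1, 5, 5))[1])
  r3 <- mutate_at(r2, 15, setdiff(c("A", "C", "G", "T"), substr(r2, 15, 15))[1])
  r4 <- mutate_at(r1, 30, setdiff(c("A", "C", "G", "T"), substr(r1, 30, 30))[1])
  rs <- read_set(c(r1, r2, r3, r4))
  dd <- find_duplicates(rs)
  edges <- collect_rounds(dd$distinct, round_config(n_rounds = 10, k1 = 13),
                          graph_config(search_limit = Inf))
  f <- kruskal_msf(4, edges)
  expect_equal(f$parent_of, c(NA, 1L, 2L, 1L))
  b <- dfs_encode(f, dd$distinct, dd)
  # preorder 1,2,3 then two pops back to the root before visiting 4
  expect_equal(length(b$s1), 5L)
  expect_equal(b$s1[1], r1)
  expect_equal(b$s1[4], "2")
  expect_equal(b$emit_nodes, c(1L, 2L, 3L, 4L))
  # a single root with no children has one raw line and no backtracking
  f1 <- kruskal_msf(1, edges[0, ])
  b1 <- dfs_encode(f1, read_set(r1), find_duplicates(read_set(r1)))
  expect_equal(b1$s1, r1)
})

test_that("order-preserving ID renumbering matches the seven-read example", {
  ids <- renumber_ids(7, is_duplicate = c(FALSE, FALSE, TRUE, FALSE, FALSE,
                                          TRUE, FALSE),
                      is_singleton = c(FALSE, TRUE, FALSE, FALSE, FALSE,
                                       FALSE, FALSE))
  expect_equal(ids, c(1L, NA, NA, 2L, 3L, NA, 4L))
})

test_that("pair distances count unprocessed reads between mates", {
  # mates adjacent in visiting order
  ps <- pair_distance_stream(c(1L, 4L, 2L, 5L, 3L, 6L), n1 = 3)
  expect_equal(ps$distances, c(0L, 0L, 0L))
  expect_equal(ps$order_bits, rep(TRUE, 3))
  # processed reads are removed from the interval before counting
  ps2 <- pair_distance_stream(c(1L, 2L, 4L, 3L, 5L, 6L), n1 = 3)
  # pair (1,4): rank interval (1,3), rank 2 unprocessed -> 1
  # pair (2,5): interval (2,5), ranks 3 (processed) and 4 -> 1
  # pair (3,6): interval (4,6), rank 5 processed -> 0
  expect_equal(ps2$distances, c(1L, 1L, 0L))
  expect_equal(ps2$pair_ids, 1:3)
  # brute-force recount oracle on random permutations
  set.seed(46)
  for (trial in 1:10) {
    n1 <- 30
    vo <- sample(2L * n1)
    ps3 <- pair_distance_stream(vo, n1)
    rank_of <- integer(2 * n1); rank_of[vo] <- seq_len(2 * n1)
    processed <- logical(2 * n1)
    k <- 0L
    for (r in seq_len(2 * n1)) {
      i <- vo[r]
      if (processed[i]) next
      k <- k + 1L
      j <- if (i <= n1) i + n1 else i - n1
      between <- vo[seq(r + 1L, rank_of[j] - 1L)[seq_len(max(0, rank_of[j] - r - 1L))]]
      expect_equal(ps3$distances[k], sum(!processed[between]))
      processed[c(i, j)] <- TRUE
    }
    # decoding recovers the exact mate ranks
    pd <- hasgraph:::.pair_decode(2L * n1, ps3$distances, ps3$order_bits)
    file1 <- vo[pd$rank1]
    file2 <- vo[pd$rank2]
    expect_true(all(file1 <= n1))
    expect_equal(file2, file1 + n1)
  }
})
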