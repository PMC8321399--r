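---
title: "Compressing short reads on a Hamming-shifting graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressing short reads on a Hamming-shifting graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hasgraph)
```

## The model

High-coverage short-read sequencing produces three kinds of redundancy that
a reference-free compressor can exploit: exact duplicate reads (including
reverse-complement duplicates), reads that differ by a handful of base-call
errors, and reads that overlap because fragmentation starts are nearly
random. `hasgraph` turns these into a graph on the *distinct* reads, the
Hamming-shifting graph: two reads are linked when their best overlap layout
has a small *mismatching distance* — the Hamming distance of the overlap
plus the (non-zero) shifting offset. Each node carries the number of
duplicate copies of its read; each edge carries the mismatching bases and
the offset, so either endpoint can be reconstructed exactly from the other.

For compression the edge weight is

$$w(e) = 3\,mb + ob,$$

where `mb` is the number of mismatching bases in the overlap and `ob` the
offset. The factor 3 reflects the encoded cost of a mismatch (position
digits plus the substituted base, about three characters) against one
character per offset base. A minimum spanning forest (MSF) of this graph,
found with Kruskal's algorithm over a disjoint-set structure, minimizes the
total edge weight, and every non-root read is stored only as its delta
against its parent: the uncovered ("shifting") substring followed by
mismatch items, e.g. child `ATGCAT` against parent `GCATCC` at offset 2
becomes `AT2G`. The weight is a *proxy* for the realized code length
(mismatch positions encode in one to three digits, delta-encoded), so the
forest minimizes total weight exactly and total characters approximately;
on exhaustively enumerated small instances the realized character total can
exceed the character-optimal spanning tree by a character or two.

## Finding light edges without all-pairs comparison

Comparing all pairs of reads is quadratic and infeasible, so candidate
edges are only sought between reads that share a *k-minimizer* (the
smallest k-mer under a fixed ordering; windows containing `N` are
ineligible) or a *k-maximizer*. Reads sharing a selected k-mer form a
block; inside a block, members are sorted by the anchor position and each
read is aligned against up to `search_limit` (default 32) predecessors,
with the anchor fixing the layout in O(L) per pair. A single k is brittle —
one mismatch can break every shared window of one size but not of a smaller
size — so the search runs over a strictly decreasing panel
`k1, k1-1, ..., k1-n+1` (defaults `n = 20`, `k1 = 29`), and the same panel
is repeated with maximizers unless the speedy mode is chosen
(`round_config(use_maximizers = FALSE)`), which roughly halves the work for
a small loss in edge quality. Edges are pooled across rounds, the lightest
kept per read pair, and fed to Kruskal in nondecreasing weight order.

The probability that a single round co-blocks two overlapping reads with
`s` offset bases and `t` differing k-mers in the overlap is, under the
uniform-minimizer hypothesis,

$$p(k) = \left(\frac{L-k+1-(s+t)}{L-k+1}\right)^2,$$

and `n` independent rounds detect the pair with probability
$1-\prod_i (1-p(k_i)) > 1-(1-\min_i p(k_i))^n$ (`p_single()`, `p_multi()`).
With 20 rounds a per-round probability as low as 0.15 still gives better
than 0.961 overall. One nuance that the package's Monte-Carlo checker
(`monte_carlo_coblocking()`) makes visible: the squared form treats the two
reads' minimizer draws as independent, but under one shared random ordering
both minimizers equal the minimum over the union of windows, whose
probability of landing in the `c` common windows is exactly
$c/(2(L-k+1)-c)$ — slightly larger. The closed form is therefore a mild
lower bound (they agree to first order), which is the safe direction for
the detection guarantee; the checker reports both values.

## Encoding streams

Duplicates are removed first: reads are blocked by their canonical
31-minimizer and its position (a key invariant under reverse complement)
and verified by full string comparison, distinguishing same-strand from
reverse-complement copies. The distinct reads then carry the forest, which
is serialized into the stream layout:

1. a text stream of encoded strings in depth-first preorder (root reads
   raw), with digits-only *backtracking lines* giving the number of upward
   steps before the next descent (trees are separated by an empty line;
   trailing pops are omitted);
2. a bit stream for the shifting direction of each child;
3. a bit stream flagging children encoded on their reverse-complement
   strand;
4. a bit stream flagging nodes that have duplicates; and
5. pairs of varint counts (same-strand copies, rc copies) for flagged
   nodes.

Encoded strings always contain at least one letter while backtracking lines
are pure digits, so the two line kinds never collide. Text and bit streams
are entropy-coded with a block-sorting backend (base R's bzip2); the
paired-end distance stream uses an LZMA backend (xz). The archive is
self-describing (magic, version, mode flags, read lengths, per-stream
metadata and checksums).

In the order-preserving single-end mode, encoded strings are emitted in
original file order instead; duplicates become empty lines, and a parent-ID
stream gives every non-root (and every duplicate) the renumbered ID of its
reference read. Because duplicate copies and *singletons* (roots with no
children and no duplicates) can never be referenced, IDs are renumbered
after removing them; a one-bit-per-root stream marks singletons so the
decoder can rebuild the same ID space before resolving references. With
seven reads, duplicates \{3, 6\} and singleton \{2\}, reads 1, 4, 5, 7
receive IDs 1–4 (`renumber_ids()`).

Paired-end files are concatenated vertically and compressed like a
single-end set; the pairing is restored from a distance stream: pairs are
processed by their first-seen mate in the visiting order (each distinct
node followed by its duplicate copies), and for each pair the number of
*not-yet-processed* reads strictly between the two mates' ranks is stored,
maintained with a Fenwick tree, plus one bit for which file the
earlier-visited mate came from. The order-preserving paired mode adds the
original index of each pair. When the two files have different read
lengths, one extra bit per node records its length class — the tree decoder
needs each child's length before the pairing streams can be read.

### Unequal read lengths

With unequal lengths the offset is recovered at decode time from the
shifting-substring length together with the two read lengths and the
direction bit. A contained alignment (the shorter read strictly inside the
longer, no overhang) would leave an empty shifting substring for *any*
offset and be undecodable, so edge construction admits a layout between
unequal-length reads only when each read overhangs the other on exactly one
side; offset-0 layouts between unequal-length reads are rejected, which is
also what keeps the encoding consistent for mixed-length paired files. For
such pairs the offset entering the weight is taken in the canonical layout
(smaller read index on its forward strand), since the start displacement of
an unequal-length layout differs between the two strand orientations.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_rounds` | 20 | number of k sizes in the panel |
| `k1` | 29 | largest k (at most 31; panel must stay ≥ 4) |
| `use_maximizers` | TRUE | repeat the panel with k-maximizers |
| `ordering` | lexicographic | k-mer ordering; `hashed` (seeded invertible 64-bit mix) approximates the uniform-ordering regime of the probability model |
| `search_limit` | 32 | preceding block members compared per read |
| `max_weight` | read length | heaviest admissible edge; an edge costing as much as a raw read is useless |

Ties are broken deterministically everywhere (leftmost window, forward
strand before reverse complement, stable arrival order among equal-weight
edges, smallest index as tree root), so archives are byte-reproducible.

## The synthetic-data generator

`simulate_reads()` emulates the statistical structure the method exploits:
a uniform random genome, uniform fragmentation at the requested coverage,
independent per-base substitutions to a different base, reverse-strand
sampling, exact duplicates, and (for paired mode) a normal insert-size
distribution with the standard forward–reverse mate orientation, including
different lengths for the two files. It does not emulate indels, quality
profiles, coverage biases, repeat structure, or platform-specific error
modes — passing round trips therefore demonstrate correctness of the codec
on substitution-and-shift structured data, and the compression ratios
reported on it should not be read as predictions for real libraries (real
genomes' repeats make blocks larger and anchors more ambiguous). Defaults
follow the validation conditions used throughout the tests: 100-bp reads at
30× coverage with a 1% substitution rate.

## Numerical and degenerate-input choices

* Reads containing characters outside `{A,C,G,T,N}` are a hard parse error.
* A read whose every window contains `N` joins no block and ends as a
  singleton root stored raw; `N` matches `N` in overlaps and may appear as
  a mismatch base.
* A read equal to its own reverse complement counts extra copies as
  same-strand duplicates.
* Empty inputs produce a valid archive that decodes to an empty read set.
* Problem sizes in the tests — simulations of roughly 1,000–1,100 reads for
  the round-trip checks, 300 distinct reads for the exhaustive-oracle
  recall experiment, 8-read instances for spanning-forest enumeration —
  keep every property verifiable by brute force while exercising all code
  paths; they are the package's validation scale, with the pipeline itself
  linear-ish in reads × rounds beyond that.

## Known limitations

* Only sequence lines are compressed; headers and qualities are discarded
  and decompression emits synthetic headers with placeholder qualities.
* One shifting event per edge; indels are not modelled.
* Order-free mode does not preserve the interleaving of duplicate copies
  (they re-materialize next to their representative), which is why exact
  file order needs the order-preserving mode.
* The whole read set, its index, the candidate edges and the forest are
  held in memory. Spilling per-weight edge bins to disk would be the
  natural extension for datasets orders of magnitude beyond the validation
  scale; at that scale an in-memory design is simpler and strictly faster,
  so no spill path is implemented.
* Archive bytes are not interchangeable with any external tool; the format
  is this package's own container.
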