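---
title: "Assembly and profiling on a colored de Bruijn graph: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly and profiling on a colored de Bruijn graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacolor)
```

This vignette is the package's account of its science: the graph and
traversal model, the demultiplexing statistic, what every tunable
parameter means and why its default is what it is, what the simulator
does and does not emulate, and the numerical corner cases.

## The graph model

A de Bruijn graph stores the DNA words of length k ("k-mers") occurring
in a read set; words overlapping by k − 1 are joined by edges. We store
each word once under its **canonical form**, the lexicographic minimum of
the word and its reverse complement, with a single coverage counter
pooling both strands. Two choices follow from this:

* **k is odd** (default 31). An even-length word can equal its own
  reverse complement, which would make strand bookkeeping ambiguous; odd
  k forbids that outright. Note one consequence of canonical storage: a
  window and the next can collapse to the *same* vertex when one is the
  reverse complement of the other (e.g. both width-3 windows of `ACGT`
  canonicalize to `ACG`), producing a legitimate self-extension edge.
* **Edges are read-observed.** An edge mark is set only when the two
  adjacent windows actually occurred side by side in some read, never
  inferred by looking up all four possible neighbors. This keeps the
  graph a record of evidence, and it is testable: every marked edge
  resolves to a stored vertex by construction.

Vertices live in S independent maps ("shards") addressed by a pure hash
of the packed word. This is a logical stand-in for a distributed hash
table: single-process here, but because `shard_of` is a pure function of
the k-mer alone, results are identical for S = 1 and S = 8 (asserted in
the tests), and the contract would survive a parallel implementation.
Coverage counters saturate at 2^16 − 1 (saturation is counted and
reported); no coverage floor is applied at build time — erroneous k-mers
are stored and then excluded by the *traversal*, not by the store.

## Assembly: local coverage, markers, votes

Metagenome coverage has no single peak, so nothing here consults a
global coverage distribution; the coverage histogram the package can
print is diagnostic only, and the assembler's interfaces accept no such
histogram. Instead:

1. **Seeds** are maximal paths whose internal vertices have exactly one
   *present* predecessor and successor. Presence means coverage ≥
   `cov_present` (default 2): a k-mer seen once is most plausibly a
   sequencing error at the ~0.25% error rates this package targets.
   Seeds shorter than `min_seed_nt` (default 2k − 1, i.e. two
   overlapping windows' worth of sequence) are noise and discarded.
2. **Seed-local statistics.** Each seed's coverage mode and minimum are
   computed from exactly its own vertices. Mode ties break toward the
   smaller value — the conservative choice, since overestimating the
   mode loosens the repeat cutoff.
3. **Markers.** A read is anchored at its first k-mer (in read order)
   that lies on the path with coverage in `[min, repeat_mult × mode]`
   (`repeat_mult` = 3). The upper cutoff avoids anchoring reads at
   repeat k-mers whose path position would be ambiguous. During
   extension beyond the seed the future path is unknown, so a read is
   anchored at the first of its eligible k-mers that joins the path.
4. **Votes.** At a branch, each markered read that (laid along the path
   from its anchor) covers the decision position votes for the base it
   reads out. If marker votes are not decisive, mates of forward
   on-path reads whose projected position falls within
   `insert_mean ± 3 insert_sd` vote for candidates whose k-mer they
   contain. A candidate wins iff it has at least `vote_min` (2) votes
   and at least `vote_ratio` (2) times the runner-up. Everything else
   stops the walk: `ambiguous` (no decisive winner), `conflict` (the
   two vote stages decisively disagree), `cycle` (re-entering the
   current path), or `no-successor`. There is deliberately no random
   tie-break — reproducibility and a low misassembly rate are worth
   more than contiguity, and every one of these constants is a
   function argument.

The insert-size model is estimated from the data: pairs with both mates
markered on one seed give outer fragment lengths; the top and bottom 5%
are discarded and the mean/sd of the rest are used (≥ 30 usable pairs
required, otherwise a configured prior with a warning). Scaffolding
links two contigs when ≥ 3 pairs agree in orientation and implied gap;
competing links for the same contig end are resolved by support, and the
gap is filled with `max(1, round(median implied gap))` Ns.

Deduplication drops contigs with identical canonical sequence and
contigs whose entire k-mer walk is owned by a single longer contig. As a
pure optimization with the same effect, a seed whose k-mers are all
already claimed by an earlier contig (seeds are processed longest-first
in a deterministic order) is skipped before extension.

## Coloring and demultiplexing

Coloring happens after assembly and cannot affect it: colors are added
only to pre-existing vertices, never touching topology or coverage (the
test suite asserts byte-identical contigs with and without coloring).
References are grouped in independent **namespaces** — genome references
and CDS references answer uniqueness questions separately. Color sets
are interned: vertices sharing a combination share one stored set.
Coloring is idempotent; a (namespace, reference-name) pair keeps its
color id on re-coloring.

Per-reference abundance uses only signal that is unambiguous:

* `matched(c)`: distinct graph k-mers carrying color c. Positions are
  gone after graph construction, so this counts distinct words, not
  occurrences.
* `mode_u(c)`: the mode coverage over k-mers whose color set is exactly
  {c} (ties low). Uniquely colored k-mers are the only ones whose
  coverage can be attributed to one reference without a model.
* `observations(c) = matched(c) × mode_u(c)`, normalized by the summed
  coverage of all colored k-mers in the namespace.

The estimator quantizes at the integer mode, so its relative error is
roughly ±0.5/mode; at the package's reference scale (ten 100 kb genomes,
30× top depth) that keeps the maximum absolute proportion error under
0.01. Two identical references have no uniquely colored k-mers at all:
both are reported with proportion 0 and a `no_unique_kmers` flag — the
honest answer, recoverable by classifying at a higher taxon instead.

**Taxonomic profiles** assign each colored vertex's full coverage to the
nearest common ancestor of its color set's taxa. We weight the shared
coverage once at the LCA rather than splitting it among the leaf taxa:
splitting would require an abundance model for exactly the references
whose signal is ambiguous, while the LCA assignment is model-free and
keeps an exact integer conservation law (Σ direct assignments = Σ
colored coverage) that the tests assert. Per-rank tables report subtree
sums plus an explicit "unclassified at this rank" bucket, so every rank
row set sums to the same total. **GO profiles** add a vertex's coverage
once per distinct term among its colors' annotations, flat — no
propagation along the ontology DAG, since ancestor propagation would
change the meaning of the printed numbers; a vertex whose colors carry
no annotation lands in an `unannotated` row.

## The simulator: what it emulates, what it does not

`sim_config()` defaults are the package's reference study conditions, a
desk-scale mirror of a 100-genome community design: 10 community genomes
of 100 kb, abundances ∝ rank^−0.5, 101 nt paired reads, 0.25%
substitution errors, mean insert 400 nt, 1% host contamination, and
enough pairs for 30× expected depth on the most abundant genome. The
insert sd defaults to 10% of the mean: only the mean is part of the
design, but scaffolding and mate votes need a realistic spread, and 10%
is typical of size-selected short-insert libraries. The power-law
proportion is interpreted as the *pair-sampling* probability; with
constant read length it equals the nucleotide proportion, which is what
the profiling module estimates.

Genomes are i.i.d. uniform ACGT. That gives the assembler an easier
substrate than real genomes: virtually no repeats, no shared gene
content, no GC or coverage bias, no indels, no quality-score structure,
no strain mixtures. Passing the end-to-end tests therefore demonstrates
the machinery (graph, traversal, demultiplexing, conservation laws) on
data whose truth is exactly known — not performance on real
metagenomes, where repeats and inter-genome homology dominate the
difficulty. The near-duplicate generator (a copy of a source genome
with i.i.d. substitutions at a configured divergence) exists precisely
to reintroduce the one hard phenomenon the profiler must handle: the
reference-duplication failure mode. Truth tables record every read's
genome, 0-based start and strand, so calibration is measured against
truth rather than against the generator's own bookkeeping.

## Evaluation rules

Contig placement uses maximal exact matches ≥ 31 nt (runs of matching
k-mer windows on a diagonal), chained colinearly; substitutions are
tolerated by chaining across the mismatch gap, and chains are extracted
greedily so a contig wrapping a circular origin yields its two abutting
chains. A contig ≥ 500 nt passes iff its best single chain covers ≥ 98%
of it, or exactly two chains abut the start and end of one reference
with combined breadth ≥ 98% (the circular exemption). Exact anchors
replace inexact alignment deliberately: the synthetic truth data are
exact or near-exact, and the 98% breadth rule is preserved verbatim.
Inter-anchor gap bases approximate mismatch counts and are labeled
approximate in reports. Breadth per genome is the union (never the sum)
of placement intervals over the reference.

## Numerical and degenerate-input choices

* Canonical comparisons are byte comparisons on A < C < G < T; contig
  output orientation is the lexicographic minimum of sequence and
  reverse complement, making output deterministic and strand-invariant.
* Windows containing any non-ACGT symbol are skipped (soft-masked
  lowercase is uppercased first); records shorter than k are counted
  and skipped, never fatal.
* Empty inputs yield empty results with a warning, not errors: an empty
  read stream gives an empty graph and an empty assembly.
* Mode ties break low everywhere a mode is taken.
* Insert resampling retries 50 times when a draw exceeds the genome,
  then clamps; draws are truncated below at one read length.
* All simulator stages derive their RNG stream from the configured seed
  plus a fixed per-stage offset, so outputs are byte-identical across
  runs and components can be regenerated independently.

## Problem sizes used by the tests

The suite exercises hand-enumerable toys (3-mers on 5 nt strings, toy
branches, 20-vertex colored graphs) for every rule, property checks on
randomized inputs under fixed seeds (canonicalization involution, strand
symmetry, LCA versus a brute-force root-path oracle on a ~50-node
taxonomy, N50 versus a re-implementation), and one full-scale run of the
reference conditions above (ten 100 kb genomes, ~75k pairs) for breadth,
misassembly rate and proportion recovery. Calibration quantities are
recomputed at 50,000 pairs (substitution rate, ≥ 10⁷ bases) and 10⁶
pairs (insert mean); the power-law slope is exact. These sizes are the
package's chosen reference scale: large enough that the stochastic
checks sit well inside their 3σ bands, small enough to run attended.

## Known limitations

* k ≤ 31 (one 64-bit word); no spaced seeds or minimizers.
* No graph simplification, error correction, or bubble popping — the
  graph is never modified, by design; the cost is shorter contigs at
  coverage dips.
* The voting heuristics are this package's own conservative stand-in
  for the original line of seed-and-extend assemblers whose exact rules
  are not published in full; they favor stopping over guessing.
* Scaffolding only links contigs whose anchors agree in relative
  orientation; opposite-orientation joins are left unlinked.
* Mismatch/indel counts from anchor gaps are approximations, not
  alignments.
* GO terms are counted flat; taxonomic ranks assume the canonical
  eight-rank chain.
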