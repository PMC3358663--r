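---
title: "Predicting gene structure from transcript clusters"
author: "spliceAgree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting gene structure from transcript clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceAgree)
```

# The problem

A eukaryotic gene is transcribed into a pre-mRNA whose introns are excised by
the spliceosome; alternative splicing produces several mature isoforms from
the same locus. Given the genomic sequence of a locus and a cluster of
transcript sequences — error-prone, truncated ESTs together with a few
curated full-length mRNAs — we want the exon–intron structure of the gene:
the set of genomic exons, one spliced alignment per transcript consistent
with that set, and the list of introns with their splice sites.

Two difficulties shape the method. First, a single transcript often has many
plausible spliced alignments (repeats, sequencing errors and junction
ambiguity all create alternatives), so committing to one alignment per
transcript *before* looking at the rest of the cluster loses information.
Second, picking one alignment per transcript so that the whole cluster
agrees on a minimal exon set is NP-hard, so the consensus step needs a
careful exact/heuristic split.

`spliceAgree` therefore works in four stages, each exposed as ordinary
functions:

1. **Maximal pairings** (`findMaximalPairings`). A *pairing* `(p, t, l)` is
   an occurrence of a common substring of the transcript `P` and the genome
   `T`; it is *maximal* if it cannot be extended by one character on both
   sequences in either direction. Maximal pairings of length at least
   `ellE` are the atoms from which every spliced alignment is built.
2. **Embedding graph** (`buildEmbeddingGraph`). A directed graph on the
   maximal pairings; an edge `(v1, v2)` means the two pairings can be
   consecutive in a *representative embedding* — a chain of non-overlapping
   pairings whose transcript-side gaps are at most `ellD` and whose
   genome-side drift is either at most `ellD` (same exon) or at least
   `ellI` (an intron). The graph represents all candidate spliced
   alignments implicitly, in `O(|V|^2)` edge tests.
3. **Composition enumeration** (`enumerateCompositions`). A visit of the
   graph from its *extended sources* extends partial alignments edge by
   edge, dispatching on the overlap pattern of consecutive pairings
   (overlap on both sequences, on one, or on neither — with a same-exon and
   an intron sub-case each), then merges runs of near-colinear pairings
   into *aligned factors* (exons). The result is a set of pairwise-distinct
   *compositions*: per-transcript spliced alignments with per-factor edit
   distances.
4. **Consensus and intron refinement** (`buildFactorUniverse`,
   `solveMFAExact`/`solveMFAGreedy`, `selectCompositions`,
   `extractIntrons`, `reduceIntrons`). The genomic factors of all
   compositions are unified into a *factor universe*; the Minimum
   Factorization Agreement (MFA) problem asks for a minimum factor subset
   such that every transcript keeps at least one composition inside it.
   The selected compositions yield introns, classified by their terminal
   dinucleotides (GT–AG and GC–AG: U2 spliceosome; AT–AC: U12; anything
   else unclassified), and a reduction step merges junction calls that are
   probably noise into nearby supported introns.

`runPipeline()` chains the stages; the `spliceagree` script in the
package's `exec/` directory exposes them from a shell.

# Parameters

All coordinates are 0-based and half-open internally; GTF/GFF3 exporters
convert to 1-based closed coordinates.

| parameter | default | meaning |
|---|---|---|
| `ellE` | 15 nt | minimum pairing length. Short enough to survive ~1 error per 15 nt of EST sequence; long enough that chance 15-mers are rare in a locus-sized genome. |
| `ellD` | 20 nt | maximum mismatch-gap span inside one exon, and the bound on the genome/transcript drift for same-exon continuation. |
| `ellI` | 60 nt | minimum intron length; roughly the shortest human intron. |
| `maxFactorEdit` | 0.05 | per-factor edit budget: 5% of the factor length, floor of 2 operations. Values ≥ 1 are absolute counts. |
| `b` | 4 | intron-reduction error bound: a junction call may be moved onto a supported intron if re-aligning its flanks costs at most `b` extra edits. |
| `minFactorLen` | 10 nt | factors shorter than this are considered unsupported and their composition is dropped. |
| `endClip` | 30 nt | tolerated unaligned transcript end; EST termini are low quality and often fail to seed a pairing. |
| `sourceWindow` | 50 nt | vertices whose transcript start is within this window are visit sources in addition to in-degree-0 vertices. |
| `shiftWindow` | `2b + 6` nt | search window of the b-reducibility test. |
| `boundaryTol` | 0 nt | boundary tolerance when unifying factors; upstream splice refinement already canonicalises junctions, so exact matching is the default. |
| `exactLimit` | 24 | largest factor universe solved exactly; larger instances fall back to the greedy solver. |

# Design choices

Several points are genuinely open in a method of this kind; the package
resolves them as follows.

**Pairing index.** Maximal pairing enumeration is implemented as a compiled
rolling-row scan over the `|P| × |T|` match structure (`O(|P|·|T|)` time,
`O(|T|)` memory) rather than a suffix-tree traversal. At locus scale (tens
of kb × a few kb per transcript) the scan is fast, exact and far simpler to
verify against brute force; the enumerated set is identical by
construction. `N` bases never match anything — including other `N`s — so
low-quality stretches split seeds rather than bridging them.

**Pairings exactly `ellE` long are vertices.** The length threshold is
applied as `l >= ellE` everywhere; tightening it is equivalent to raising
`ellE` by one.

**Edge orientation.** The two compatibility conditions alone admit edges
that move backwards along the transcript; an orientation constraint
(`p1 < p2`, ties by `t1 < t2`) is added so that every edge advances the
embedding. Directed cycles among overlapping pairings of repeats remain
possible and are tolerated: the visit walks simple paths only, and on
repeat-bearing instances the emitted factor sets match the exhaustive
chain enumeration (this is asserted by the tests rather than assumed).

**Extended sources.** The visit starts from vertices of in-degree zero
united with vertices whose transcript start is within `sourceWindow` of the
5' end. The union is a superset of all chain heads, so no representative
embedding is missed; spurious starts are filtered later by the retention
rules.

**Overlap cases.** When consecutive pairings overlap on the transcript and
the genomic drift is intron-sized, the junction placement is ambiguous (a
suffix of the donor exon equals a prefix of the acceptor exon). The cut is
chosen by splice-pattern priority GT–AG > GC–AG > AT–AC > other, then by
the leftmost donor. When pairings overlap on both sequences with
intron-sized drift — the signature of a genomic tandem repeat — *both*
interpretations (an intron, or one long exon absorbing the repeat) are
emitted and the consensus stage arbitrates; the long-exon branch usually
dies at the per-factor edit budget unless the repeat is genuinely present
in the transcript.

**Gap splitting.** For disjoint pairings with intron-sized drift, the
genomic gap is split into an exonic prefix, the intron, and an exonic
suffix so that the edit distance between the transcript gap and the
concatenated flanks is minimal; the search is restricted to flank
combinations of total length at most twice the transcript gap, which
provably contains every optimum. Ties follow the same splice-pattern
priority. The edit-cost model is unit-cost Levenshtein throughout (the
choice of cost model is not dictated by the problem; unit cost keeps every
threshold interpretable as an operation count).

**Retention.** A candidate composition is kept only if every factor is at
least `minFactorLen` long and within its edit budget, unaligned transcript
ends are at most `endClip`, and all genomic gaps between factors are at
least `ellI`. Compositions with identical genomic factor lists are
reported once (lowest total edit wins). A per-source cap of 10,000
embeddings and a per-transcript cap of 500 retained compositions guard
against pathological repeat structures; hitting a cap is reported as a
warning, never silently.

**Factor unification.** Factors are keyed by their *splice* boundaries: a
boundary adjacent to an intron must match exactly (within `boundaryTol`),
while a boundary at a transcript end is free. Truncated ESTs therefore
share the consensus factor of the full exon, whose representative takes
the widest observed extent; without this, every truncation depth would
mint a new "exon" and no minimal consensus could exist. A free boundary
may also *overhang* its group representative by up to `max(8, boundaryTol)`
nt: the terminal pairing of a 3'-truncated EST frequently chance-extends a
few bases into the intron (each extra base survives with probability 1/4),
and a transcript end carries no splice-site evidence that could justify a
distinct factor.

**MFA solving.** The exact solver does branch-and-bound over the candidate
factor sets of one unsatisfied transcript at a time, pruning on the best
cardinality found; every minimum solution is a union of one factor set per
transcript, so the search is complete, and ties resolve to the
lexicographically smallest index set. It is used up to `exactLimit = 24`
factors (the problem is NP-hard). Beyond that, a greedy heuristic adds the
factor satisfying the most transcripts (falling back to reducing the
tightest deficits) and flags its result as possibly non-minimal.
Transcripts with no surviving composition are excluded from the instance
with a warning rather than failing the locus: one unalignable EST must not
block the consensus.

**Post-reduction exon set.** The MFA pass necessarily works on the
compositions as aligned, so an EST whose sequencing error shifted one
junction contributes a slightly off exon variant that the agreement set
must include. After the intron-reduction step re-aligns those junction
calls onto supported introns, the pipeline re-unifies the factors of the
(now corrected) chosen compositions and reports that union as the final
consensus exon set; with one composition per transcript the agreement set
is simply the union, so no second search is needed. On error-free input
the second pass is the identity.

**Intron reduction.** Junction calls are partitioned into pairs
`(intron, supporting transcript)`: RefSeq-supported pairs (`R`) and, among
the rest, GT–AG (`C1`), GC–AG (`C2`), AT–AC (`C3`) and everything else
(`N`). Only `N` pairs are reduction candidates; each is moved to the first
reducible target scanning `R`, then `C1`, `C2`, `C3` (nearest interval
first, ties leftmost) where reducibility means the flanking factors
re-align at the target boundaries within `b` extra edits and within
`shiftWindow`. RefSeq transcripts are treated as trusted because they are
curated, full-length and essentially error-free; a transcript is flagged
RefSeq when its id matches `NM_`/`NR_` or appears in a user-supplied list.
The U2/U12 call is purely dinucleotide-based and labelled as such;
position-weight-matrix scoring of minor-spliceosome introns is out of
scope.

# The simulator

`generateGene()` builds a uniform-random locus with planted exons
(default: 6 exons of 80–200 nt separated by gaps of 70–250 nt, 120 nt
flanks) and a default isoform set containing the classic alternative
splicing events: a competing-exon pair (exons 3 and 4 never co-occur) and
a cassette exon (exon 2, skipped by the third isoform). Splice-site
dinucleotides are planted at every true junction; 98% of introns are GT–AG
(human-like), the rest GC–AG or AT–AC, with introns sharing a donor or
acceptor position forced to one class so the planted letters never
conflict. An optional flag duplicates the end of the first exon at the
start of the following intron to exercise the tandem-repeat branch.

`generateTranscripts()` emits, per isoform, one exact full-length RefSeq
mRNA and a configurable number of ESTs: contiguous fragments (geometric
5'/3' truncations, mean 20 nt, capped at 20% of the transcript per end)
perturbed by i.i.d. substitutions, insertions and deletions in equal
proportion. Everything is deterministic given the seed.

What the simulator does *not* emulate: base-quality-correlated errors,
chimeric or antisense ESTs, paralogous loci, genomic polymorphism between
the transcript source and the reference, and polyA tails. Passing the
round-trip suites therefore shows that the algorithmic chain is faithful
under controlled noise — not that the defaults are tuned for any
particular organism's real EST archive.

The test and acceptance suites run the pipeline on 6-exon / 3-isoform /
~50-EST clusters (about 1.5–2 kb of genome), 20 replicates per condition;
oracle comparisons use 200 random string pairs up to 200 nt and exhaustive
chain or subset enumeration on instances small enough to enumerate
(transcripts ≤ 60 nt, genomes ≤ 150 nt, factor universes ≤ 15). These
sizes make every oracle literal rather than sampled.

# Degenerate inputs and numerical corners

* Empty sequences or non-ACGTN characters are rejected up front.
* A transcript that aligns nowhere yields an empty composition list, a
  warning, and exclusion from the consensus; if *no* transcript aligns,
  the pipeline returns an empty structure and the CLI exits non-zero.
* A single-exon gene produces single-factor compositions and no introns;
  `reduceIntrons` on an empty support table is the identity.
* Junction ties are broken deterministically (splice priority, then
  leftmost donor), vertex and edge orders are canonical, and no stage uses
  randomness, so a rerun on identical input is byte-identical.

# Known limitations

* The spliced alignment model is ungapped within a factor except through
  the edit distance; affine or quality-aware scoring is not attempted.
* The greedy MFA fallback can over-report exons on universes larger than
  `exactLimit`; the run report flags when its trivial lower bound is not
  met.
* Full-length isoform reconstruction (combining compositions into
  transcript models beyond the per-transcript chosen composition) and
  CDS/UTR annotation are outside the package's scope.
* The strand is taken as given; `runPipeline` assumes the genome is
  supplied on the gene strand (transcripts from the opposite strand will
  simply fail to align).
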