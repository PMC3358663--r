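# spliceAgree

Consensus gene-structure prediction from transcript clusters.

Given the genomic sequence of a gene locus and a cluster of transcript
sequences — error-prone, truncated ESTs together with curated full-length
mRNAs — `spliceAgree` predicts the exon–intron structure of the gene: the
minimal set of genomic exons supported by the whole cluster, one spliced
alignment per transcript consistent with that set, and the predicted introns
with their splice sites and U2/U12 classification. It is aimed at genome
annotators and alternative-splicing analyses where a locus must be resolved
from expressed-sequence evidence rather than called ab initio.

## Method

All spliced alignments of a transcript *P* against the genome *T* are
represented implicitly rather than computed one by one:

* A **pairing** (*p*, *t*, *l*) is an occurrence of a common substring of
  length *l* at positions *p* on *P* and *t* on *T*; it is **maximal** when
  it cannot be extended by one character on both sequences in either
  direction.
* The **embedding graph** has the maximal pairings of length ≥ ℓ<sub>E</sub>
  as vertices and an edge (v₁, v₂) whenever
  p₂ − (p₁ + l₁) ≤ ℓ<sub>D</sub> and
  |t₂ − t₁ − (p₂ − p₁)| ≤ ℓ<sub>D</sub> or
  t₂ − t₁ − (p₂ − p₁) ≥ ℓ<sub>I</sub> — i.e. the two pairings can be
  consecutive inside one exon (drift ≤ ℓ<sub>D</sub>) or across an intron
  (drift ≥ ℓ<sub>I</sub>).
* A visit of the graph extends partial alignments according to the overlap
  pattern of consecutive pairings and merges near-colinear runs into
  aligned factors, yielding the **compositions** of each transcript: lists
  of (transcript factor, genomic exon) interval pairs with bounded edit
  distance. Ambiguous junctions are placed by splice-site priority
  (GT–AG > GC–AG > AT–AC), leftmost donor.
* The **Minimum Factorization Agreement** (MFA) problem — NP-hard, solved
  exactly by branch-and-bound up to 24 factors, greedily beyond — selects a
  minimum exon set *F′* such that every transcript keeps at least one
  composition whose exons all lie in *F′* (maximum-parsimony consensus).
* Introns are extracted from the selected compositions, classified by their
  terminal dinucleotides, and a **reduction** step merges junction calls
  that re-align within *b* extra edit operations onto RefSeq-supported or
  canonical introns nearby.

A full account of the model, parameters and design choices is in the
vignette: `vignettes/gene-structure-from-transcripts.Rmd`.

## Worked example

Simulate a 6-exon locus with three isoforms (one cassette exon, one
competing-exon pair), 50 ESTs at a 1% per-base error rate plus one RefSeq
mRNA per isoform, and run the pipeline:

```r
library(spliceAgree)

gene <- generateGene(seed = 42)
gene
#> SimulatedGene: |T|=1965 nt, 6 exons, 3 isoforms, 7 distinct introns

tx <- generateTranscripts(gene, nPerIsoform = c(17, 17, 16),
                          errorRate = 0.01, refseqPerIsoform = 1, seed = 43)
gs <- runPipeline(gene@genome, structure(as.character(tx), names = names(tx)))
gs
#> GeneStructure: 6 consensus exons, 47 transcripts, 7 introns

as.data.frame(consensusExons(gs))[, 1:4]
#>   seqnames start  end width
#> 1   genome   121  248   128
#> 2   genome   464  643   180
#> 3   genome   835  978   144
#> 4   genome  1097 1200   104
#> 5   genome  1398 1550   153
#> 6   genome  1667 1845   179
```

The six consensus exons coincide with the planted exons (`gene@exons`,
0-based, = 120–248, 463–643, 834–978, 1096–1200, 1397–1550, 1666–1845).
Exons 2 and 3 here are the competing pair: no isoform contains both. The
predicted introns carry splice sites, U-type and support counts:

```r
head(as.data.frame(predictedIntrons(gs))[, c("start", "end", "pattern",
                                             "uType", "nSupports",
                                             "refseqSupported")], 3)
#>   start end pattern uType nSupports refseqSupported
#> 1   249 463   GT-AG    U2        31            TRUE
#> 2   249 834   GT-AG    U2        15            TRUE
#> 3   644 834   GT-AG    U2        16            TRUE
```

All seven distinct planted introns are recovered with exact boundaries
despite the sequencing errors; 47 of the 53 transcripts receive a spliced
alignment (six ESTs whose errors leave no composition within the edit
budget are excluded with a warning, visible in `runReport(gs)`).

The same pipeline is available from a shell; it writes GTF (consensus
exons), BED12 (per-transcript compositions), GFF3/JSON (introns) and a run
report:

```sh
spliceagree simulate --seed 9 --out sim
spliceagree run --genome sim/genome.fa --transcripts sim/transcripts.fa --out out
#> consensus exons: 6; introns: 7; outputs in out
```

(The script is installed under the package's `exec/` directory;
`system.file("exec", "spliceagree", package = "spliceAgree")` gives its
path.)

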