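#' @useDynLib spliceAgree, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats rbinom rgeom runif
#' @importFrom utils adist head tail
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges start end width strand
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
NULL

#' Alignment and consensus parameters
#'
#' Container for every tunable threshold of the pipeline.  All coordinates in
#' the package are 0-based, half-open; all lengths are in nucleotides.
#'
#' @slot ellE minimum pairing (seed) length in nt.
#' @slot ellD maximum span, in nt, of a mismatch gap tolerated inside a single
#'   exon (also bounds the transcript-side gap between consecutive pairings).
#' @slot ellI minimum intron length in nt; a genomic gap at least this long
#'   between consecutive aligned factors is interpreted as an intron.
#' @slot maxFactorEdit maximum edit distance allowed between a transcript
#'   factor and its genomic factor; values < 1 are read as a fraction of the
#'   factor length (with a floor of 2 operations), values >= 1 as an absolute
#'   count.
#' @slot b intron-reduction error bound: a junction call may be merged into a
#'   supported one when re-aligning its flanking factors at the new boundaries
#'   costs at most `b` additional edit operations.
#' @slot minFactorLen minimum retained aligned-factor length in nt.
#' @slot endClip maximum number of unaligned nt tolerated at either end of a
#'   transcript before a composition is rejected (EST ends are noisy).
#' @slot sourceWindow transcript-start window (nt): vertices whose transcript
#'   position is within this window are treated as visit sources in addition
#'   to in-degree-0 vertices.
#' @slot shiftWindow maximum junction shift (nt) searched by the
#'   b-reducibility test.
#' @slot boundaryTol tolerance (nt) when unifying near-identical genomic
#'   factor boundaries into one consensus factor.
#' @slot exactLimit largest factor-universe size handled by the exact
#'   branch-and-bound MFA solver.
#' @slot maxEmbeddings cap on embeddings explored per visit source.
#' @slot maxCompositions cap on compositions retained per transcript.
#' @export
setClass("AlignParams",
  representation(
    ellE = "integer", ellD = "integer", ellI = "integer",
    maxFactorEdit = "numeric", b = "integer", minFactorLen = "integer",
    endClip = "integer", sourceWindow = "integer", shiftWindow = "integer",
    boundaryTol = "integer", exactLimit = "integer",
    maxEmbeddings = "integer", maxCompositions = "integer"
  )
)

setValidity("AlignParams", function(object) {
  msg <- character()
  if (object@ellE < 1L) msg <- c(msg, "ellE must be >= 1")
  if (object@ellD < 0L) msg <- c(msg, "ellD must be >= 0")
  if (object@ellI <= object@ellD) msg <- c(msg, "ellI must be > ellD")
  if (object@b < 0L) msg <- c(msg, "b must be >= 0")
  if (object@maxFactorEdit < 0) msg <- c(msg, "maxFactorEdit must be >= 0")
  if (object@minFactorLen < 1L) msg <- c(msg, "minFactorLen must be >= 1")
  if (object@endClip < 0L) msg <- c(msg, "endClip must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an [AlignParams-class] object
#'
#' @param ellE minimum pairing length (nt); default 15.
#' @param ellD maximum mismatch-gap span inside an exon (nt); default 20.
#' @param ellI minimum intron length (nt); default 60, about the shortest
#'   human intron.
#' @param maxFactorEdit per-factor edit budget; default 0.05 (5% of the factor
#'   length, floor of 2 operations).  Values >= 1 are absolute counts.
#' @param b intron-reduction error bound (edit operations); default 4.
#' @param minFactorLen minimum retained factor length (nt); default 10.
#' @param endClip tolerated unaligned transcript end length (nt); default 30.
#' @param sourceWindow visit-source transcript window (nt); default 50.
#' @param shiftWindow junction-shift search window (nt); default `2*b + 6`.
#' @param boundaryTol factor boundary unification tolerance (nt); default 0.
#' @param exactLimit exact MFA solver size limit; default 24.
#' @param maxEmbeddings visit cap per source; default 10000.
#' @param maxCompositions retained compositions per transcript; default 500.
#' @return an `AlignParams` object.
#' @examples
#' alignParams(ellE = 10, ellI = 40)
#' @export
alignParams <- function(ellE = 15, ellD = 20, ellI = 60, maxFactorEdit = 0.05,
                        b = 4, minFactorLen = 10, endClip = 30,
                        sourceWindow = 50, shiftWindow = 2 * b + 6,
                        boundaryTol = 0, exactLimit = 24,
                        maxEmbeddings = 10000, maxCompositions = 500) {
  new("AlignParams",
    ellE = as.integer(ellE), ellD = as.integer(ellD), ellI = as.integer(ellI),
    maxFactorEdit = as.numeric(maxFactorEdit), b = as.integer(b),
    minFactorLen = as.integer(minFactorLen), endClip = as.integer(endClip),
    sourceWindow = as.integer(sourceWindow),
    shiftWindow = as.integer(shiftWindow),
    boundaryTol = as.integer(boundaryTol), exactLimit = as.integer(exactLimit),
    maxEmbeddings = as.integer(maxEmbeddings),
    maxCompositions = as.integer(maxCompositions)
  )
}

setMethod("show", "AlignParams", function(object) {
  cat("AlignParams: ellE=", object@ellE, " ellD=", object@ellD,
      " ellI=", object@ellI, " maxFactorEdit=", object@maxFactorEdit,
      " b=", object@b, "\n", sep = "")
})

# resolve the per-factor edit budget against a factor length
editBudget <- function(len, params) {
  x <- params@maxFactorEdit
  if (x < 1) max(2L, as.integer(ceiling(x * len))) else as.integer(floor(x))
}

#' Embedding graph of a transcript against a genome
#'
#' Directed graph whose vertices are the maximal pairings (of length at least
#' `ellE`) of a transcript P in a genome T and whose edges join pairings that
#' can appear consecutively in a representative embedding.  Directed cycles
#' are permitted (they arise among overlapping pairings of repeats).
#'
#' @slot vertices integer matrix with columns `p`, `t`, `l` (0-based starts on
#'   P and T, length), rows sorted by `(p, t)`.
#' @slot edges two-column integer matrix of vertex row indices (from, to),
#'   sorted; may have zero rows.
#' @slot pLen,tLen lengths of P and T.
#' @slot params the [AlignParams-class] used to build the graph.
#' @export
setClass("EmbeddingGraph",
  representation(vertices = "matrix", edges = "matrix",
                 pLen = "integer", tLen = "integer", params = "AlignParams")
)

setMethod("show", "EmbeddingGraph", function(object) {
  cat("EmbeddingGraph: ", nrow(object@vertices), " vertices, ",
      nrow(object@edges), " edges (|P|=", object@pLen,
      ", |T|=", object@tLen, ")\n", sep = "")
})

#' Spliced composition of a transcript on a genome
#'
#' A spliced alignment: an ordered list of aligned factors, each pairing a
#' transcript interval with a genomic interval (an exon), consecutive genomic
#' factors being separated by introns.  Transcript intervals are contiguous;
#' genomic intervals strictly increase.
#'
#' @slot transcript transcript identifier.
#' @slot factors data.frame with integer columns `pStart`, `pEnd`, `tStart`,
#'   `tEnd` (0-based half-open) and `edit` (unit-cost edit distance between
#'   the two induced substrings).
#' @slot totalEdit sum of the per-factor edit distances.
#' @export
setClass("Composition",
  representation(transcript = "character", factors = "data.frame",
                 totalEdit = "integer")
)

setValidity("Composition", function(object) {
  f <- object@factors
  need <- c("pStart", "pEnd", "tStart", "tEnd", "edit")
  if (!all(need %in% names(f))) return("factors lacks required columns")
  if (nrow(f) == 0L) return("composition must have at least one factor")
  if (any(f$pEnd <= f$pStart) || any(f$tEnd <= f$tStart))
    return("factor intervals must be non-empty")
  if (nrow(f) > 1L) {
    if (any(f$pStart[-1L] != f$pEnd[-nrow(f)]))
      return("transcript intervals must be contiguous")
    if (any(f$tStart[-1L] <= f$tEnd[-nrow(f)]))
      return("genomic intervals must strictly increase")
  }
  TRUE
})

setMethod("show", "Composition", function(object) {
  cat("Composition of '", object@transcript, "': ", nrow(object@factors),
      " factor(s), total edit ", object@totalEdit, "\n", sep = "")
})

#' Factor universe for the consensus (MFA) stage
#'
#' The ordered set of consensus genomic factors (exons) induced by all
#' retained compositions, together with, for each transcript, the list of
#' factor-index sets of its compositions.
#'
#' @slot factors data.frame with columns `start`, `end` (0-based half-open
#'   representative interval) ordered by left boundary then right.
#' @slot sets named list; one entry per covered transcript holding a list of
#'   integer vectors (the factor sets of its compositions, parallel to
#'   `compositions`).
#' @slot compositions named list of lists of [Composition-class] objects,
#'   parallel to `sets`.
#' @slot uncovered character vector of transcripts excluded because no
#'   composition survived alignment.
#' @export
setClass("FactorUniverse",
  representation(factors = "data.frame", sets = "list",
                 compositions = "list", uncovered = "character")
)

setMethod("show", "FactorUniverse", function(object) {
  cat("FactorUniverse: ", nrow(object@factors), " factors, ",
      length(object@sets), " transcripts",
      if (length(object@uncovered))
        paste0(" (", length(object@uncovered), " uncovered)") else "",
      "\n", sep = "")
})

#' Predicted consensus gene structure
#'
#' Result of the full pipeline: the minimum consensus exon set (the
#' factorization agreement set), one selected composition per transcript, the
#' predicted introns, and a run report.
#'
#' @slot exons [GenomicRanges::GRanges] of consensus exons (selected factors).
#' @slot selected integer indices of the selected factors in the universe.
#' @slot universe the [FactorUniverse-class] the solution was computed on.
#' @slot compositions named list of [Composition-class], one per transcript.
#' @slot introns [GenomicRanges::GRanges] of predicted introns with splice
#'   pattern, U-type and support annotations.
#' @slot report list of per-stage counters, warnings and parameters.
#' @export
setClass("GeneStructure",
  representation(exons = "GRanges", selected = "integer",
                 universe = "FactorUniverse", compositions = "list",
                 introns = "GRanges", report = "list")
)

setMethod("show", "GeneStructure", function(object) {
  cat("GeneStructure: ", length(object@exons), " consensus exons, ",
      length(object@compositions), " transcripts, ",
      length(object@introns), " introns\n", sep = "")
})

#' @describeIn GeneStructure-class consensus exons as a `GRanges`.
#' @param x a `GeneStructure`.
#' @export
consensusExons <- function(x) x@exons

#' @describeIn GeneStructure-class selected composition per transcript.
#' @export
chosenCompositions <- function(x) x@compositions

#' @describeIn GeneStructure-class predicted introns as a `GRanges`.
#' @export
predictedIntrons <- function(x) x@introns

#' @describeIn GeneStructure-class run report (per-stage counters, warnings).
#' @export
runReport <- function(x) x@report

#' Simulated gene locus
#'
#' A synthetic gene locus: a genomic sequence with planted exons, isoforms
#' (exon-index lists) and true introns whose terminal dinucleotides follow
#' configured splice-site classes.
#'
#' @slot genome genomic sequence (character).
#' @slot exons integer matrix with columns `start`, `end` (0-based half-open),
#'   rows sorted and disjoint.
#' @slot isoforms list of integer vectors of exon indices.
#' @slot introns data.frame of distinct true introns: `start`, `end`,
#'   `pattern` plus the isoforms using each.
#' @slot seed integer seed the locus was generated from.
#' @export
setClass("SimulatedGene",
  representation(genome = "character", exons = "matrix", isoforms = "list",
                 introns = "data.frame", seed = "integer")
)

setMethod("show", "SimulatedGene", function(object) {
  cat("SimulatedGene: |T|=", nchar(object@genome), " nt, ",
      nrow(object@exons), " exons, ", length(object@isoforms),
      " isoforms, ", nrow(object@introns), " distinct introns\n", sep = "")
})
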