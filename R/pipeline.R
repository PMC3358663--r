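# End-to-end pipeline: pairings -> embedding graph -> compositions per
# transcript, then MFA consensus and intron refinement across transcripts.

emptyIntronGRanges <- function() {
  gr <- GRanges()
  mcols(gr) <- DataFrame(donor = character(0), acceptor = character(0),
                         pattern = character(0), uType = character(0),
                         intronLength = integer(0), nSupports = integer(0),
                         supports = character(0),
                         refseqSupported = logical(0))
  gr
}

paramsAsList <- function(params) {
  sl <- slotNames(params)
  out <- lapply(sl, function(s) slot(params, s))
  names(out) <- sl
  out
}

#' Run the full gene-structure prediction pipeline
#'
#' For each transcript: enumerate maximal pairings, build the embedding
#' graph and extract spliced compositions.  Across transcripts: build the
#' factor universe, solve the Minimum Factorization Agreement problem
#' (exactly when the universe is small enough, greedily otherwise), select
#' one composition per transcript, extract and classify introns, and run the
#' intron-reduction step.  Per-transcript failures are isolated and
#' reported, never fatal.
#'
#' @param genome genomic sequence (character or `DNAString`).
#' @param transcripts named character vector or `DNAStringSet` of transcript
#'   sequences.
#' @param params an [AlignParams-class].
#' @param refseq RefSeq flags: logical vector parallel to `transcripts`,
#'   character vector of ids, or `NULL` to flag ids matching `NM_`/`NR_`.
#' @param mfa `"auto"` (exact when the factor universe has at most
#'   `exactLimit` factors), `"exact"` or `"greedy"`.
#' @param outDir optional directory; when given, writes `consensus.gtf`,
#'   `compositions.bed`, `introns.gff3`, `introns.json` and `report.json`.
#' @param genomeName sequence name used in all outputs.
#' @param geneId gene id used in the GTF.
#' @return a [GeneStructure-class].
#' @export
runPipeline <- function(genome, transcripts, params = alignParams(),
                        refseq = NULL, mfa = c("auto", "exact", "greedy"),
                        outDir = NULL, genomeName = "genome",
                        geneId = "gene1") {
  mfa <- match.arg(mfa)
  genome <- checkSeq(genome, "T")
  if (is(transcripts, "XStringSet"))
    transcripts <- structure(toupper(as.character(transcripts)),
                             names = names(transcripts))
  if (is.null(names(transcripts)) || anyDuplicated(names(transcripts)))
    stop("transcripts must have unique names")
  ids <- names(transcripts)
  refseqIds <- if (is.null(refseq)) {
    ids[grepl("^(NM_|NR_)", ids)]
  } else if (is.logical(refseq)) {
    ids[rep_len(refseq, length(ids))]
  } else {
    intersect(as.character(refseq), ids)
  }

  report <- list(genomeName = genomeName, genomeLength = nchar(genome),
                 nTranscripts = length(ids), refseqIds = refseqIds,
                 params = paramsAsList(params), warnings = character(0),
                 failures = character(0), perTranscript = list())

  compList <- vector("list", length(ids))
  names(compList) <- ids
  for (id in ids) {
    res <- tryCatch({
      withCallingHandlers({
        g <- buildEmbeddingGraph(P = transcripts[[id]], T = genome,
                                 params = params)
        comps <- enumerateCompositions(g, transcripts[[id]], genome, params,
                                       transcript = id)
        report$perTranscript[[id]] <- list(
          nVertices = nrow(g@vertices), nEdges = nrow(g@edges),
          nCompositions = length(comps)
        )
        comps
      }, warning = function(w) {
        report$warnings <<- c(report$warnings,
                              paste0(id, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    }, error = function(e) {
      report$failures <<- c(report$failures,
                            paste0(id, ": ", conditionMessage(e)))
      list()
    })
    compList[[id]] <- res
  }

  emptyResult <- function(report) {
    new("GeneStructure",
        exons = GRanges(), selected = integer(0),
        universe = new("FactorUniverse",
                       factors = data.frame(start = integer(0),
                                            end = integer(0)),
                       sets = list(), compositions = list(),
                       uncovered = ids),
        compositions = list(), introns = emptyIntronGRanges(),
        report = report)
  }

  if (all(lengths(compList) == 0L)) {
    warning("no transcript produced a spliced composition")
    report$warnings <- c(report$warnings,
                         "no transcript produced a spliced composition")
    res <- emptyResult(report)
    if (!is.null(outDir)) writeOutputs(res, outDir, genomeName, geneId)
    return(res)
  }

  universe <- withCallingHandlers(
    buildFactorUniverse(compList, params@boundaryTol),
    warning = function(w) {
      report$warnings <<- c(report$warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  nF <- nrow(universe@factors)
  useExact <- switch(mfa,
                     exact = TRUE,
                     greedy = FALSE,
                     auto = nF <= params@exactLimit)
  selected <- if (useExact) solveMFAExact(universe, params@exactLimit)
              else solveMFAGreedy(universe)
  chosen <- selectCompositions(universe, selected)
  introns <- extractIntrons(chosen, genome, refseqIds, genomeName)
  nBefore <- length(introns)
  red <- reduceIntrons(introns, params@b, chosen, transcripts, genome,
                       refseqIds, params, genomeName)

  report$mfa <- list(mode = if (useExact) "exact" else "greedy",
                     nFactors = nF, nSelected = length(selected),
                     optimal = isTRUE(attr(selected, "optimal")),
                     uncovered = universe@uncovered)
  report$introns <- list(before = nBefore, after = length(red$introns))

  # the reduction step re-aligns junction calls onto supported introns, so
  # the final exon set is re-unified over the reduced compositions (with one
  # composition per transcript the agreement set is simply the union)
  finalUni <- buildFactorUniverse(lapply(red$compositions, list),
                                  params@boundaryTol)
  finalSel <- sort(unique(unlist(finalUni@sets)))
  report$exonsAfterReduction <- length(finalSel)
  exons <- factorsToGRanges(finalUni@factors[finalSel, , drop = FALSE],
                            genomeName)
  res <- new("GeneStructure", exons = exons,
             selected = as.integer(finalSel), universe = finalUni,
             compositions = red$compositions, introns = red$introns,
             report = report)
  if (!is.null(outDir)) writeOutputs(res, outDir, genomeName, geneId)
  res
}

writeOutputs <- function(structure, outDir, genomeName, geneId) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeConsensusGTF(structure@exons, file.path(outDir, "consensus.gtf"),
                    geneId)
  if (length(structure@compositions))
    writeCompositionsBED(structure@compositions,
                         file.path(outDir, "compositions.bed"), genomeName)
  writeIntronsGFF3(structure@introns, file.path(outDir, "introns.gff3"))
  writeIntronsJSON(structure@introns, file.path(outDir, "introns.json"))
  jsonlite::write_json(structure@report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(outDir)
}
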