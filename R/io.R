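# FASTA input, coordinate conversion, and GTF/BED12/GFF3/JSON exporters.

#' Read the genomic sequence and the transcript cluster
#'
#' @param genomePath FASTA file with exactly one record (the gene locus,
#'   assumed on the coding strand).
#' @param transcriptsPath multi-FASTA of EST/mRNA sequences.  Duplicate ids
#'   are suffixed (`_dup2`, ...) with a warning.
#' @param refseqPattern regular expression on the transcript id marking
#'   RefSeq (trusted, full-length) transcripts.
#' @param refseqIds optional explicit RefSeq id vector (united with the
#'   pattern matches).
#' @return list with `genome` (uppercase character), `genomeName`,
#'   `transcripts` (named uppercase character vector) and `refseq` (named
#'   logical vector).
#' @export
readSequences <- function(genomePath, transcriptsPath,
                          refseqPattern = "^(NM_|NR_)",
                          refseqIds = NULL) {
  g <- readDNAStringSet(genomePath)
  if (length(g) != 1L)
    stop("genome FASTA must contain exactly one record (found ",
         length(g), ")")
  tx <- readDNAStringSet(transcriptsPath)
  if (length(tx) == 0L)
    stop("transcript FASTA is empty")
  firstToken <- function(x) sub("\\s.*$", "", x)
  ids <- firstToken(names(tx))
  if (anyDuplicated(ids)) {
    warning("duplicate transcript ids found; suffixing duplicates")
    dup <- ave(seq_along(ids), ids, FUN = seq_along)
    ids[dup > 1L] <- paste0(ids[dup > 1L], "_dup", dup[dup > 1L])
  }
  seqs <- toupper(as.character(tx))
  names(seqs) <- ids
  refseq <- grepl(refseqPattern, ids)
  if (!is.null(refseqIds)) refseq <- refseq | ids %in% refseqIds
  names(refseq) <- ids
  list(genome = toupper(as.character(g[[1L]])),
       genomeName = firstToken(names(g)[1L]),
       transcripts = seqs, refseq = refseq)
}

#' Convert between internal and annotation coordinates
#'
#' Internally every interval is 0-based half-open; GTF/GFF3 use 1-based
#' closed coordinates.  The two functions are exact inverses.
#'
#' @param start,end interval bounds (vectors).
#' @return data.frame with converted `start`, `end`.
#' @examples
#' coordsToGtf(0, 100)    # -> 1, 100
#' coordsFromGtf(1, 100)  # -> 0, 100
#' @export
coordsToGtf <- function(start, end) {
  data.frame(start = as.integer(start) + 1L, end = as.integer(end))
}

#' @rdname coordsToGtf
#' @export
coordsFromGtf <- function(start, end) {
  data.frame(start = as.integer(start) - 1L, end = as.integer(end))
}

factorsToGRanges <- function(factors, genomeName) {
  GRanges(seqnames = genomeName,
          ranges = IRanges(start = factors$start + 1L, end = factors$end))
}

#' Write the consensus exons as GTF
#'
#' @param exons `GRanges` of consensus exons (1-based closed, as stored in a
#'   [GeneStructure-class]).
#' @param path output file.
#' @param geneId gene identifier for the GTF attributes.
#' @return the path, invisibly.
#' @export
writeConsensusGTF <- function(exons, path, geneId = "gene1") {
  gr <- exons
  if (length(gr)) {
    mcols(gr) <- DataFrame(
      source = "spliceAgree", type = "exon",
      gene_id = geneId,
      transcript_id = paste0(geneId, ".consensus"),
      exon_number = seq_along(gr)
    )
  }
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Write per-transcript chosen compositions as BED12
#'
#' Each transcript becomes one BED12 line whose blocks are its genomic
#' factors (exons).
#'
#' @param compositions named list of [Composition-class].
#' @param path output file.
#' @param genomeName chromosome/sequence name.
#' @return the path, invisibly.
#' @export
writeCompositionsBED <- function(compositions, path, genomeName = "genome") {
  grl <- GenomicRanges::GRangesList(lapply(compositions, function(comp) {
    f <- comp@factors
    GRanges(seqnames = genomeName,
            ranges = IRanges(start = f$tStart + 1L, end = f$tEnd))
  }))
  bed <- rtracklayer::asBED(grl)
  rtracklayer::export(bed, path, format = "bed")
  invisible(path)
}

#' Write predicted introns as GFF3 / JSON
#'
#' The GFF3 carries one `intron` feature per record with the splice pattern,
#' U-type, supports and RefSeq flag as attributes; the JSON mirrors the full
#' intron table (both absolute 1-based coordinates and lengths).
#'
#' @param introns `GRanges` from [extractIntrons()] / [reduceIntrons()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeIntronsGFF3 <- function(introns, path) {
  gr <- introns
  if (length(gr)) {
    mcols(gr) <- DataFrame(
      source = "spliceAgree", type = "intron",
      pattern = mcols(introns)$pattern,
      u_type = mcols(introns)$uType,
      donor = mcols(introns)$donor,
      acceptor = mcols(introns)$acceptor,
      supports = mcols(introns)$supports,
      refseq_supported = mcols(introns)$refseqSupported
    )
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname writeIntronsGFF3
#' @export
writeIntronsJSON <- function(introns, path) {
  d <- as.data.frame(introns)
  jsonlite::write_json(d, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
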