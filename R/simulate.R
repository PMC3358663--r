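# Simulator of gene loci, transcript isoforms and error-perturbed EST
# clusters: every pipeline stage is testable without external data.

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  }
  set.seed(seed)
  expr
}

randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

# overwrite genome[at .. at+nchar(what)) (0-based) with `what`
plantAt <- function(genome, at, what) {
  paste0(substr(genome, 1L, at), what,
         substr(genome, at + nchar(what) + 1L, nchar(genome)))
}

#' Generate a synthetic gene locus
#'
#' Builds a uniform-random genomic sequence with `nExons` planted exons
#' separated by intronic gaps, a set of isoforms exercising common
#' alternative-splicing events, and splice-site dinucleotides planted at
#' every true intron boundary.  With four or more exons the default isoform
#' set contains a competing-exon pair (the 3rd and 4th exons never co-occur)
#' and a cassette exon (the 2nd exon, skipped by the last isoform).
#'
#' Intron classes are drawn per splice-site group: `canonicalFraction` of
#' the introns are GT-AG, the remainder GC-AG or AT-AC (4:1); introns that
#' share a donor or an acceptor position receive the same class.
#'
#' @param seed integer seed; the locus is deterministic given the seed.
#' @param nExons number of genomic exons (>= 1).
#' @param exonLenRange,intronLenRange integer ranges (nt) for uniform exon
#'   and inter-exon gap lengths; the intron minimum must be at least `ellI`.
#' @param canonicalFraction fraction of GT-AG introns (default 0.98,
#'   human-like).
#' @param flank flanking genomic sequence on each side (nt).
#' @param isoforms optional list of exon-index vectors overriding the
#'   default isoform set.
#' @param tandemRepeat plant a copy of the end of the first exon at the
#'   start of the following intron, creating overlapping pairings (exercises
#'   the tandem-repeat branch of the visit).
#' @param ellI minimum intron length the gene must respect (nt).
#' @return a [SimulatedGene-class].
#' @examples
#' generateGene(seed = 1, nExons = 3)
#' @export
generateGene <- function(seed, nExons = 6, exonLenRange = c(80, 200),
                         intronLenRange = c(70, 250),
                         canonicalFraction = 0.98, flank = 120,
                         isoforms = NULL, tandemRepeat = FALSE, ellI = 60) {
  nExons <- as.integer(nExons)
  if (nExons < 1L) stop("invalid config: nExons must be >= 1")
  if (min(intronLenRange) < ellI)
    stop("invalid config: intronLenRange minimum must be >= ellI")
  if (min(exonLenRange) < 1L)
    stop("invalid config: exonLenRange minimum must be >= 1")
  if (canonicalFraction < 0 || canonicalFraction > 1)
    stop("invalid config: canonicalFraction must be in [0, 1]")

  rint <- function(lo, hi, n) {
    lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
  }
  withSeed(seed, {
    exLen <- rint(exonLenRange[1L], exonLenRange[2L], nExons)
    gapLen <- if (nExons > 1L)
      rint(intronLenRange[1L], intronLenRange[2L], nExons - 1L)
    else integer(0)
    starts <- flank + cumsum(c(0L, head(exLen + c(gapLen, 0L), -1L)))
    exons <- cbind(start = as.integer(starts),
                   end = as.integer(starts + exLen))
    tLen <- flank + sum(exLen) + sum(gapLen) + flank
    genome <- randSeq(tLen)

    if (is.null(isoforms)) {
      isoforms <- if (nExons >= 4L) {
        base <- setdiff(seq_len(nExons), 4L)      # uses the 3rd exon
        swap <- sort(c(setdiff(base, 3L), 4L))    # competing: 4th for 3rd
        skip <- setdiff(base, 2L)                 # cassette: 2nd skipped
        list(base, swap, skip)
      } else if (nExons >= 2L) {
        list(seq_len(nExons), setdiff(seq_len(nExons), 2L))
      } else {
        list(1L)
      }
    }
    isoforms <- lapply(isoforms, function(v) sort(as.integer(v)))

    # distinct true introns over all isoforms
    ii <- do.call(rbind, lapply(seq_along(isoforms), function(k) {
      v <- isoforms[[k]]
      if (length(v) < 2L) return(NULL)
      data.frame(start = exons[v[-length(v)], "end"],
                 end = exons[v[-1L], "start"], iso = k)
    }))
    introns <- data.frame(start = integer(0), end = integer(0),
                          pattern = character(0), isoforms = character(0))
    if (!is.null(ii) && nrow(ii)) {
      key <- paste(ii$start, ii$end)
      u <- ii[!duplicated(key), c("start", "end"), drop = FALSE]
      u <- u[order(u$start, u$end), , drop = FALSE]
      usedBy <- vapply(paste(u$start, u$end), function(k)
        paste(sort(unique(ii$iso[key == k])), collapse = ","), character(1),
        USE.NAMES = FALSE)

      # same class for introns sharing a donor or an acceptor position
      m <- nrow(u)
      parent <- seq_len(m)
      find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
      for (i in seq_len(m)) for (j in seq_len(m)) {
        if (i < j && (u$start[i] == u$start[j] || u$end[i] == u$end[j])) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
      comp <- vapply(seq_len(m), find, integer(1))
      classes <- c("GT-AG", "GC-AG", "AT-AC")
      compCls <- vapply(unique(comp), function(g) {
        if (runif(1) <= canonicalFraction) "GT-AG"
        else sample(c("GC-AG", "AT-AC"), 1L, prob = c(0.8, 0.2))
      }, character(1))
      names(compCls) <- as.character(unique(comp))
      pattern <- compCls[as.character(comp)]

      if (isTRUE(tandemRepeat) && nrow(u)) {
        rep0 <- u$start[1L]
        repLen <- min(23L, exons[1L, "end"] - exons[1L, "start"],
                      u$end[1L] - u$start[1L] - 10L)
        genome <- plantAt(genome, rep0,
                          substr(genome, rep0 - repLen + 1L, rep0))
      }
      for (i in seq_len(m)) {
        dd <- strsplit(pattern[i], "-")[[1L]]
        genome <- plantAt(genome, u$start[i], dd[1L])
        genome <- plantAt(genome, u$end[i] - 2L, dd[2L])
      }
      introns <- data.frame(start = u$start, end = u$end,
                            pattern = unname(pattern), isoforms = usedBy)
    }

    new("SimulatedGene", genome = genome, exons = exons,
        isoforms = isoforms, introns = introns, seed = as.integer(seed))
  })
}

#' @describeIn generateGene the distinct true introns of a simulated gene.
#' @param gene a [SimulatedGene-class].
#' @export
trueIntrons <- function(gene) gene@introns

#' @describeIn generateGene exon intervals used by at least one isoform.
#' @export
expressedExons <- function(gene) {
  used <- sort(unique(unlist(gene@isoforms)))
  gene@exons[used, , drop = FALSE]
}

matureMRNA <- function(gene, isoform) {
  ex <- gene@exons[gene@isoforms[[isoform]], , drop = FALSE]
  paste(substr(rep(gene@genome, nrow(ex)), ex[, "start"] + 1L, ex[, "end"]),
        collapse = "")
}

applyErrors <- function(seq, errorRate) {
  n <- nchar(seq)
  pos <- which(runif(n) < errorRate)
  if (!length(pos))
    return(list(seq = seq, errors = character(0)))
  ops <- sample(c("sub", "ins", "del"), length(pos), replace = TRUE)
  chars <- strsplit(seq, "")[[1L]]
  out <- as.list(chars)
  bases <- c("A", "C", "G", "T")
  for (k in seq_along(pos)) {
    i <- pos[k]
    if (ops[k] == "sub") {
      out[[i]] <- sample(setdiff(bases, chars[i]), 1L)
    } else if (ops[k] == "del") {
      out[[i]] <- ""
    } else {
      out[[i]] <- paste0(sample(bases, 1L), chars[i])
    }
  }
  list(seq = paste(unlist(out), collapse = ""),
       errors = paste0(pos, ":", ops))
}

#' Generate a simulated transcript cluster
#'
#' Emits, per isoform, `refseqPerIsoform` exact full-length mRNAs (RefSeq,
#' ids `NM_...`) and `nPerIsoform` ESTs: contiguous fragments of the mature
#' mRNA (5'/3' truncation lengths geometric with mean `truncationMean`,
#' capped at `truncationCapFrac` of the transcript length per end) perturbed
#' by i.i.d. substitutions, insertions and deletions (one third each) at
#' `errorRate` per base.
#'
#' @param gene a [SimulatedGene-class].
#' @param nPerIsoform ESTs per isoform (scalar or vector, recycled).
#' @param errorRate per-base error probability in `[0, 0.1]`.
#' @param truncationMean mean truncation per EST end (nt).
#' @param truncationCapFrac cap on the truncation of each end, as a fraction
#'   of the transcript length.
#' @param refseqPerIsoform exact full-length transcripts per isoform.
#' @param seed integer seed.
#' @return a `DNAStringSet` with metadata columns `isoform`, `isRefseq`,
#'   `trunc5`, `trunc3` and `errors` (comma-separated `position:op` in
#'   fragment coordinates).
#' @export
generateTranscripts <- function(gene, nPerIsoform = 10, errorRate = 0,
                                truncationMean = 20,
                                truncationCapFrac = 0.2,
                                refseqPerIsoform = 1, seed = 1) {
  if (errorRate < 0 || errorRate > 0.1)
    stop("invalid config: errorRate must be in [0, 0.1]")
  nIso <- length(gene@isoforms)
  nPerIsoform <- rep_len(as.integer(nPerIsoform), nIso)
  withSeed(seed, {
    ids <- character(0); seqs <- character(0)
    iso <- integer(0); isRef <- logical(0)
    t5 <- integer(0); t3 <- integer(0); errs <- character(0)
    nm <- 0L; est <- 0L
    for (k in seq_len(nIso)) {
      mrna <- matureMRNA(gene, k)
      len <- nchar(mrna)
      for (r in seq_len(refseqPerIsoform)) {
        nm <- nm + 1L
        ids <- c(ids, sprintf("NM_%06d", nm))
        seqs <- c(seqs, mrna)
        iso <- c(iso, k); isRef <- c(isRef, TRUE)
        t5 <- c(t5, 0L); t3 <- c(t3, 0L); errs <- c(errs, "")
      }
      cap <- floor(truncationCapFrac * len)
      for (r in seq_len(nPerIsoform[k])) {
        est <- est + 1L
        a <- min(rgeom(1L, 1 / (1 + truncationMean)), cap)
        b <- min(rgeom(1L, 1 / (1 + truncationMean)), cap)
        frag <- substr(mrna, a + 1L, len - b)
        pe <- applyErrors(frag, errorRate)
        ids <- c(ids, sprintf("EST%05d", est))
        seqs <- c(seqs, pe$seq)
        iso <- c(iso, k); isRef <- c(isRef, FALSE)
        t5 <- c(t5, a); t3 <- c(t3, b)
        errs <- c(errs, paste(pe$errors, collapse = ","))
      }
    }
    out <- DNAStringSet(seqs)
    names(out) <- ids
    mcols(out) <- DataFrame(isoform = iso, isRefseq = isRef,
                            trunc5 = t5, trunc3 = t3, errors = errs)
    out
  })
}

#' Write simulator outputs to disk
#'
#' `writeGenomeFASTA()` and `writeTranscriptsFASTA()` write plain FASTA;
#' `writeTruthJSON()` records the planted exons, isoforms and introns so an
#' independent run can be checked against the simulation truth.
#'
#' @param gene a [SimulatedGene-class].
#' @param transcripts a `DNAStringSet` from [generateTranscripts()].
#' @param path output file path.
#' @param name genome record name.
#' @return the path, invisibly.
#' @export
writeGenomeFASTA <- function(gene, path, name = "genome") {
  x <- DNAStringSet(gene@genome)
  names(x) <- name
  writeXStringSet(x, path)
  invisible(path)
}

#' @rdname writeGenomeFASTA
#' @export
writeTranscriptsFASTA <- function(transcripts, path) {
  writeXStringSet(transcripts, path)
  invisible(path)
}

#' @rdname writeGenomeFASTA
#' @export
writeTruthJSON <- function(gene, path) {
  obj <- list(
    seed = gene@seed,
    genomeLength = nchar(gene@genome),
    exons = data.frame(start = gene@exons[, "start"],
                       end = gene@exons[, "end"]),
    isoforms = lapply(gene@isoforms, as.integer),
    introns = gene@introns
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
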