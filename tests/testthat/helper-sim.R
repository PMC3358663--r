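# Small constructed instances used across the composition tests.

smallParams <- function(...) {
  alignParams(ellE = 8, ellD = 6, ellI = 20, maxFactorEdit = 0.08,
              minFactorLen = 5, endClip = 8, sourceWindow = 15,
              maxEmbeddings = 5000, maxCompositions = 200, ...)
}

# transcript = concatenation of nBlocks exact exon blocks; genome = flank +
# blocks separated by GT..AG introns + flank.  Returns the planted truth.
plantedSmall <- function(seed, nBlocks = 2, exonLen = 30, intronLen = 30,
                         flank = 6, noise = 0) {
  set.seed(seed)
  exons <- replicate(nBlocks, randomDNA(exonLen))
  gparts <- list(randomDNA(flank))
  starts <- integer(nBlocks)
  pos <- flank
  for (i in seq_len(nBlocks)) {
    starts[i] <- pos
    gparts <- c(gparts, exons[i])
    pos <- pos + exonLen
    if (i < nBlocks) {
      gparts <- c(gparts, paste0("GT", randomDNA(intronLen - 4L), "AG"))
      pos <- pos + intronLen
    }
  }
  gparts <- c(gparts, randomDNA(flank))
  T <- paste(unlist(gparts), collapse = "")
  P <- paste(exons, collapse = "")
  if (noise > 0) {
    chars <- strsplit(P, "")[[1L]]
    hit <- which(runif(length(chars)) < noise)
    for (i in hit) chars[i] <- sample(setdiff(c("A", "C", "G", "T"),
                                              chars[i]), 1L)
    P <- paste(chars, collapse = "")
  }
  list(P = P, T = T,
       exonStarts = starts, exonLen = exonLen,
       introns = if (nBlocks > 1L)
         cbind(start = starts[-nBlocks] + exonLen,
               end = starts[-1L]) else NULL)
}

# genomic tandem repeat: the end of exon 1 is duplicated at the intron start
tandemSmall <- function(seed, repLen = 12, exonLen = 30, intronLen = 34) {
  x <- plantedSmall(seed, nBlocks = 2, exonLen = exonLen,
                    intronLen = intronLen)
  repSeq <- substr(x$T, x$introns[1L, "start"] - repLen + 1L,
                   x$introns[1L, "start"])
  T2 <- paste0(substr(x$T, 1L, x$introns[1L, "start"]), repSeq,
               substr(x$T, x$introns[1L, "start"] + 1L, nchar(x$T)))
  list(P = x$P, T = T2)
}

# ambiguous junction: a motif shared by the donor exon suffix and the
# acceptor exon prefix, so pairings overlap on the transcript (case c)
sharedJunctionSmall <- function(seed, sharedLen = 6, armLen = 24,
                                intronLen = 30) {
  set.seed(seed)
  shared <- randomDNA(sharedLen)
  e1 <- paste0(randomDNA(armLen), shared)
  e2 <- paste0(shared, randomDNA(armLen))
  T <- paste0(randomDNA(6), e1, "GT", randomDNA(intronLen - 4L), "AG", e2,
              randomDNA(6))
  P <- paste0(e1, substr(e2, sharedLen + 1L, nchar(e2)))
  list(P = P, T = T)
}
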