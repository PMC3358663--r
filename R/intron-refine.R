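# Intron extraction, splice-pattern / U-type classification, and the
# reduction procedure that merges probable false-positive junction calls
# into supported introns.

#' Classify an intron by its terminal dinucleotides
#'
#' The three most frequent splice-site rules are GT-AG and GC-AG (major
#' spliceosome, U2) and AT-AC (minor spliceosome, U12).  Anything else is
#' reported as `other`/`unclassified`.  This is a pattern-based
#' simplification: no position-weight-matrix scoring is attempted.
#'
#' @param donor,acceptor character vectors of the first and last two intron
#'   bases.
#' @return data.frame with columns `pattern` (`GT-AG`, `GC-AG`, `AT-AC`,
#'   `other`) and `uType` (`U2`, `U12`, `unclassified`).
#' @examples
#' classifyIntron(c("GT", "AT", "CT"), c("AG", "AC", "TG"))
#' @export
classifyIntron <- function(donor, acceptor) {
  pattern <- rep("other", length(donor))
  pattern[donor == "GT" & acceptor == "AG"] <- "GT-AG"
  pattern[donor == "GC" & acceptor == "AG"] <- "GC-AG"
  pattern[donor == "AT" & acceptor == "AC"] <- "AT-AC"
  uType <- c("GT-AG" = "U2", "GC-AG" = "U2", "AT-AC" = "U12",
             "other" = "unclassified")[pattern]
  data.frame(pattern = pattern, uType = unname(uType))
}

# internal: explode chosen compositions into one row per (intron, support)
intronPairs <- function(chosen, refseqIds) {
  rows <- lapply(names(chosen), function(tr) {
    f <- chosen[[tr]]@factors
    k <- nrow(f)
    if (k < 2L) return(NULL)
    data.frame(tr = tr, junction = seq_len(k - 1L),
               start = f$tEnd[-k], end = f$tStart[-1L],
               refseq = tr %in% refseqIds)
  })
  do.call(rbind, c(rows, list(NULL)))
}

pairsToGRanges <- function(pairs, T, genomeName) {
  if (is.null(pairs) || nrow(pairs) == 0L) {
    gr <- GRanges()
    return(gr)
  }
  key <- paste(pairs$start, pairs$end)
  uk <- !duplicated(key)
  u <- pairs[uk, c("start", "end"), drop = FALSE]
  o <- order(u$start, u$end)
  u <- u[o, , drop = FALSE]
  ukey <- paste(u$start, u$end)
  donor <- substr(rep(T, nrow(u)), u$start + 1L, u$start + 2L)
  acceptor <- substr(rep(T, nrow(u)), u$end - 1L, u$end)
  cls <- classifyIntron(donor, acceptor)
  supports <- lapply(ukey, function(k) {
    sel <- pairs[key == k, , drop = FALSE]
    paste0(sel$tr, ":", sel$junction)
  })
  refseqSupported <- vapply(ukey, function(k)
    any(pairs$refseq[key == k]), logical(1), USE.NAMES = FALSE)
  gr <- GRanges(
    seqnames = genomeName,
    ranges = IRanges(start = u$start + 1L, end = u$end)  # 1-based closed
  )
  mcols(gr) <- DataFrame(
    donor = donor, acceptor = acceptor,
    pattern = cls$pattern, uType = cls$uType,
    intronLength = u$end - u$start,
    nSupports = lengths(supports),
    supports = vapply(supports, paste, character(1), collapse = ","),
    refseqSupported = refseqSupported
  )
  gr
}

#' Extract predicted introns from the chosen compositions
#'
#' One record per distinct genomic interval between consecutive factors
#' across all chosen compositions; supports are aggregated, donor and
#' acceptor dinucleotides are read from the genome, and each intron is
#' classified by splice pattern and U-type.
#'
#' @param chosen named list of [Composition-class] (one per transcript).
#' @param T genome sequence.
#' @param refseqIds character vector of RefSeq-flagged transcript ids.
#' @param genomeName seqname used in the returned ranges.
#' @return a `GRanges` (1-based closed coordinates) with metadata columns
#'   `donor`, `acceptor`, `pattern`, `uType`, `intronLength`, `nSupports`,
#'   `supports` (comma-separated `transcript:junction` pairs) and
#'   `refseqSupported`.
#' @export
extractIntrons <- function(chosen, T, refseqIds = character(0),
                           genomeName = "genome") {
  T <- checkSeq(T, "T")
  pairs <- intronPairs(chosen, refseqIds)
  pairsToGRanges(pairs, T, genomeName)
}

#' Test b-reducibility of one junction call onto another intron
#'
#' A junction call `(i, s)` — intron `i` supported by transcript `s` — is
#' b-reducible to intron `i'` when the two factors of `s` flanking the
#' junction can be re-aligned with their boundaries moved to the ends of
#' `i'` at a cost of at most `b` additional edit operations.  The transcript
#' split point between the two factors is re-optimised within
#' `shiftWindow` nt of its current position.
#'
#' @param src intron interval `c(start, end)` (0-based half-open) currently
#'   induced by the support.
#' @param support list with `tr` (transcript id) and `junction` (index of the
#'   junction in the composition).
#' @param target candidate intron interval `c(start, end)`.
#' @param b error bound (edit operations).
#' @param compositions named list of [Composition-class].
#' @param P transcript sequence of `support$tr`.
#' @param T genome sequence.
#' @param params an [AlignParams-class] (supplies `ellI` and `shiftWindow`).
#' @return list with `ok` (logical), `junction` (the shifted interval when
#'   `ok`, else `NULL`) and `addedErrors`.
#' @export
bReducible <- function(src, support, target, b, compositions, P, T,
                       params = alignParams()) {
  comp <- compositions[[support$tr]]
  if (is.null(comp))
    stop("contract error: transcript '", support$tr, "' not found")
  f <- comp@factors
  j <- support$junction
  if (j < 1L || j >= nrow(f))
    stop("contract error: junction index out of range")
  if (f$tEnd[j] != src[1L] || f$tStart[j + 1L] != src[2L])
    stop("contract error: support does not induce the source intron")
  if (target[2L] - target[1L] < params@ellI)
    stop("contract error: target interval shorter than ellI")
  shift <- max(abs(target[1L] - src[1L]), abs(target[2L] - src[2L]))
  if (shift > params@shiftWindow)
    return(list(ok = FALSE, junction = NULL, addedErrors = NA_integer_))

  old <- sum(editDistance(
    substr(rep(P, 2L), f$pStart[j:(j + 1L)] + 1L, f$pEnd[j:(j + 1L)]),
    substr(rep(T, 2L), f$tStart[j:(j + 1L)] + 1L, f$tEnd[j:(j + 1L)])
  ))
  cOld <- f$pEnd[j]
  cutLo <- max(f$pStart[j] + 1L, cOld - params@shiftWindow)
  cutHi <- min(f$pEnd[j + 1L] - 1L, cOld + params@shiftWindow)
  if (cutLo > cutHi || target[1L] <= f$tStart[j] ||
      target[2L] >= f$tEnd[j + 1L])
    return(list(ok = FALSE, junction = NULL, addedErrors = NA_integer_))
  cuts <- cutLo:cutHi
  newCost <- vapply(cuts, function(cc) {
    sum(editDistance(
      c(subseq0(P, f$pStart[j], cc), subseq0(P, cc, f$pEnd[j + 1L])),
      c(subseq0(T, f$tStart[j], target[1L]),
        subseq0(T, target[2L], f$tEnd[j + 1L]))
    ))
  }, integer(1))
  added <- min(newCost) - old
  if (added <= b) {
    list(ok = TRUE, junction = as.integer(target),
         addedErrors = as.integer(added),
         pCut = cuts[which.min(newCost)])
  } else {
    list(ok = FALSE, junction = NULL, addedErrors = as.integer(added))
  }
}

#' Reduce probable false-positive introns onto supported ones
#'
#' Junction calls are partitioned into pairs `(intron, support)`: `R` (the
#' support is a RefSeq transcript), and, among the rest, `C1` (GT-AG), `C2`
#' (GC-AG), `C3` (AT-AC) and `N` (any other pattern).  Only `N` pairs are
#' candidates for reduction: each is re-assigned to the first reducible
#' target scanning `R`, then `C1`, `C2`, `C3` (within a set, the nearest
#' interval, ties to the leftmost).  Unreducible calls keep their intron;
#' intron records left without supports are dropped; RefSeq-supported and
#' U12/U2-pattern introns are never modified.
#'
#' @param introns `GRanges` from [extractIntrons()].
#' @param b error bound (edit operations).
#' @param compositions named list of [Composition-class] (the chosen
#'   composition of every supporting transcript).
#' @param sequences named character vector of transcript sequences.
#' @param T genome sequence.
#' @param refseqIds RefSeq-flagged transcript ids.
#' @param params an [AlignParams-class].
#' @param genomeName seqname for the returned ranges.
#' @return list with `introns` (rebuilt `GRanges`) and `compositions` (with
#'   re-aligned junction boundaries where calls were reduced).
#' @export
reduceIntrons <- function(introns, b, compositions, sequences, T,
                          refseqIds = character(0), params = alignParams(),
                          genomeName = "genome") {
  T <- checkSeq(T, "T")
  pairs <- intronPairs(compositions, refseqIds)
  if (is.null(pairs) || nrow(pairs) == 0L)
    return(list(introns = introns, compositions = compositions))
  donor <- substr(rep(T, nrow(pairs)), pairs$start + 1L, pairs$start + 2L)
  acceptor <- substr(rep(T, nrow(pairs)), pairs$end - 1L, pairs$end)
  cls <- classifyIntron(donor, acceptor)
  pairClass <- ifelse(pairs$refseq, "R",
                      c("GT-AG" = "C1", "GC-AG" = "C2", "AT-AC" = "C3",
                        "other" = "N")[cls$pattern])

  targetsOf <- function(klass) {
    sel <- pairs[pairClass == klass, c("start", "end"), drop = FALSE]
    unique(sel)
  }

  nIdx <- which(pairClass == "N")
  nIdx <- nIdx[order(pairs$tr[nIdx], pairs$junction[nIdx])]
  for (i in nIdx) {
    src <- c(pairs$start[i], pairs$end[i])
    done <- FALSE
    for (klass in c("R", "C1", "C2", "C3")) {
      tg <- targetsOf(klass)
      if (!nrow(tg)) next
      dist <- abs(tg$start - src[1L]) + abs(tg$end - src[2L])
      keep <- dist > 0L & pmax(abs(tg$start - src[1L]),
                               abs(tg$end - src[2L])) <= params@shiftWindow
      tg <- tg[keep, , drop = FALSE]
      if (!nrow(tg)) next
      tg <- tg[order(dist[keep], tg$start), , drop = FALSE]
      for (k in seq_len(nrow(tg))) {
        tr <- pairs$tr[i]
        res <- bReducible(src, list(tr = tr, junction = pairs$junction[i]),
                          c(tg$start[k], tg$end[k]), b, compositions,
                          sequences[[tr]], T, params)
        if (res$ok) {
          # move the junction: update the pair and the composition boundaries
          pairs$start[i] <- tg$start[k]
          pairs$end[i] <- tg$end[k]
          f <- compositions[[tr]]@factors
          jj <- pairs$junction[i]
          f$tEnd[jj] <- tg$start[k]
          f$tStart[jj + 1L] <- tg$end[k]
          f$pEnd[jj] <- res$pCut
          f$pStart[jj + 1L] <- res$pCut
          f$edit[jj] <- editDistance(subseq0(sequences[[tr]], f$pStart[jj],
                                             f$pEnd[jj]),
                                     subseq0(T, f$tStart[jj], f$tEnd[jj]))
          f$edit[jj + 1L] <- editDistance(
            subseq0(sequences[[tr]], f$pStart[jj + 1L], f$pEnd[jj + 1L]),
            subseq0(T, f$tStart[jj + 1L], f$tEnd[jj + 1L]))
          comp <- compositions[[tr]]
          comp@factors <- f
          comp@totalEdit <- as.integer(sum(f$edit))
          compositions[[tr]] <- comp
          done <- TRUE
          break
        }
      }
      if (done) break
    }
  }
  list(introns = pairsToGRanges(pairs, T, genomeName),
       compositions = compositions)
}
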