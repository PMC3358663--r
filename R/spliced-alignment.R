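# Enumeration of biologically meaningful spliced compositions by a visit of
# the embedding graph, extending embeddings according to the relative
# position (overlap pattern) of consecutive maximal pairings.

# 0-based half-open substring
subseq0 <- function(s, from, to) {
  if (to <= from) return("")
  substr(s, from + 1L, to)
}

#' Unit-cost edit distance
#'
#' Standard Levenshtein distance (substitution, insertion and deletion each
#' cost 1), computed elementwise with recycling when both arguments are
#' vectors.
#'
#' @param a,b character vectors.
#' @return integer vector of distances.
#' @examples
#' editDistance("ACGT", "AGGT")
#' @export
editDistance <- function(a, b) {
  if (length(a) == 1L) return(as.integer(adist(a, b)))
  if (length(b) == 1L) return(as.integer(adist(b, a)))
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  vapply(seq_len(n), function(i) as.integer(adist(a[i], b[i])), integer(1))
}

# splice-site pattern priority used for ambiguous junction placement:
# GT-AG > GC-AG > AT-AC > other
splicePriority <- function(donor, acceptor) {
  pr <- integer(length(donor))
  pr[donor == "GT" & acceptor == "AG"] <- 3L
  pr[donor == "GC" & acceptor == "AG"] <- 2L
  pr[donor == "AT" & acceptor == "AC"] <- 1L
  pr
}

#' Split a genomic gap into exon flanks and an intron
#'
#' Given the transcript-side gap `gapP` and the (much longer) genome-side gap
#' `gapT` between two consecutive pairings, finds the prefix and suffix of
#' `gapT` whose concatenation has minimum edit distance to `gapP`; the
#' remaining middle of `gapT` is the intron.  The excised interval must be at
#' least `ellI` long.  Ties on edit distance are broken by splice-site
#' pattern priority (GT-AG > GC-AG > AT-AC > other) on the excised interval,
#' then by the leftmost donor.
#'
#' @param gapP transcript gap substring (possibly empty).
#' @param gapT genomic gap substring with `nchar(gapT) - nchar(gapP) >= ellI`.
#' @param ellI minimum intron length (nt).
#' @return list with `prefixLen`, `suffixLen`, `edit`, `donor`, `acceptor`
#'   (first/last two bases of the excised interval) and `pCut` (the split
#'   point of `gapP` between the two flanks).
#' @examples
#' refineIntronSplit("ACGT", paste0("ACGT", "GTCCCCAG"), ellI = 8)
#' @export
refineIntronSplit <- function(gapP, gapT, ellI = 60L) {
  nP <- nchar(gapP); nT <- nchar(gapT)
  if (nT - nP < ellI)
    stop("contract error: gapT must exceed gapP by at least ellI")
  # any split longer than |gapP| + bestEdit cannot win; bestEdit <= |gapP|
  # (the empty split), so prefix+suffix <= 2*|gapP| suffices for optimality
  maxLen <- min(nT - ellI, 2L * nP)
  cand <- expand.grid(i = 0:maxLen, j = 0:maxLen)
  cand <- cand[cand$i + cand$j <= maxLen, , drop = FALSE]
  concat <- paste0(substr(rep(gapT, nrow(cand)), 1L, cand$i),
                   substr(rep(gapT, nrow(cand)), nT - cand$j + 1L, nT))
  ed <- editDistance(gapP, concat)
  donor <- substr(rep(gapT, nrow(cand)), cand$i + 1L, cand$i + 2L)
  acceptor <- substr(rep(gapT, nrow(cand)), nT - cand$j - 1L, nT - cand$j)
  pr <- splicePriority(donor, acceptor)
  best <- order(ed, -pr, cand$i)[1L]
  i <- cand$i[best]; j <- cand$j[best]
  # split gapP between the two flanks at minimum cost, leftmost tie-break
  pCut <- 0L
  if (nP > 0L) {
    cuts <- 0:nP
    left <- editDistance(substr(rep(gapP, nP + 1L), 1L, cuts),
                         substr(gapT, 1L, i))
    right <- editDistance(substr(rep(gapP, nP + 1L), cuts + 1L, nP),
                          substr(gapT, nT - j + 1L, nT))
    pCut <- cuts[which.min(left + right)]
  }
  list(prefixLen = as.integer(i), suffixLen = as.integer(j),
       edit = ed[best], donor = donor[best], acceptor = acceptor[best],
       pCut = as.integer(pCut))
}

# ---------------------------------------------------------------------------
# Embedding extension.  A partial composition state holds:
#   factors : integer matrix, columns pS, pE, tS, tE (0-based half-open);
#             the last row is the open factor and ends where `ek` ends
#   ek      : effective last pairing (p, t, l)

newState <- function(v) {
  list(factors = matrix(as.integer(c(v[1L], v[1L] + v[3L],
                                     v[2L], v[2L] + v[3L])), 1L, 4L,
                        dimnames = list(NULL, c("pS", "pE", "tS", "tE"))),
       ek = as.integer(v[1:3]))
}

mergeState <- function(state, vn) {
  f <- state$factors
  n <- nrow(f)
  pe <- vn[1L] + vn[3L]; te <- vn[2L] + vn[3L]
  if (pe > f[n, "pE"] && te > f[n, "tE"]) {
    f[n, "pE"] <- pe; f[n, "tE"] <- te
    list(factors = f, ek = vn)
  } else {
    # nested or one-axis-only advance: keep the state, continue the path
    state
  }
}

intronCutStates <- function(state, vn, T, params) {
  # junction placement inside a transcript-side overlap: the overlapping
  # stretch of P matches both the end of the donor exon and the start of the
  # acceptor exon; choose the cut by splice-pattern priority, leftmost donor
  f <- state$factors
  n <- nrow(f)
  ek <- state$ek
  pk <- ek[1L]; tk <- ek[2L]; lk <- ek[3L]
  pn <- vn[1L]; tn <- vn[2L]; ln <- vn[3L]
  cLo <- max(pn, f[n, "pS"] + 1L)
  cHi <- min(pk + lk, pn + ln - 1L)
  if (cLo > cHi) return(list())
  cuts <- cLo:cHi
  d <- tk + (cuts - pk)   # donor exon end / intron start
  a <- tn + (cuts - pn)   # intron end / acceptor exon start
  ok <- d > f[n, "tS"] & a < tn + ln
  if (!any(ok)) return(list())
  cuts <- cuts[ok]; d <- d[ok]; a <- a[ok]
  donor <- substr(rep(T, length(d)), d + 1L, d + 2L)
  acceptor <- substr(rep(T, length(a)), a - 1L, a)
  best <- order(-splicePriority(donor, acceptor), d)[1L]
  cut <- cuts[best]
  f[n, "pE"] <- cut
  f[n, "tE"] <- d[best]
  f <- rbind(f, c(cut, pn + ln, a[best], tn + ln))
  list(list(factors = f, ek = as.integer(c(pn, tn, ln))))
}

#' Extend a partial spliced composition across one embedding-graph edge
#'
#' Core step of the graph visit.  Given the current partial composition (its
#' aligned factors, the last one still open), the effective last pairing and
#' the next vertex, dispatches on the overlap pattern of the two pairings:
#'
#' * overlap with small genomic drift (cases where both pairings belong to
#'   the same exon): the open factor absorbs the next pairing;
#' * overlap with drift of at least `ellI`: the junction is placed inside the
#'   transcript-side overlap by splice-pattern priority; when the pairings
#'   overlap on both sequences (a genomic tandem repeat) the single-exon
#'   interpretation is emitted as a second branch;
#' * disjoint pairings with small drift: merged if the edit distance between
#'   the two gap substrings is within the (gap-scaled) edit budget, else the
#'   edge is discarded;
#' * disjoint pairings with drift of at least `ellI`: [refineIntronSplit()]
#'   places the intron; the edge is discarded if the residual edit distance
#'   exceeds the budget.
#'
#' @param state a partial composition state: list with `factors` (integer
#'   matrix with columns `pS`, `pE`, `tS`, `tE`; last row open) and `ek`
#'   (effective last pairing `(p, t, l)`), as produced by previous calls or
#'   by starting from a single pairing.
#' @param vNext next pairing `(p, t, l)` (an embedding-graph successor).
#' @param P,T the sequences.
#' @param params an [AlignParams-class].
#' @return list of zero (edge discarded), one or two extended states.
#' @export
extendEmbedding <- function(state, vNext, P, T, params = alignParams()) {
  vn <- as.integer(vNext[1:3])
  ek <- state$ek
  pk <- ek[1L]; tk <- ek[2L]; lk <- ek[3L]
  pn <- vn[1L]; tn <- vn[2L]; ln <- vn[3L]
  oP <- (pk + lk) - pn > 0L
  oT <- (tk + lk) - tn > 0L
  drift <- tn - tk - (pn - pk)

  if (oP && oT) {                      # case (a)
    if (abs(drift) <= params@ellD) return(list(mergeState(state, vn)))
    if (drift >= params@ellI) {
      # intron vs genomic tandem repeat: emit both interpretations
      return(c(intronCutStates(state, vn, T, params),
               list(mergeState(state, vn))))
    }
    return(list())
  }
  if (oT) {                            # case (b): overlap on T only
    return(list(mergeState(state, vn)))
  }
  if (oP) {                            # case (c): overlap on P only
    if (abs(drift) <= params@ellD) return(list(mergeState(state, vn)))
    if (drift >= params@ellI) return(intronCutStates(state, vn, T, params))
    return(list())
  }
  # case (d): disjoint on both sequences
  gapP <- subseq0(P, pk + lk, pn)
  gapT <- subseq0(T, tk + lk, tn)
  thr <- editBudget(nchar(gapP), params)
  if (abs(drift) <= params@ellD) {
    if (editDistance(gapP, gapT) > thr) return(list())
    f <- state$factors
    n <- nrow(f)
    f[n, "pE"] <- pn + ln; f[n, "tE"] <- tn + ln
    return(list(list(factors = f, ek = vn)))
  }
  if (drift >= params@ellI) {
    sp <- refineIntronSplit(gapP, gapT, params@ellI)
    if (sp$edit > thr) return(list())
    f <- state$factors
    n <- nrow(f)
    f[n, "pE"] <- pk + lk + sp$pCut
    f[n, "tE"] <- tk + lk + sp$prefixLen
    f <- rbind(f, c(pk + lk + sp$pCut, pn + ln, tn - sp$suffixLen, tn + ln))
    return(list(list(factors = f, ek = vn)))
  }
  list()
}

# finalize a state into a Composition, applying the retention rules;
# returns NULL when the composition is rejected
finalizeState <- function(state, P, T, params, transcript) {
  f <- state$factors
  if (any(f[, "pE"] - f[, "pS"] < params@minFactorLen)) return(NULL)
  if (any(f[, "tE"] <= f[, "tS"])) return(NULL)
  if (f[1L, "pS"] > params@endClip) return(NULL)
  if (nchar(P) - f[nrow(f), "pE"] > params@endClip) return(NULL)
  if (nrow(f) > 1L) {
    gaps <- f[-1L, "tS"] - f[-nrow(f), "tE"]
    if (any(gaps < params@ellI)) return(NULL)
  }
  ed <- editDistance(
    substr(rep(P, nrow(f)), f[, "pS"] + 1L, f[, "pE"]),
    substr(rep(T, nrow(f)), f[, "tS"] + 1L, f[, "tE"])
  )
  if (any(ed > editBudget(f[, "pE"] - f[, "pS"], params))) return(NULL)
  df <- data.frame(pStart = f[, "pS"], pEnd = f[, "pE"],
                   tStart = f[, "tS"], tEnd = f[, "tE"], edit = ed)
  rownames(df) <- NULL
  new("Composition", transcript = transcript, factors = df,
      totalEdit = as.integer(sum(ed)))
}

#' Enumerate the spliced compositions of a transcript
#'
#' Visits the embedding graph from its extended sources along simple paths,
#' extending partial compositions with [extendEmbedding()]; a path that can
#' no longer be extended yields a candidate composition, whose merged factors
#' are then checked against the retention rules (per-factor edit budget,
#' minimum factor length, bounded unaligned transcript ends, minimum intron
#' length).  Compositions with identical genomic factor lists are reported
#' once (the one with the lowest total edit distance).
#'
#' @param g an [EmbeddingGraph-class] built from `P` and `T` with `params`.
#' @param P,T the sequences.
#' @param params an [AlignParams-class] (defaults to the graph's).
#' @param transcript identifier stored in the results.
#' @return list of [Composition-class] objects, sorted by total edit
#'   distance, then number of factors, then leftmost genomic start; empty
#'   list when nothing aligns.
#' @export
enumerateCompositions <- function(g, P, T, params = g@params,
                                  transcript = "P") {
  P <- checkSeq(P, "P"); T <- checkSeq(T, "T")
  V <- g@vertices
  n <- nrow(V)
  if (n == 0L) return(list())
  adj <- vector("list", n)
  if (nrow(g@edges))
    adj <- split(g@edges[, 2L], factor(g@edges[, 1L], levels = seq_len(n)))

  env <- new.env(parent = emptyenv())
  env$results <- list()       # key (genomic factor list) -> Composition
  env$capped <- FALSE

  emit <- function(state) {
    comp <- finalizeState(state, P, T, params, transcript)
    if (is.null(comp)) return(invisible())
    key <- paste(comp@factors$tStart, comp@factors$tEnd,
                 sep = "-", collapse = ";")
    old <- env$results[[key]]
    if (is.null(old) ||
        comp@totalEdit < old@totalEdit ||
        (comp@totalEdit == old@totalEdit &&
         nrow(comp@factors) < nrow(old@factors)))
      env$results[[key]] <- comp
    invisible()
  }

  visit <- function(vi, state, visited, budget) {
    # budget: embeddings still allowed for this source
    if (budget <= 0L) { env$capped <- TRUE; return(0L) }
    used <- 1L
    extended <- FALSE
    for (vj in adj[[vi]]) {
      if (visited[vj]) next
      states <- extendEmbedding(state, V[vj, ], P, T, params)
      for (s in states) {
        extended <- TRUE
        visited2 <- visited
        visited2[vj] <- TRUE
        used <- used + visit(vj, s, visited2, budget - used)
        if (budget - used <= 0L) { env$capped <- TRUE; break }
      }
      if (budget - used <= 0L) break
    }
    if (!extended) emit(state)
    used
  }

  for (src in extendedSources(g)) {
    visited <- logical(n)
    visited[src] <- TRUE
    visit(src, newState(V[src, ]), visited, params@maxEmbeddings)
  }
  if (env$capped)
    warning("embedding visit cap reached for transcript '", transcript,
            "'; composition enumeration may be incomplete")

  res <- unname(env$results)
  if (length(res) == 0L) return(list())
  ord <- order(vapply(res, function(x) x@totalEdit, integer(1)),
               vapply(res, function(x) nrow(x@factors), integer(1)),
               vapply(res, function(x) x@factors$tStart[1L], integer(1)))
  res <- res[ord]
  if (length(res) > params@maxCompositions) {
    warning("composition cap reached for transcript '", transcript,
            "'; keeping the ", params@maxCompositions, " best")
    res <- res[seq_len(params@maxCompositions)]
  }
  res
}
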