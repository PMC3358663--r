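# Consensus gene structure via Minimum Factorization Agreement: choose a
# minimum set of genomic factors (exons) such that every transcript keeps at
# least one composition whose factors all belong to the set.

#' Build the factor universe from per-transcript compositions
#'
#' Collects the genomic factors (exons) induced by all retained compositions
#' and unifies equivalent ones into consensus factors.  Factors are keyed by
#' their splice boundaries: a boundary adjacent to an intron within its
#' composition is *internal* and must match (within `boundaryTol` nt) for two
#' factors to be unified, while a boundary at a transcript end is free —
#' 5'/3'-truncated ESTs therefore share the consensus factor of the full
#' exon, whose representative interval takes the widest observed extent.
#' Factors internal on both sides are unified when both boundaries agree
#' within `boundaryTol`; the representative is the most frequent exact
#' interval, ties going to the leftmost.
#'
#' @param compositions named list: transcript id -> list of
#'   [Composition-class] objects.  Transcripts with an empty list are
#'   recorded as uncovered and excluded, with a warning.
#' @param boundaryTol boundary unification tolerance in nt (default 0).
#' @return a [FactorUniverse-class]; factors are ordered by left boundary,
#'   then right.
#' @export
buildFactorUniverse <- function(compositions, boundaryTol = 0L) {
  boundaryTol <- as.integer(boundaryTol)
  if (is.null(names(compositions)) && length(compositions))
    stop("compositions must be a named list (one entry per transcript)")
  uncovered <- names(compositions)[lengths(compositions) == 0L]
  if (length(uncovered))
    warning("transcript(s) without compositions excluded from consensus: ",
            paste(uncovered, collapse = ", "))
  compositions <- compositions[lengths(compositions) > 0L]
  if (length(compositions) == 0L)
    stop("no transcript has any composition; consensus is infeasible")

  rows <- do.call(rbind, unlist(lapply(names(compositions), function(tr) {
    lapply(seq_along(compositions[[tr]]), function(ci) {
      f <- compositions[[tr]][[ci]]@factors
      k <- nrow(f)
      data.frame(tr = tr, ci = ci, fi = seq_len(k),
                 s = as.integer(f$tStart), e = as.integer(f$tEnd),
                 leftInt = seq_len(k) > 1L, rightInt = seq_len(k) < k)
    })
  }), recursive = FALSE))

  near <- function(a, b) abs(a - b) <= boundaryTol

  # --- core groups: factors internal on both sides -------------------------
  groups <- list()  # each: list(s, e) representative
  addGroup <- function(s, e) {
    groups[[length(groups) + 1L]] <<- list(s = s, e = e)
    length(groups)
  }
  core <- rows[rows$leftInt & rows$rightInt, , drop = FALSE]
  coreKey <- character(0)
  if (nrow(core)) {
    uniq <- unique(core[, c("s", "e")])
    m <- nrow(uniq)
    parent <- seq_len(m)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    if (boundaryTol > 0L && m > 1L) {
      for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
        if (near(uniq$s[i], uniq$s[j]) && near(uniq$e[i], uniq$e[j])) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    comp <- vapply(seq_len(m), find, integer(1))
    counts <- table(paste(core$s, core$e))
    for (g in unique(comp)) {
      members <- uniq[comp == g, , drop = FALSE]
      cnt <- as.integer(counts[paste(members$s, members$e)])
      cnt[is.na(cnt)] <- 0L
      pick <- order(-cnt, members$s, members$e)[1L]
      gid <- addGroup(members$s[pick], members$e[pick])
      coreKey[paste(members$s, members$e)] <- gid
    }
  }

  rowGroup <- integer(nrow(rows))
  isCore <- rows$leftInt & rows$rightInt
  rowGroup[isCore] <- as.integer(coreKey[paste(rows$s, rows$e)[isCore]])

  # transcript-end boundaries carry no splice-site evidence: when attaching
  # a terminal factor to a group, its free end may overhang the group
  # representative by a few chance-matched bases (the run extends into the
  # intron until the first mismatch)
  termTol <- max(8L, boundaryTol)

  nCore <- length(groups)
  matchCore <- function(s, e, leftFree, rightFree) {
    if (nCore == 0L) return(NA_integer_)
    cand <- integer(0)
    for (gi in seq_len(nCore)) {
      gr <- groups[[gi]]
      okL <- if (leftFree) s >= gr$s - termTol else near(s, gr$s)
      okR <- if (rightFree) e <= gr$e + termTol else near(e, gr$e)
      if (okL && okR) cand <- c(cand, gi)
    }
    if (!length(cand)) return(NA_integer_)
    w <- vapply(cand, function(gi) groups[[gi]]$e - groups[[gi]]$s, integer(1))
    s0 <- vapply(cand, function(gi) groups[[gi]]$s, integer(1))
    cand[order(w, s0)][1L]
  }

  # --- terminal factors: one free boundary ---------------------------------
  assignTerminal <- function(idx, keyCol, freeLeft) {
    # idx: row indices sharing the constrained boundary column keyCol
    leftovers <- integer(0)
    for (i in idx) {
      g <- matchCore(rows$s[i], rows$e[i], leftFree = freeLeft,
                     rightFree = !freeLeft)
      if (is.na(g)) leftovers <- c(leftovers, i) else rowGroup[i] <<- g
    }
    if (!length(leftovers)) return(invisible())
    key <- rows[[keyCol]][leftovers]
    for (k in sort(unique(key))) {
      sel <- leftovers[abs(key - k) <= boundaryTol & rowGroup[leftovers] == 0L]
      if (!length(sel)) next
      if (freeLeft) {
        gid <- addGroup(min(rows$s[sel]), k)
      } else {
        gid <- addGroup(k, max(rows$e[sel]))
      }
      rowGroup[sel] <<- gid
    }
    invisible()
  }
  assignTerminal(which(!rows$leftInt & rows$rightInt), "e", freeLeft = TRUE)
  assignTerminal(which(rows$leftInt & !rows$rightInt), "s", freeLeft = FALSE)

  # --- single-factor compositions: both boundaries free --------------------
  freeIdx <- which(!rows$leftInt & !rows$rightInt)
  if (length(freeIdx)) {
    matchAny <- function(s, e) {
      cand <- which(vapply(groups, function(gr)
        s >= gr$s - termTol && e <= gr$e + termTol, logical(1)))
      if (!length(cand)) return(NA_integer_)
      w <- vapply(cand, function(gi) groups[[gi]]$e - groups[[gi]]$s,
                  integer(1))
      s0 <- vapply(cand, function(gi) groups[[gi]]$s, integer(1))
      cand[order(w, s0)][1L]
    }
    leftovers <- integer(0)
    for (i in freeIdx) {
      g <- matchAny(rows$s[i], rows$e[i])
      if (is.na(g)) leftovers <- c(leftovers, i) else rowGroup[i] <- g
    }
    for (i in leftovers) {
      if (rowGroup[i] != 0L) next
      sel <- leftovers[rowGroup[leftovers] == 0L &
                       near(rows$s[leftovers], rows$s[i]) &
                       near(rows$e[leftovers], rows$e[i])]
      gid <- addGroup(min(rows$s[sel]), max(rows$e[sel]))
      rowGroup[sel] <- gid
    }
  }

  stopifnot(all(rowGroup > 0L))

  # order factors by left boundary, then right; remap indices
  reps <- data.frame(
    start = vapply(groups, `[[`, integer(1), "s"),
    end = vapply(groups, `[[`, integer(1), "e")
  )
  ord <- order(reps$start, reps$end)
  remap <- integer(length(groups))
  remap[ord] <- seq_along(groups)
  reps <- reps[ord, , drop = FALSE]
  rownames(reps) <- NULL
  rowGroup <- remap[rowGroup]

  sets <- lapply(names(compositions), function(tr) {
    lapply(seq_along(compositions[[tr]]), function(ci) {
      sel <- rows$tr == tr & rows$ci == ci
      sort(unique(rowGroup[sel]))
    })
  })
  names(sets) <- names(compositions)

  new("FactorUniverse", factors = reps, sets = sets,
      compositions = compositions, uncovered = as.character(uncovered))
}

setMask <- function(v) {
  if (!length(v)) return(0L)
  sum(bitwShiftL(1L, v - 1L))
}

maskToSet <- function(m, nF) which(bitwAnd(bitwShiftR(m, 0:(nF - 1L)), 1L) == 1L)

subsetOfMask <- function(m, chosen) bitwAnd(m, bitwNot(chosen)) == 0L

#' Check that a factor set is a factorization agreement set
#'
#' @param universe a [FactorUniverse-class].
#' @param fPrime integer vector of factor indices.
#' @return `TRUE` iff every covered transcript has at least one composition
#'   whose factor set is a subset of `fPrime`.
#' @export
isAgreementSet <- function(universe, fPrime) {
  chosen <- setMask(fPrime)
  all(vapply(universe@sets, function(ls)
    any(vapply(ls, function(v) subsetOfMask(setMask(v), chosen), logical(1))),
    logical(1)))
}

#' Exact Minimum Factorization Agreement solver
#'
#' Branch-and-bound search for a minimum-cardinality factor subset such that
#' every transcript has a composition whose factor set lies inside it.  The
#' search branches over the candidate factor sets of one unsatisfied
#' transcript at a time and prunes on the cardinality of the best solution
#' found; among minimum solutions, the lexicographically smallest index set
#' is returned.
#'
#' @param universe a [FactorUniverse-class].
#' @param exactLimit refuse instances with more factors than this (the
#'   problem is NP-hard); default 24.
#' @return sorted integer vector of selected factor indices, with attribute
#'   `optimal = TRUE`.
#' @export
solveMFAExact <- function(universe, exactLimit = 24L) {
  nF <- nrow(universe@factors)
  if (nF > exactLimit)
    stop("factor universe too large for exact search (", nF, " > ",
         exactLimit, " factors); use solveMFAGreedy()")
  sets <- universe@sets
  if (!length(sets)) {
    out <- integer(0); attr(out, "optimal") <- TRUE; return(out)
  }
  masks <- lapply(sets, function(ls) vapply(ls, setMask, integer(1)))
  masks <- masks[order(lengths(masks))]   # branch on constrained transcripts
  nT <- length(masks)
  pop <- function(m) sum(bitwAnd(bitwShiftR(m, 0:(nF - 1L)), 1L))

  best <- NULL
  bestCard <- nF + 1L
  lexLess <- function(a, b) {
    # a, b sorted integer vectors of equal length
    d <- which(a != b)
    if (!length(d)) FALSE else a[d[1L]] < b[d[1L]]
  }
  rec <- function(i, chosen, card) {
    while (i <= nT && any(subsetOfMask(masks[[i]], chosen))) i <- i + 1L
    if (i > nT) {
      vec <- if (nF) maskToSet(chosen, nF) else integer(0)
      if (card < bestCard || (card == bestCard && lexLess(vec, best))) {
        best <<- vec; bestCard <<- card
      }
      return(invisible())
    }
    branches <- masks[[i]]
    newMasks <- bitwOr(branches, chosen)
    newCards <- vapply(newMasks, pop, integer(1))
    ord <- order(newCards, newMasks)
    for (k in ord) {
      if (newCards[k] > bestCard) next
      rec(i + 1L, newMasks[k], newCards[k])
    }
    invisible()
  }
  rec(1L, 0L, 0L)
  if (is.null(best)) stop("no agreement set exists")  # cannot happen
  attr(best, "optimal") <- TRUE
  best
}

#' Greedy Minimum Factorization Agreement heuristic
#'
#' Scalable fallback for large factor universes.  Iteratively adds the factor
#' that newly satisfies the most transcripts (a transcript is satisfied when
#' one of its factor sets is fully selected); when no single factor completes
#' a set, it adds the factor that reduces the smallest remaining deficit for
#' the most transcripts.  Ties go to the lowest factor index.  The result is
#' always a valid agreement set but not necessarily minimum; the `optimal`
#' attribute is `TRUE` only when the result matches the trivial lower bound
#' (the largest minimum factor-set size over transcripts).
#'
#' @param universe a [FactorUniverse-class].
#' @return sorted integer vector of factor indices with attribute `optimal`.
#' @export
solveMFAGreedy <- function(universe) {
  sets <- universe@sets
  nF <- nrow(universe@factors)
  if (!length(sets)) {
    out <- integer(0); attr(out, "optimal") <- TRUE; return(out)
  }
  masks <- lapply(sets, function(ls) vapply(ls, setMask, integer(1)))
  chosen <- 0L
  satisfied <- vapply(masks, function(ms) any(subsetOfMask(ms, chosen)),
                      logical(1))
  pop <- function(m) sum(bitwAnd(bitwShiftR(m, 0:max(nF - 1L, 0L)), 1L))
  while (!all(satisfied)) {
    un <- which(!satisfied)
    gain <- integer(nF)
    for (f in seq_len(nF)) {
      if (subsetOfMask(bitwShiftL(1L, f - 1L), chosen)) next
      withF <- bitwOr(chosen, bitwShiftL(1L, f - 1L))
      gain[f] <- sum(vapply(masks[un], function(ms)
        any(subsetOfMask(ms, withF)), logical(1)))
    }
    if (max(gain) > 0L) {
      f <- which.max(gain)
    } else {
      # no single factor completes a set: help the tightest deficits
      score <- integer(nF)
      for (tr in un) {
        rem <- vapply(masks[[tr]], function(m)
          pop(bitwAnd(m, bitwNot(chosen))), integer(1))
        bestSets <- masks[[tr]][rem == min(rem)]
        needed <- Reduce(bitwOr, lapply(bestSets, function(m)
          bitwAnd(m, bitwNot(chosen))), 0L)
        hit <- which(bitwAnd(bitwShiftR(needed, 0:(nF - 1L)), 1L) == 1L)
        score[hit] <- score[hit] + 1L
      }
      f <- which.max(score)
    }
    chosen <- bitwOr(chosen, bitwShiftL(1L, f - 1L))
    satisfied <- vapply(masks, function(ms) any(subsetOfMask(ms, chosen)),
                        logical(1))
  }
  out <- maskToSet(chosen, nF)
  lb <- max(vapply(sets, function(ls) min(lengths(ls)), integer(1)))
  attr(out, "optimal") <- length(out) == lb
  out
}

#' Select one composition per transcript under an agreement set
#'
#' For each transcript, among its compositions whose factor set lies inside
#' `fPrime`, picks the one with the lowest total edit distance; ties are
#' broken by fewer factors, then by leftmost genomic start.
#'
#' @param universe a [FactorUniverse-class].
#' @param fPrime a valid agreement set (integer factor indices).
#' @return named list of [Composition-class], one per covered transcript.
#' @export
selectCompositions <- function(universe, fPrime) {
  chosen <- setMask(fPrime)
  out <- lapply(names(universe@sets), function(tr) {
    ok <- which(vapply(universe@sets[[tr]], function(v)
      subsetOfMask(setMask(v), chosen), logical(1)))
    if (!length(ok))
      stop("contract violation: fPrime is not an agreement set (transcript '",
           tr, "' has no qualifying composition)")
    comps <- universe@compositions[[tr]][ok]
    o <- order(vapply(comps, function(x) as.numeric(x@totalEdit), numeric(1)),
               vapply(comps, function(x) nrow(x@factors), integer(1)),
               vapply(comps, function(x) as.numeric(x@factors$tStart[1L]),
                      numeric(1)))
    comps[[o[1L]]]
  })
  names(out) <- names(universe@sets)
  out
}

#' Export / import an MFA instance as JSON
#'
#' Writes the factor intervals and the per-transcript factor-index sets so a
#' standalone solver can be tested against the same instance.
#'
#' @param universe a [FactorUniverse-class].
#' @param path JSON file path.
#' @return `exportMFAInstance`: the path, invisibly.  `importMFAInstance`: a
#'   [FactorUniverse-class] (without compositions).
#' @export
exportMFAInstance <- function(universe, path) {
  obj <- list(
    factors = universe@factors,
    transcripts = lapply(universe@sets, function(ls) lapply(ls, as.integer))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname exportMFAInstance
#' @export
importMFAInstance <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  factors <- data.frame(
    start = vapply(obj$factors, function(x) as.integer(x$start), integer(1)),
    end = vapply(obj$factors, function(x) as.integer(x$end), integer(1))
  )
  sets <- lapply(obj$transcripts, function(ls)
    lapply(ls, function(v) as.integer(unlist(v))))
  comps <- lapply(sets, function(x) list())
  new("FactorUniverse", factors = factors, sets = sets,
      compositions = comps, uncovered = character(0))
}
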