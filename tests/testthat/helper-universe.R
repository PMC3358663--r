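# Build a FactorUniverse by hand from per-transcript lists of factor-index
# sets; dummy compositions are constructed so that selectCompositions() can
# run (factor intervals are spaced 100 nt apart, 50 nt wide).

makeUniverse <- function(sets, nF = max(unlist(sets)), edits = NULL) {
  factors <- data.frame(start = (seq_len(nF) - 1L) * 100L,
                        end = (seq_len(nF) - 1L) * 100L + 50L)
  comps <- lapply(seq_along(sets), function(ti) {
    lapply(seq_along(sets[[ti]]), function(ci) {
      v <- sort(sets[[ti]][[ci]])
      k <- length(v)
      f <- data.frame(
        pStart = (seq_len(k) - 1L) * 50L,
        pEnd = seq_len(k) * 50L,
        tStart = factors$start[v],
        tEnd = factors$end[v],
        edit = rep(0L, k)
      )
      ed <- if (is.null(edits)) 0L else edits[[ti]][[ci]]
      f$edit[1L] <- ed
      new("Composition", transcript = paste0("s", ti), factors = f,
          totalEdit = as.integer(sum(f$edit)))
    })
  })
  names(comps) <- paste0("s", seq_along(sets))
  names(sets) <- names(comps)
  sets <- lapply(sets, function(ls) lapply(ls, function(v) sort(as.integer(v))))
  new("FactorUniverse", factors = factors, sets = sets,
      compositions = comps, uncovered = character(0))
}

# random MFA instance for the exactness sweeps
randomMFAInstance <- function(seed, maxF = 15L, maxS = 8L, maxC = 4L) {
  set.seed(seed)
  nF <- sample(3:maxF, 1L)
  nS <- sample(1:maxS, 1L)
  sets <- lapply(seq_len(nS), function(i) {
    nC <- sample(1:maxC, 1L)
    unique(lapply(seq_len(nC), function(j)
      sort(sample(nF, sample(1:min(4L, nF), 1L)))))
  })
  makeUniverse(sets, nF)
}
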