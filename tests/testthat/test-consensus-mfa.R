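compKeys <- function(u) {
  vapply(seq_len(nrow(u@factors)), function(i)
    paste(u@factors$start[i], u@factors$end[i]), character(1))
}

makeComp <- function(tr, pInt, tInt, edit = 0L) {
  k <- nrow(tInt)
  new("Composition", transcript = tr,
      factors = data.frame(pStart = pInt[, 1L], pEnd = pInt[, 2L],
                           tStart = tInt[, 1L], tEnd = tInt[, 2L],
                           edit = rep(edit, k)),
      totalEdit = as.integer(edit * k))
}

test_that("factor universe collects and deduplicates genomic factors", {
  c1 <- makeComp("a", rbind(c(0, 100), c(100, 200)),
                 rbind(c(0, 100), c(200, 300)))
  u <- buildFactorUniverse(list(a = list(c1)))
  expect_equal(nrow(u@factors), 2L)
  expect_equal(u@sets$a[[1L]], c(1L, 2L))
  # an identical interval in a second transcript maps to the same factor
  c2 <- makeComp("b", rbind(c(0, 100), c(100, 180)),
                 rbind(c(0, 100), c(200, 280)))
  u2 <- buildFactorUniverse(list(a = list(c1), b = list(c2)))
  expect_equal(u2@sets$a[[1L]][1L], u2@sets$b[[1L]][1L])
})

test_that("boundary tolerance unifies near-identical intervals", {
  # middle factors (internal on both sides) differing by <= 3 nt
  c1 <- makeComp("a", rbind(c(0, 50), c(50, 150), c(150, 200)),
                 rbind(c(0, 50), c(300, 400), c(500, 550)))
  c2 <- makeComp("b", rbind(c(0, 50), c(50, 151), c(151, 200)),
                 rbind(c(0, 50), c(301, 402), c(500, 549)))
  u0 <- buildFactorUniverse(list(a = list(c1), b = list(c2)), boundaryTol = 0)
  u3 <- buildFactorUniverse(list(a = list(c1), b = list(c2)), boundaryTol = 3)
  expect_gt(nrow(u0@factors), nrow(u3@factors))
  # with tolerance, the two middle factors share one index
  expect_equal(u3@sets$a[[1L]][2L], u3@sets$b[[1L]][2L])
})

test_that("truncated terminal factors unify with the full exon", {
  # full-length transcript: exons [100,200) and [300,400)
  full <- makeComp("NM_1", rbind(c(0, 100), c(100, 200)),
                   rbind(c(100, 200), c(300, 400)))
  # EST truncated at the 5' end: first factor starts inside the exon but
  # shares the donor boundary 200
  est <- makeComp("e1", rbind(c(0, 60), c(60, 160)),
                  rbind(c(140, 200), c(300, 400)))
  u <- buildFactorUniverse(list(NM_1 = list(full), e1 = list(est)))
  expect_equal(nrow(u@factors), 2L)
  expect_equal(u@sets$NM_1[[1L]], u@sets$e1[[1L]])
  # representative keeps the widest (full-length) extent
  expect_equal(u@factors$start[1L], 100L)
})

test_that("transcripts without compositions are excluded with a warning", {
  c1 <- makeComp("a", rbind(c(0, 100)), rbind(c(0, 100)))
  expect_warning(u <- buildFactorUniverse(list(a = list(c1), b = list())),
                 "excluded")
  expect_equal(u@uncovered, "b")
  expect_equal(names(u@sets), "a")
  suppressWarnings(
    expect_error(buildFactorUniverse(list(b = list())), "infeasible"))
})

test_that("exact MFA solves hand-checked instances", {
  # single transcript, single composition: forced
  u <- makeUniverse(list(list(c(1, 2))), nF = 2)
  expect_equal(as.integer(solveMFAExact(u)), c(1L, 2L))
  # F(s1) = {{1,2},{3}}, F(s2) = {{3},{1,4}} -> {3}
  u <- makeUniverse(list(list(c(1, 2), 3), list(3, c(1, 4))), nF = 4)
  expect_equal(as.integer(solveMFAExact(u)), 3L)
  expect_equal(exhaustiveMFA(u@sets, 4L), 3L)
  # disjoint singletons: union forced
  u <- makeUniverse(list(list(1), list(2)), nF = 2)
  expect_equal(as.integer(solveMFAExact(u)), c(1L, 2L))
  # over-limit instances are refused
  u <- makeUniverse(list(list(c(1, 30))), nF = 30)
  expect_error(solveMFAExact(u, exactLimit = 24), "exact")
})

test_that("exact solver matches exhaustive search on random instances", {
  for (s in 1:60) {
    u <- randomMFAInstance(600 + s, maxF = 12L, maxS = 6L, maxC = 4L)
    ex <- solveMFAExact(u)
    oracle <- exhaustiveMFA(u@sets, nrow(u@factors))
    expect_equal(length(ex), length(oracle))
    expect_true(isAgreementSet(u, ex))
    # lexicographic tie-break reproduces the oracle's choice exactly
    expect_equal(as.integer(ex), oracle)
    # local minimality: removing any factor breaks the agreement
    for (f in ex)
      expect_false(isAgreementSet(u, setdiff(ex, f)))
  }
})

test_that("greedy solver is valid and never beats the exact one", {
  for (s in 1:60) {
    u <- randomMFAInstance(700 + s, maxF = 12L, maxS = 6L, maxC = 4L)
    gr <- solveMFAGreedy(u)
    ex <- solveMFAExact(u)
    expect_true(isAgreementSet(u, gr))
    expect_gte(length(gr), length(ex))
  }
  # single transcript: greedy returns its smallest factor set
  u <- makeUniverse(list(list(c(1, 2, 3), c(2, 4))), nF = 4)
  expect_equal(as.integer(solveMFAGreedy(u)), c(2L, 4L))
})

test_that("composition selection applies the edit/factors/position rules", {
  u <- makeUniverse(list(list(c(1, 2))), nF = 2)
  sel <- selectCompositions(u, c(1L, 2L))
  expect_equal(names(sel), "s1")
  # two qualifying compositions with edits 3 and 1: the lower edit wins
  u <- makeUniverse(list(list(c(1, 2), c(1, 3))), nF = 3,
                    edits = list(list(3L, 1L)))
  sel <- selectCompositions(u, 1:3)
  expect_equal(sel$s1@totalEdit, 1L)
  # tie on edit and factor count: leftmost genomic start wins
  c1 <- makeComp("s1", rbind(c(0, 50)), rbind(c(200, 250)))
  c2 <- makeComp("s1", rbind(c(0, 50)), rbind(c(100, 150)))
  u2 <- new("FactorUniverse",
            factors = data.frame(start = c(100L, 200L), end = c(150L, 250L)),
            sets = list(s1 = list(2L, 1L)),
            compositions = list(s1 = list(c1, c2)),
            uncovered = character(0))
  sel <- selectCompositions(u2, c(1L, 2L))
  expect_equal(sel$s1@factors$tStart, 100L)
  # an invalid agreement set is a contract violation
  expect_error(selectCompositions(u2, integer(0)), "contract")
})

test_that("MFA instances round-trip through JSON", {
  u <- randomMFAInstance(801)
  path <- tempfile(fileext = ".json")
  exportMFAInstance(u, path)
  u2 <- importMFAInstance(path)
  expect_equal(u2@factors, u@factors)
  expect_equal(u2@sets, u@sets)
  expect_equal(as.integer(solveMFAExact(u2)), as.integer(solveMFAExact(u)))
})
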