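test_that("edit distance is unit-cost Levenshtein", {
  expect_equal(editDistance("", "ACG"), 3L)
  expect_equal(editDistance("ACGT", "ACGT"), 0L)
  expect_equal(editDistance("ACGT", "AGGT"), 1L)
  expect_equal(editDistance(c("A", "AC"), c("AC", "AC")), c(1L, 0L))
})

test_that("intron split minimises edit and prefers canonical sites", {
  r <- refineIntronSplit("", "GTAAAAAG", ellI = 8)
  expect_equal(r[c("prefixLen", "suffixLen", "edit", "donor", "acceptor")],
               list(prefixLen = 0L, suffixLen = 0L, edit = 0L,
                    donor = "GT", acceptor = "AG"))
  r <- refineIntronSplit("ACGT", paste0("ACGT", "GTCCCCAG"), ellI = 8)
  expect_equal(r$prefixLen, 4L)
  expect_equal(r$suffixLen, 0L)
  expect_equal(r$edit, 0L)
  expect_equal(r$donor, "GT")
  expect_equal(r$acceptor, "AG")
  # several zero-edit splits exist; only (2, 2) excises a GT..AG interval
  r <- refineIntronSplit("ACGT", paste0("AC", "GTCCCCCCCCAG", "GT"),
                         ellI = 12)
  expect_equal(r$prefixLen, 2L)
  expect_equal(r$suffixLen, 2L)
  expect_equal(r$edit, 0L)
  expect_equal(r$donor, "GT")
  expect_equal(r$acceptor, "AG")
  expect_error(refineIntronSplit("ACGTACGT", "ACGTACGTA", ellI = 8),
               "contract")
})

test_that("intron split matches exhaustive enumeration on random gaps", {
  set.seed(431)
  for (i in 1:20) {
    gp <- randomDNA(sample(0:8, 1))
    gt <- paste0(randomDNA(sample(0:4, 1)), randomDNA(sample(24:40, 1)),
                 randomDNA(sample(0:4, 1)))
    ellI <- 20L
    if (nchar(gt) - nchar(gp) < ellI) next
    r <- refineIntronSplit(gp, gt, ellI)
    # independent full enumeration
    nT <- nchar(gt)
    best <- NULL
    for (a in 0:(nT - ellI)) for (b in 0:(nT - ellI - a)) {
      con <- paste0(substr(gt, 1, a), substr(gt, nT - b + 1, nT))
      e <- adist(gp, con)[1, 1]
      d <- substr(gt, a + 1, a + 2); ac <- substr(gt, nT - b - 1, nT - b)
      pr <- if (d == "GT" && ac == "AG") 3L else if (d == "GC" && ac == "AG")
        2L else if (d == "AT" && ac == "AC") 1L else 0L
      if (is.null(best) || e < best$e ||
          (e == best$e && (pr > best$pr || (pr == best$pr && a < best$a))))
        best <- list(a = a, b = b, e = e, pr = pr)
    }
    expect_equal(r$edit, best$e)
    expect_equal(r$prefixLen, best$a)
    expect_equal(r$suffixLen, best$b)
  }
})

test_that("embedding extension handles the abutting, intron and discard cases", {
  pr <- smallParams()
  set.seed(432)
  # abutting pairings, zero drift: single extension, one factor, no intron
  S <- randomDNA(60)
  st <- spliceAgree:::newState(c(0L, 0L, 20L))
  out <- extendEmbedding(st, c(20L, 20L, 20L), S, S, pr)
  expect_length(out, 1L)
  expect_equal(nrow(out[[1L]]$factors), 1L)
  expect_equal(unname(out[[1L]]$factors[1L, ]), c(0L, 40L, 0L, 40L))
  # disjoint with intronic drift: one extension carrying the planted intron
  x <- plantedSmall(433, nBlocks = 2, exonLen = 30, intronLen = 30)
  g <- buildEmbeddingGraph(P = x$P, T = x$T, params = pr)
  v <- g@vertices
  expect_gte(nrow(v), 2L)
  first <- which(v[, "p"] == 0L)[1L]
  second <- which(v[, "p"] + v[, "l"] == nchar(x$P))[1L]
  st <- spliceAgree:::newState(v[first, ])
  out <- extendEmbedding(st, v[second, ], x$P, x$T, pr)
  expect_length(out, 1L)
  f <- out[[1L]]$factors
  expect_equal(nrow(f), 2L)
  expect_equal(unname(f[1L, "tE"]), unname(x$introns[1L, "start"]))
  expect_equal(unname(f[2L, "tS"]), unname(x$introns[1L, "end"]))
  # small drift but gap substrings too divergent: edge discarded
  P2 <- paste0(S, "AAAAAA", substr(S, 1, 20))
  T2 <- paste0(S, "CCCCCC", substr(S, 1, 20))
  st <- spliceAgree:::newState(c(0L, 0L, 60L))
  out <- extendEmbedding(st, c(66L, 66L, 20L), P2, T2, pr)
  expect_length(out, 0L)
})

test_that("a verbatim substring yields one single-factor composition", {
  set.seed(434)
  T <- randomDNA(150)
  P <- substr(T, 41, 110)
  pr <- smallParams()
  g <- buildEmbeddingGraph(P = P, T = T, params = pr)
  cc <- enumerateCompositions(g, P, T, pr)
  expect_length(cc, 1L)
  expect_equal(cc[[1L]]@factors$tStart, 40L)
  expect_equal(cc[[1L]]@factors$tEnd, 110L)
  expect_equal(cc[[1L]]@totalEdit, 0L)
})

test_that("planted two-exon transcripts recover the planted junction", {
  for (seed in c(441, 442, 443)) {
    x <- plantedSmall(seed, nBlocks = 2, exonLen = 30, intronLen = 32)
    pr <- smallParams()
    g <- buildEmbeddingGraph(P = x$P, T = x$T, params = pr)
    cc <- enumerateCompositions(g, x$P, x$T, pr)
    keys <- vapply(cc, function(co)
      paste(co@factors$tStart, co@factors$tEnd, sep = "-", collapse = ";"),
      character(1))
    want <- paste(c(x$exonStarts[1], x$introns[1, "end"]),
                  c(x$introns[1, "start"],
                    x$exonStarts[2] + x$exonLen), sep = "-", collapse = ";")
    expect_true(want %in% keys)
  }
})

test_that("every emitted composition satisfies its invariants", {
  set.seed(444)
  pr <- smallParams()
  for (i in 1:10) {
    x <- plantedSmall(500 + i, nBlocks = sample(1:3, 1), exonLen = 28,
                      intronLen = 30, noise = 0.02)
    g <- buildEmbeddingGraph(P = x$P, T = x$T, params = pr)
    cc <- enumerateCompositions(g, x$P, x$T, pr)
    for (co in cc) {
      expect_true(validObject(co))
      f <- co@factors
      if (nrow(f) > 1L)
        expect_true(all(f$tStart[-1L] - f$tEnd[-nrow(f)] >= pr@ellI))
      budget <- vapply(f$pEnd - f$pStart, function(l)
        max(2L, as.integer(ceiling(pr@maxFactorEdit * l))), integer(1))
      expect_true(all(f$edit <= budget))
    }
    # distinctness: genomic factor lists are unique
    keys <- vapply(cc, function(co)
      paste(co@factors$tStart, co@factors$tEnd, collapse = ";"), character(1))
    expect_equal(anyDuplicated(keys), 0L)
  }
})

test_that("composition enumeration equals the naive chain oracle", {
  pr <- smallParams()
  insts <- c(
    lapply(451:458, function(s) plantedSmall(s, nBlocks = sample(1:3, 1),
                                             exonLen = 26, intronLen = 28)),
    lapply(459:461, function(s) plantedSmall(s, nBlocks = 2, exonLen = 30,
                                             intronLen = 30, noise = 0.03)),
    list(tandemSmall(462), sharedJunctionSmall(463)),
    lapply(464:466, function(s) {
      set.seed(s); list(P = randomDNA(50), T = randomDNA(140))
    })
  )
  for (inst in insts) {
    g <- buildEmbeddingGraph(P = inst$P, T = inst$T, params = pr)
    cc <- enumerateCompositions(g, inst$P, inst$T, pr)
    keys <- sort(vapply(cc, function(co)
      paste(co@factors$tStart, co@factors$tEnd, sep = "-", collapse = ";"),
      character(1)))
    expect_equal(keys, oracleCompositions(inst$P, inst$T, pr))
  }
})

test_that("the tandem-repeat branch emits both interpretations", {
  x <- tandemSmall(471, repLen = 12)
  pr <- smallParams()
  g <- buildEmbeddingGraph(P = x$P, T = x$T, params = pr)
  cc <- enumerateCompositions(g, x$P, x$T, pr)
  nf <- vapply(cc, function(co) nrow(co@factors), integer(1))
  # the intron interpretation must be present; the single-factor reading of
  # the repeat is filtered by the edit budget (the repeat is long)
  expect_true(any(nf == 2L))
})

test_that("erroneous transcripts still recover the planted composition", {
  pr <- smallParams()
  hits <- vapply(1:8, function(s) {
    x <- plantedSmall(480 + s, nBlocks = 2, exonLen = 30, intronLen = 30,
                      noise = 0.02)
    g <- buildEmbeddingGraph(P = x$P, T = x$T, params = pr)
    cc <- enumerateCompositions(g, x$P, x$T, pr)
    keys <- vapply(cc, function(co)
      paste(co@factors$tStart, co@factors$tEnd, sep = "-", collapse = ";"),
      character(1))
    want <- paste(c(x$exonStarts[1], x$introns[1, "end"]),
                  c(x$introns[1, "start"],
                    x$exonStarts[2] + x$exonLen), sep = "-", collapse = ";")
    want %in% keys
  }, logical(1))
  expect_gte(mean(hits), 0.75)
})
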