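# A controlled two-exon locus used across the reduction tests: exon A and
# exon B with a canonical GT..AG intron at [100, 200); the genome flanks are
# random but fixed by seed.
refineFixture <- function(seed = 901, shiftCall = 0L) {
  set.seed(seed)
  A <- randomDNA(100)
  B <- paste0("CC", randomDNA(98))   # starts CC: a +2 shift costs edits
  mid <- paste0("GT", randomDNA(96), "AG")
  T <- paste0(A, mid, B, randomDNA(40))
  P <- paste0(A, B)
  comp <- new("Composition", transcript = "est1",
              factors = data.frame(
                pStart = c(0L, 100L + shiftCall),
                pEnd = c(100L + shiftCall, 200L),
                tStart = c(0L, 200L + shiftCall),
                tEnd = c(100L + shiftCall, 300L),
                edit = c(0L, 0L)),
              totalEdit = 0L)
  f <- comp@factors
  comp@factors$edit <- editDistance(
    substr(rep(P, 2), f$pStart + 1L, f$pEnd),
    substr(rep(T, 2), f$tStart + 1L, f$tEnd))
  comp@totalEdit <- as.integer(sum(comp@factors$edit))
  refComp <- new("Composition", transcript = "NM_000001",
                 factors = data.frame(pStart = c(0L, 100L),
                                      pEnd = c(100L, 200L),
                                      tStart = c(0L, 200L),
                                      tEnd = c(100L, 300L),
                                      edit = c(0L, 0L)),
                 totalEdit = 0L)
  list(P = P, T = T, comp = comp, refComp = refComp)
}

test_that("introns are extracted with coordinates, sites and supports", {
  set.seed(902)
  T <- randomDNA(400)
  c1 <- new("Composition", transcript = "a",
            factors = data.frame(pStart = c(0L, 100L), pEnd = c(100L, 200L),
                                 tStart = c(0L, 200L), tEnd = c(100L, 300L),
                                 edit = c(0L, 0L)), totalEdit = 0L)
  c2 <- new("Composition", transcript = "b",
            factors = data.frame(pStart = c(0L, 80L), pEnd = c(80L, 180L),
                                 tStart = c(20L, 200L), tEnd = c(100L, 300L),
                                 edit = c(0L, 0L)), totalEdit = 0L)
  gr <- extractIntrons(list(a = c1, b = c2), T, refseqIds = "a")
  expect_length(gr, 1L)
  expect_equal(GenomicRanges::start(gr), 101L)  # 1-based
  expect_equal(GenomicRanges::end(gr), 200L)
  expect_equal(gr$donor, substr(T, 101, 102))
  expect_equal(gr$acceptor, substr(T, 199, 200))
  expect_equal(gr$nSupports, 2L)
  expect_true(gr$refseqSupported)
  # single-factor compositions induce no introns
  c3 <- new("Composition", transcript = "c",
            factors = data.frame(pStart = 0L, pEnd = 50L, tStart = 0L,
                                 tEnd = 50L, edit = 0L), totalEdit = 0L)
  expect_length(extractIntrons(list(c = c3), T), 0L)
})

test_that("dinucleotide classification follows the U2/U12 rules", {
  cls <- classifyIntron(c("GT", "GC", "AT", "CT", "GT"),
                        c("AG", "AG", "AC", "TG", "AC"))
  expect_equal(cls$pattern, c("GT-AG", "GC-AG", "AT-AC", "other", "other"))
  expect_equal(cls$uType, c("U2", "U2", "U12", "unclassified",
                            "unclassified"))
})

test_that("b-reducibility accepts zero shifts and true junctions", {
  fx <- refineFixture(shiftCall = 0L)
  comps <- list(est1 = fx$comp)
  pr <- alignParams(b = 2)
  # zero shift: no additional errors
  r <- bReducible(c(100L, 200L), list(tr = "est1", junction = 1L),
                  c(100L, 200L), b = 0L, comps, fx$P, fx$T, pr)
  expect_true(r$ok)
  expect_equal(r$addedErrors, 0L)
  expect_equal(r$junction, c(100L, 200L))
})

test_that("a shifted junction call is reducible to the true intron", {
  fx <- refineFixture(shiftCall = 2L)
  comps <- list(est1 = fx$comp)
  pr <- alignParams(b = 2)
  src <- c(102L, 202L)
  r <- bReducible(src, list(tr = "est1", junction = 1L), c(100L, 200L),
                  b = 2L, comps, fx$P, fx$T, pr)
  expect_true(r$ok)
  expect_equal(r$junction, c(100L, 200L))
  # oracle: brute-force re-alignment over all transcript split points
  o <- oracleShiftCost(fx$comp, 1L, c(100L, 200L), fx$P, fx$T)
  expect_equal(r$addedErrors, o$new - o$old)
  # moving away from the truth needs extra errors: rejected at b = 0
  fx0 <- refineFixture(shiftCall = 0L)
  r0 <- bReducible(c(100L, 200L), list(tr = "est1", junction = 1L),
                   c(98L, 198L), b = 0L, list(est1 = fx0$comp),
                   fx0$P, fx0$T, pr)
  expect_false(r0$ok)
  o0 <- oracleShiftCost(fx0$comp, 1L, c(98L, 198L), fx0$P, fx0$T)
  expect_gt(o0$new - o0$old, 0L)
})

test_that("reduction merges spurious calls into supported introns", {
  fx <- refineFixture(shiftCall = 2L)
  comps <- list(NM_000001 = fx$refComp, est1 = fx$comp)
  pr <- alignParams(b = 4)
  introns <- extractIntrons(comps, fx$T, refseqIds = "NM_000001")
  expect_length(introns, 2L)
  seqs <- c(NM_000001 = fx$P, est1 = fx$P)
  red <- reduceIntrons(introns, b = 4L, comps, seqs, fx$T,
                       refseqIds = "NM_000001", params = pr)
  expect_length(red$introns, 1L)
  expect_equal(GenomicRanges::start(red$introns), 101L)
  expect_equal(red$introns$nSupports, 2L)
  # support conservation
  expect_equal(sum(red$introns$nSupports), sum(introns$nSupports))
  # idempotence
  red2 <- reduceIntrons(red$introns, b = 4L, red$compositions, seqs, fx$T,
                        refseqIds = "NM_000001", params = pr)
  expect_equal(as.data.frame(red2$introns), as.data.frame(red$introns))
})

test_that("canonical introns are never reduced", {
  # two GT-AG introns 4 nt apart, neither RefSeq: both in C1, none reduced
  set.seed(903)
  plant <- function(s, at, what) {
    paste0(substr(s, 1, at), what, substr(s, at + nchar(what) + 1, nchar(s)))
  }
  T2 <- randomDNA(340)
  T2 <- plant(T2, 100, "GT"); T2 <- plant(T2, 104, "GT")
  T2 <- plant(T2, 198, "AG"); T2 <- plant(T2, 202, "AG")
  mkComp <- function(tr, s, e) {
    f <- data.frame(pStart = c(0L, s), pEnd = c(s, s + 100L),
                    tStart = c(0L, e), tEnd = c(s, e + 100L),
                    edit = c(0L, 0L))
    new("Composition", transcript = tr, factors = f, totalEdit = 0L)
  }
  comps <- list(x = mkComp("x", 100L, 200L), y = mkComp("y", 104L, 204L))
  seqs <- c(x = paste0(substr(T2, 1, 100), substr(T2, 201, 300)),
            y = paste0(substr(T2, 1, 104), substr(T2, 205, 304)))
  introns <- extractIntrons(comps, T2)
  expect_true(all(introns$pattern == "GT-AG"))
  red <- reduceIntrons(introns, b = 4L, comps, seqs, T2,
                       params = alignParams())
  expect_equal(as.data.frame(red$introns)[, c("start", "end")],
               as.data.frame(introns)[, c("start", "end")])
})

test_that("unreducible calls keep their original intron", {
  fx <- refineFixture(shiftCall = 2L)
  comps <- list(est1 = fx$comp)   # no RefSeq, no canonical target
  introns <- extractIntrons(comps, fx$T)
  seqs <- c(est1 = fx$P)
  red <- reduceIntrons(introns, b = 4L, comps, seqs, fx$T,
                       params = alignParams())
  expect_equal(as.data.frame(red$introns)[, c("start", "end")],
               as.data.frame(introns)[, c("start", "end")])
})
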