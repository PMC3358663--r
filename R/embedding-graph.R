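# Embedding graph: directed graph on maximal pairings whose edges mark pairs
# that can be consecutive in a representative embedding.

#' Edge condition of the embedding graph
#'
#' Two distinct maximal pairings `v1 = (p1, t1, l1)` and `v2 = (p2, t2, l2)`
#' are joined by a directed edge when (i) the transcript-side gap
#' `p2 - (p1 + l1)` is at most `ellD`, and (ii) the genomic drift
#' `t2 - t1 - (p2 - p1)` either has absolute value at most `ellD`
#' (same-exon compatibility) or is at least `ellI` (intron compatibility).
#' An orientation constraint `p1 < p2`, ties broken by `t1 < t2`, keeps edges
#' moving forward along the transcript; self-edges are excluded.
#'
#' @param v1,v2 pairings as numeric vectors `(p, t, l)`.
#' @param params an [AlignParams-class] object.
#' @return logical.
#' @examples
#' edgeCondition(c(0, 0, 5), c(5, 100, 5), alignParams(ellD = 2, ellI = 50))
#' @export
edgeCondition <- function(v1, v2, params = alignParams()) {
  v1 <- as.integer(v1[1:3]); v2 <- as.integer(v2[1:3])
  if (all(v1 == v2)) return(FALSE)
  if (!(v1[1L] < v2[1L] || (v1[1L] == v2[1L] && v1[2L] < v2[2L])))
    return(FALSE)
  gapP <- v2[1L] - (v1[1L] + v1[3L])
  if (gapP > params@ellD) return(FALSE)
  drift <- v2[2L] - v1[2L] - (v2[1L] - v1[1L])
  abs(drift) <= params@ellD || drift >= params@ellI
}

#' Build the embedding graph of a transcript against a genome
#'
#' Vertices are the maximal pairings of length at least `ellE`; edges are all
#' ordered pairs satisfying [edgeCondition()] (an all-pairs test).  Vertex and
#' edge orderings are canonical, so repeated builds are identical.
#'
#' @param vertices data.frame or matrix of maximal pairings with columns
#'   `p`, `t`, `l` (as returned by [findMaximalPairings()]), or `NULL` to
#'   compute them from `P` and `T`.
#' @param params an [AlignParams-class].
#' @param P,T sequences; required when `vertices` is `NULL` and recorded for
#'   downstream visits.
#' @return an [EmbeddingGraph-class].
#' @examples
#' g <- buildEmbeddingGraph(P = "ACGTACGTAA", T = "ACGTACGTAA",
#'                          params = alignParams(ellE = 2, ellI = 3))
#' @export
buildEmbeddingGraph <- function(vertices = NULL, params = alignParams(),
                                P = NULL, T = NULL) {
  if (is.null(P) || is.null(T))
    stop("P and T must be supplied")
  P <- checkSeq(P, "P"); T <- checkSeq(T, "T")
  if (is.null(vertices))
    vertices <- findMaximalPairings(P, T, params@ellE)
  v <- as.matrix(vertices)
  storage.mode(v) <- "integer"
  if (nrow(v)) {
    colnames(v) <- c("p", "t", "l")
    v <- v[order(v[, "p"], v[, "t"]), , drop = FALSE]
    v <- v[!duplicated(v), , drop = FALSE]
  } else {
    v <- matrix(integer(), 0L, 3L, dimnames = list(NULL, c("p", "t", "l")))
  }
  n <- nrow(v)
  edges <- matrix(integer(), 0L, 2L)
  if (n > 1L) {
    i <- rep(seq_len(n), each = n)
    j <- rep(seq_len(n), times = n)
    keep <- i != j
    i <- i[keep]; j <- j[keep]
    p1 <- v[i, "p"]; t1 <- v[i, "t"]; l1 <- v[i, "l"]
    p2 <- v[j, "p"]; t2 <- v[j, "t"]
    ok <- (p1 < p2 | (p1 == p2 & t1 < t2)) &
      (p2 - (p1 + l1) <= params@ellD)
    drift <- t2 - t1 - (p2 - p1)
    ok <- ok & (abs(drift) <= params@ellD | drift >= params@ellI)
    edges <- cbind(i[ok], j[ok])
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  new("EmbeddingGraph", vertices = v, edges = edges,
      pLen = nchar(P), tLen = nchar(T), params = params)
}

#' Extended sources of an embedding graph visit
#'
#' Vertices from which the composition-enumerating visit starts: vertices of
#' in-degree zero, united with vertices whose transcript start lies within
#' `sourceWindow` of the transcript 5' end.  This superset guarantees that
#' the first pairing of every representative embedding is reachable from a
#' returned vertex, including when overlapping pairings form directed cycles.
#'
#' @param g an [EmbeddingGraph-class].
#' @return integer vector of vertex row indices, sorted.
#' @export
extendedSources <- function(g) {
  n <- nrow(g@vertices)
  if (n == 0L) return(integer())
  indeg <- tabulate(g@edges[, 2L], nbins = n)
  sort(which(indeg == 0L | g@vertices[, "p"] <= g@params@sourceWindow))
}

#' Dump an embedding graph for debugging
#'
#' `writeGraphDOT()` writes GraphViz DOT; `writeGraphTSV()` writes a TSV edge
#' list with columns `v1_p, v1_t, v1_l, v2_p, v2_t, v2_l`.
#'
#' @param g an [EmbeddingGraph-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeGraphDOT <- function(g, path) {
  v <- g@vertices
  lab <- sprintf("\"(%d,%d,%d)\"", v[, "p"], v[, "t"], v[, "l"])
  lines <- c("digraph embedding {",
             sprintf("  n%d [label=%s];", seq_len(nrow(v)), lab))
  if (nrow(g@edges))
    lines <- c(lines, sprintf("  n%d -> n%d;", g@edges[, 1L], g@edges[, 2L]))
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeGraphDOT
#' @export
writeGraphTSV <- function(g, path) {
  v <- g@vertices
  e <- g@edges
  d <- data.frame(
    v1_p = v[e[, 1L], "p"], v1_t = v[e[, 1L], "t"], v1_l = v[e[, 1L], "l"],
    v2_p = v[e[, 2L], "p"], v2_t = v[e[, 2L], "t"], v2_l = v[e[, 2L], "l"]
  )
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
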