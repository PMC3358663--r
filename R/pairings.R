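# Maximal pairings: occurrences of common substrings of a transcript P and a
# genome T that cannot be extended by one character on both sequences.

checkSeq <- function(x, what) {
  if (is(x, "XString") || is(x, "XStringSet")) x <- as.character(x)
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("invalid input: ", what, " must be a single character string")
  x <- toupper(x)
  if (nchar(x) == 0L)
    stop("invalid input: ", what, " is empty")
  if (grepl("[^ACGTN]", x))
    stop("invalid input: ", what, " contains non-IUPAC characters ",
         "(only A, C, G, T, N are accepted)")
  x
}

#' Find all maximal pairings of a transcript in a genome
#'
#' A pairing `(p, t, l)` records an occurrence of a common substring of
#' length `l` starting at 0-based positions `p` on the transcript `P` and `t`
#' on the genome `T`.  A pairing is *maximal* when the common factor cannot be
#' extended by one character on both sequences, to the left or to the right.
#' `N` never matches anything (including `N`), so low-quality stretches split
#' matches into separate pairings.
#'
#' @param P transcript sequence (character or `DNAString`), alphabet ACGTN.
#' @param T genome sequence, same alphabet.
#' @param ellE minimum pairing length to report (nt).
#' @return data.frame with integer columns `p`, `t`, `l`, sorted by `(p, t)`,
#'   one row per maximal pairing with `l >= ellE`, no duplicates.
#' @examples
#' findMaximalPairings("ACGTACGT", "ACGT", 2)
#' @export
findMaximalPairings <- function(P, T, ellE = 15L) {
  P <- checkSeq(P, "P"); T <- checkSeq(T, "T")
  ellE <- as.integer(ellE)
  if (is.na(ellE) || ellE < 1L) stop("invalid input: ellE must be >= 1")
  m <- mems_scan(P, T, ellE)
  d <- data.frame(p = m[, "p"], t = m[, "t"], l = m[, "l"])
  d <- d[order(d$p, d$t), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# validate a single pairing against P and T (invariant check)
checkPairing <- function(v, P, T) {
  v <- as.integer(v[1:3])
  if (any(is.na(v))) stop("invalid input: pairing must be (p, t, l)")
  p <- v[1L]; t <- v[2L]; l <- v[3L]
  if (l < 1L || p < 0L || t < 0L || p + l > nchar(P) || t + l > nchar(T))
    stop("invalid input: pairing violates bounds")
  fp <- substr(P, p + 1L, p + l)
  ft <- substr(T, t + 1L, t + l)
  if (fp != ft || grepl("N", fp, fixed = TRUE))
    stop("invalid input: pairing does not induce a common factor")
  c(p = p, t = t, l = l)
}

#' Test whether a pairing is maximal
#'
#' @param v pairing as a numeric vector `(p, t, l)` (0-based).
#' @param P,T the sequences the pairing refers to.
#' @return `TRUE` iff the induced factor cannot be extended one character to
#'   the left on both sequences nor to the right on both sequences.
#' @examples
#' isMaximalPairing(c(0, 0, 4), "ACGT", "ACGT")
#' @export
isMaximalPairing <- function(v, P, T) {
  P <- checkSeq(P, "P"); T <- checkSeq(T, "T")
  v <- checkPairing(v, P, T)
  p <- v["p"]; t <- v["t"]; l <- v["l"]
  chr <- function(s, i) substr(s, i + 1L, i + 1L)  # 0-based char access
  leftMax <- p == 0L || t == 0L || chr(P, p - 1L) != chr(T, t - 1L) ||
    chr(P, p - 1L) == "N"
  rightMax <- p + l == nchar(P) || t + l == nchar(T) ||
    chr(P, p + l) != chr(T, t + l) || chr(P, p + l) == "N"
  leftMax && rightMax
}

pairingsOverlap <- function(a, b) {
  # overlap on P or on T (half-open intervals)
  (a[1L] < b[1L] + b[3L] && b[1L] < a[1L] + a[3L]) ||
    (a[2L] < b[2L] + b[3L] && b[2L] < a[2L] + a[3L])
}

#' Trim two overlapping pairings into non-overlapping prefix/suffix pairings
#'
#' When consecutive pairings of an embedding overlap on the transcript and/or
#' the genome, the first is replaced by the shortest prefix-pairing of itself
#' and the second by the longest suffix-pairing of itself such that the two
#' no longer overlap on either sequence and both are at least `ellE` long.
#' Non-overlapping inputs are returned unchanged.
#'
#' @param e1 first pairing `(p, t, l)` (earlier in the embedding).
#' @param e2 second pairing `(p, t, l)`.
#' @param P,T the sequences.
#' @param ellE minimum retained pairing length.
#' @return list with elements `e1`, `e2` (integer named vectors), or `NULL`
#'   when no valid trim exists.
#' @examples
#' resolveOverlap(c(0, 0, 8), c(4, 4, 8), "ACGTACGTACGT", "ACGTACGTACGT", 3)
#' @export
resolveOverlap <- function(e1, e2, P, T, ellE = 15L) {
  P <- checkSeq(P, "P"); T <- checkSeq(T, "T")
  e1 <- checkPairing(e1, P, T); e2 <- checkPairing(e2, P, T)
  ellE <- as.integer(ellE)
  if (!pairingsOverlap(e1, e2)) return(list(e1 = e1, e2 = e2))
  if (e1[["l"]] < ellE) return(NULL)
  le <- ellE  # shortest admissible prefix of e1
  p2e <- e2[["p"]] + e2[["l"]]; t2e <- e2[["t"]] + e2[["l"]]
  # longest suffix of e2 clearing the trimmed e1 on both sequences
  lv <- min(e2[["l"]], p2e - (e1[["p"]] + le), t2e - (e1[["t"]] + le))
  if (lv < ellE) return(NULL)
  list(
    e1 = c(p = e1[["p"]], t = e1[["t"]], l = le),
    e2 = c(p = p2e - lv, t = t2e - lv, l = lv)
  )
}
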