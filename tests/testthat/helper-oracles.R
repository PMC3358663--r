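# Independent oracles used to cross-check the implementation.  These are
# deliberately naive (enumeration-first) and share no code with the package
# internals.

randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# literal brute force over all (p, t, l): substring equality plus
# one-character non-extendability; quartic, for tiny strings only
quarticMaximalPairings <- function(P, T, ellE) {
  np <- nchar(P); nt <- nchar(T)
  ch <- function(s, i) substr(s, i, i)            # 1-based char
  res <- list()
  for (p in 1:np) for (t in 1:nt) {
    lmax <- min(np - p + 1L, nt - t + 1L)
    if (lmax < ellE) next
    for (l in ellE:lmax) {
      fp <- substr(P, p, p + l - 1L)
      if (fp != substr(T, t, t + l - 1L)) next
      if (grepl("N", fp, fixed = TRUE)) next
      leftOk <- p == 1L || t == 1L || ch(P, p - 1L) != ch(T, t - 1L) ||
        ch(P, p - 1L) == "N"
      rightOk <- p + l - 1L == np || t + l - 1L == nt ||
        ch(P, p + l) != ch(T, t + l) || ch(P, p + l) == "N"
      if (leftOk && rightOk)
        res[[length(res) + 1L]] <- c(p - 1L, t - 1L, l)
    }
  }
  if (!length(res))
    return(data.frame(p = integer(0), t = integer(0), l = integer(0)))
  m <- unique(do.call(rbind, res))
  d <- data.frame(p = m[, 1L], t = m[, 2L], l = m[, 3L])
  d <- d[order(d$p, d$t), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# independent vectorised enumeration: boolean match matrix, row-wise run
# lengths, left-maximality mask; same defining property, different code path
oracleMaximalPairings <- function(P, T, ellE) {
  pv <- strsplit(P, "")[[1L]]
  tv <- strsplit(T, "")[[1L]]
  np <- length(pv); nt <- length(tv)
  res <- list()
  runBelow <- integer(nt + 1L)    # run lengths for row p + 1
  for (p in np:1) {
    match <- pv[p] == tv & pv[p] != "N"
    run <- ifelse(match, 1L + runBelow[2:(nt + 1L)], 0L)
    hit <- which(run >= ellE)
    if (length(hit)) {
      if (p == 1L) {
        leftMax <- rep(TRUE, length(hit))
      } else {
        prevP <- pv[p - 1L]
        leftMax <- hit == 1L | prevP == "N" |
          prevP != c("", tv)[hit]   # tv[hit - 1] with guard for hit == 1
      }
      keep <- hit[leftMax]
      if (length(keep))
        res[[length(res) + 1L]] <- cbind(p - 1L, keep - 1L, run[keep])
    }
    runBelow <- c(run, 0L)
  }
  if (!length(res))
    return(data.frame(p = integer(0), t = integer(0), l = integer(0)))
  m <- do.call(rbind, res)
  d <- data.frame(p = m[, 1L], t = m[, 2L], l = m[, 3L])
  d <- d[order(d$p, d$t), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# direct scalar evaluation of the two printed edge conditions plus the
# forward-orientation rule, over all ordered vertex pairs
oracleEdges <- function(vertices, ellD, ellI) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  out <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    p1 <- v[i, 1L]; t1 <- v[i, 2L]; l1 <- v[i, 3L]
    p2 <- v[j, 1L]; t2 <- v[j, 2L]
    if (!(p1 < p2 || (p1 == p2 && t1 < t2))) next
    if (p2 - (p1 + l1) > ellD) next
    drift <- t2 - t1 - (p2 - p1)
    if (abs(drift) <= ellD || drift >= ellI)
      out[[length(out) + 1L]] <- c(i, j)
  }
  if (!length(out)) return(matrix(integer(), 0L, 2L))
  m <- do.call(rbind, out)
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

# enumeration oracle for resolveOverlap: try every (prefixLen, suffixLen)
oracleResolveOverlap <- function(e1, e2, ellE) {
  p1 <- e1[1L]; t1 <- e1[2L]; l1 <- e1[3L]
  p2 <- e2[1L]; t2 <- e2[2L]; l2 <- e2[3L]
  overl <- function(a1, a2, b1, b2) a1 < b2 && b1 < a2
  if (!(overl(p1, p1 + l1, p2, p2 + l2) || overl(t1, t1 + l1, t2, t2 + l2)))
    return(list(e1 = e1, e2 = e2))
  best <- NULL
  for (le in ellE:l1) for (lv in ellE:l2) {
    q2 <- p2 + l2 - lv; s2 <- t2 + l2 - lv
    if (overl(p1, p1 + le, q2, q2 + lv)) next
    if (overl(t1, t1 + le, s2, s2 + lv)) next
    cand <- list(e1 = c(p1, t1, le), e2 = c(q2, s2, lv))
    if (is.null(best) || le < best$e1[3L] ||
        (le == best$e1[3L] && lv > best$e2[3L]))
      best <- cand
  }
  best
}

# exhaustive 2^nF search for the Minimum Factorization Agreement problem;
# sets: list (per transcript) of lists of integer factor-index vectors
exhaustiveMFA <- function(sets, nF) {
  subsets <- 0:(2^nF - 1L)
  validAll <- rep(TRUE, length(subsets))
  for (trSets in sets) {
    ok <- rep(FALSE, length(subsets))
    for (fs in trSets) {
      m <- sum(bitwShiftL(1L, fs - 1L))
      ok <- ok | bitwAnd(subsets, m) == m
    }
    validAll <- validAll & ok
  }
  valid <- subsets[validAll]
  if (!length(valid)) return(NULL)
  card <- vapply(valid, function(s)
    sum(bitwAnd(bitwShiftR(s, 0:(nF - 1L)), 1L)), integer(1))
  best <- valid[card == min(card)]
  sets2 <- lapply(best, function(s)
    which(bitwAnd(bitwShiftR(s, 0:(nF - 1L)), 1L) == 1L))
  # lexicographically smallest index set among minima
  key <- vapply(sets2, function(v) paste(sprintf("%03d", v), collapse = ","),
                character(1))
  sets2[[order(key)[1L]]]
}

# brute-force b-reducibility: re-align the two flanking factors at the
# target boundaries over every admissible transcript split point
oracleShiftCost <- function(comp, j, target, P, T) {
  f <- comp@factors
  old <- adist(substr(P, f$pStart[j] + 1L, f$pEnd[j]),
               substr(T, f$tStart[j] + 1L, f$tEnd[j]))[1L, 1L] +
    adist(substr(P, f$pStart[j + 1L] + 1L, f$pEnd[j + 1L]),
          substr(T, f$tStart[j + 1L] + 1L, f$tEnd[j + 1L]))[1L, 1L]
  costs <- vapply((f$pStart[j] + 1L):(f$pEnd[j + 1L] - 1L), function(cc) {
    adist(substr(P, f$pStart[j] + 1L, cc),
          substr(T, f$tStart[j] + 1L, target[1L]))[1L, 1L] +
      adist(substr(P, cc + 1L, f$pEnd[j + 1L]),
            substr(T, target[2L] + 1L, f$tEnd[j + 1L]))[1L, 1L]
  }, numeric(1))
  list(old = old, new = min(costs))
}

# ---------------------------------------------------------------------------
# Naive chain-based composition oracle.  Enumerates every simple chain of
# maximal pairings starting at an extended source, converts it step by step
# into factors using full-enumeration versions of the overlap rules, emits at
# dead ends, applies the retention rules, and returns the set of genomic
# factor lists.  Shares no code with the package visit.

oracleCompositions <- function(P, T, params) {
  ellE <- params@ellE; ellD <- params@ellD; ellI <- params@ellI
  verts <- oracleMaximalPairings(P, T, ellE)
  n <- nrow(verts)
  if (n == 0L) return(character(0))
  V <- as.matrix(verts)
  E <- oracleEdges(V, ellD, ellI)
  adjacency <- lapply(seq_len(n), function(i) E[E[, 1L] == i, 2L])
  indeg <- tabulate(E[, 2L], nbins = n)
  sources <- which(indeg == 0L | V[, 1L] <= params@sourceWindow)

  budget <- function(len) {
    x <- params@maxFactorEdit
    if (x < 1) max(2L, as.integer(ceiling(x * len))) else as.integer(floor(x))
  }
  prio <- function(d, a) {
    if (d == "GT" && a == "AG") return(3L)
    if (d == "GC" && a == "AG") return(2L)
    if (d == "AT" && a == "AC") return(1L)
    0L
  }
  lev <- function(a, b) as.integer(adist(a, b)[1L, 1L])

  # one extension step; state = list(factors = list of c(pS,pE,tS,tE), ek)
  step <- function(state, vn) {
    ek <- state$ek
    pk <- ek[1L]; tk <- ek[2L]; lk <- ek[3L]
    pn <- vn[1L]; tn <- vn[2L]; ln <- vn[3L]
    oP <- (pk + lk) > pn
    oT <- (tk + lk) > tn
    drift <- tn - tk - (pn - pk)
    fl <- state$factors
    last <- fl[[length(fl)]]
    merge1 <- function() {
      if (pn + ln > last[2L] && tn + ln > last[4L]) {
        last[2L] <- pn + ln; last[4L] <- tn + ln
        fl[[length(fl)]] <- last
        list(list(factors = fl, ek = vn))
      } else list(state)
    }
    cutStates <- function() {
      cLo <- max(pn, last[1L] + 1L)
      cHi <- min(pk + lk, pn + ln - 1L)
      if (cLo > cHi) return(list())
      cuts <- cLo:cHi
      cand <- list()
      for (cc in cuts) {
        d <- tk + (cc - pk); a <- tn + (cc - pn)
        if (d <= last[3L] || a >= tn + ln) next
        cand[[length(cand) + 1L]] <- list(
          cc = cc, d = d, a = a,
          pr = prio(substr(T, d + 1L, d + 2L), substr(T, a - 1L, a)))
      }
      if (!length(cand)) return(list())
      prs <- vapply(cand, function(x) as.integer(x[["pr"]]), integer(1))
      ds <- vapply(cand, function(x) as.numeric(x[["d"]]), numeric(1))
      b <- cand[[order(-prs, ds)[1L]]]
      last[2L] <- b$cc; last[4L] <- b$d
      fl[[length(fl)]] <- last
      fl[[length(fl) + 1L]] <- c(b$cc, pn + ln, b$a, tn + ln)
      list(list(factors = fl, ek = vn))
    }
    if (oP && oT) {
      if (abs(drift) <= ellD) return(merge1())
      if (drift >= ellI) return(c(cutStates(), merge1()))
      return(list())
    }
    if (oT) return(merge1())
    if (oP) {
      if (abs(drift) <= ellD) return(merge1())
      if (drift >= ellI) return(cutStates())
      return(list())
    }
    gp <- if (pn > pk + lk) substr(P, pk + lk + 1L, pn) else ""
    gt <- if (tn > tk + lk) substr(T, tk + lk + 1L, tn) else ""
    thr <- budget(nchar(gp))
    if (abs(drift) <= ellD) {
      if (lev(gp, gt) > thr) return(list())
      last[2L] <- pn + ln; last[4L] <- tn + ln
      fl[[length(fl)]] <- last
      return(list(list(factors = fl, ek = vn)))
    }
    if (drift >= ellI) {
      nT2 <- nchar(gt)
      best <- NULL
      for (i in 0:(nT2 - ellI)) for (j in 0:(nT2 - ellI - i)) {
        con <- paste0(substr(gt, 1L, i), substr(gt, nT2 - j + 1L, nT2))
        e <- lev(gp, con)
        pr <- prio(substr(gt, i + 1L, i + 2L),
                   substr(gt, nT2 - j - 1L, nT2 - j))
        if (is.null(best) || e < best$e ||
            (e == best$e && (pr > best$pr || (pr == best$pr && i < best$i))))
          best <- list(i = i, j = j, e = e, pr = pr)
      }
      if (best$e > thr) return(list())
      pcuts <- 0:nchar(gp)
      cost <- vapply(pcuts, function(cc)
        lev(substr(gp, 1L, cc), substr(gt, 1L, best$i)) +
          lev(substr(gp, cc + 1L, nchar(gp)),
              substr(gt, nT2 - best$j + 1L, nT2)), integer(1))
      pc <- pcuts[which.min(cost)]
      last[2L] <- pk + lk + pc; last[4L] <- tk + lk + best$i
      fl[[length(fl)]] <- last
      fl[[length(fl) + 1L]] <- c(pk + lk + pc, pn + ln,
                                 tn - best$j, tn + ln)
      return(list(list(factors = fl, ek = vn)))
    }
    list()
  }

  retain <- function(fl) {
    f <- do.call(rbind, fl)
    if (any(f[, 2L] - f[, 1L] < params@minFactorLen)) return(NULL)
    if (any(f[, 4L] <= f[, 3L])) return(NULL)
    if (f[1L, 1L] > params@endClip) return(NULL)
    if (nchar(P) - f[nrow(f), 2L] > params@endClip) return(NULL)
    if (nrow(f) > 1L &&
        any(f[-1L, 3L] - f[-nrow(f), 4L] < ellI)) return(NULL)
    for (r in seq_len(nrow(f))) {
      e <- lev(substr(P, f[r, 1L] + 1L, f[r, 2L]),
               substr(T, f[r, 3L] + 1L, f[r, 4L]))
      if (e > budget(f[r, 2L] - f[r, 1L])) return(NULL)
    }
    paste(f[, 3L], f[, 4L], sep = "-", collapse = ";")
  }

  keys <- character(0)
  walk <- function(vi, state, visited) {
    extended <- FALSE
    for (vj in adjacency[[vi]]) {
      if (visited[vj]) next
      for (s in step(state, V[vj, ])) {
        extended <- TRUE
        vis2 <- visited; vis2[vj] <- TRUE
        walk(vj, s, vis2)
      }
    }
    if (!extended) {
      k <- retain(state$factors)
      if (!is.null(k)) keys <<- c(keys, k)
    }
  }
  for (src in sources) {
    visited <- logical(n)
    visited[src] <- TRUE
    st <- list(factors = list(c(V[src, 1L], V[src, 1L] + V[src, 3L],
                                V[src, 2L], V[src, 2L] + V[src, 3L])),
               ek = V[src, ])
    walk(src, st, visited)
  }
  sort(unique(keys))
}

# all chains of (possibly non-maximal) pairings satisfying the
# representative-embedding constraints; used by the crucial-property test.
# Returns a list of matrices (one chain per element, rows = pairings).
oracleConstraintChains <- function(P, T, ellE, ellD, ellI, maxChains = 2e5) {
  mx <- oracleMaximalPairings(P, T, ellE)
  subs <- list()
  for (r in seq_len(nrow(mx))) {
    p0 <- mx$p[r]; t0 <- mx$t[r]; l0 <- mx$l[r]
    for (a in 0:(l0 - ellE)) for (m in ellE:(l0 - a)) {
      subs[[length(subs) + 1L]] <- c(p0 + a, t0 + a, m)
    }
  }
  if (!length(subs)) return(list())
  S <- unique(do.call(rbind, subs))
  S <- S[order(S[, 1L], S[, 2L], S[, 3L]), , drop = FALSE]
  ns <- nrow(S)
  compat <- function(i, j) {
    # j follows i: non-overlapping, forward, gap/drift constraints
    if (S[j, 1L] < S[i, 1L] + S[i, 3L]) return(FALSE)
    if (S[j, 2L] < S[i, 2L] + S[i, 3L]) return(FALSE)
    if (S[j, 1L] - S[i, 1L] - S[i, 3L] > ellD) return(FALSE)
    drift <- S[j, 2L] - S[i, 2L] - (S[j, 1L] - S[i, 1L])
    abs(drift) <= ellD || drift >= ellI
  }
  chains <- list()
  grow <- function(chain) {
    if (length(chains) >= maxChains)
      stop("chain enumeration blew past the cap; shrink the instance")
    chains[[length(chains) + 1L]] <<- chain
    last <- chain[length(chain)]
    for (j in seq_len(ns)) {
      if (compat(last, j)) grow(c(chain, j))
    }
  }
  for (i in seq_len(ns)) grow(i)
  lapply(chains, function(ch) S[ch, , drop = FALSE])
}

# the unique maximal pairing containing a given pairing
containingMaximal <- function(v, maximals) {
  hit <- which(maximals$p <= v[1L] & maximals$t <= v[2L] &
                 maximals$p + maximals$l >= v[1L] + v[3L] &
                 maximals$t + maximals$l >= v[2L] + v[3L] &
                 (v[1L] - maximals$p) == (v[2L] - maximals$t))
  stopifnot(length(hit) == 1L)
  hit
}
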