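# Independent brute-force oracles. These deliberately re-derive every
# statistic from its definition (pair loops, constant-by-constant
# formulas, recursive enumerations) rather than reusing package internals.

# mean pairwise difference count over all C(n,2) column pairs
bfPi <- function(mat) {
  n <- ncol(mat)
  tot <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      tot <- tot + sum(mat[, i] != mat[, j])
  tot / choose(n, 2)
}

bfThetaW <- function(mat) {
  n <- ncol(mat)
  i <- rowSums(mat)
  sum(i >= 1 & i <= n - 1) / sum(1 / seq_len(n - 1))
}

# Tajima (1989) constants transcribed independently
bfTajimaD <- function(mat) {
  n <- ncol(mat)
  cnt <- rowSums(mat)
  S <- sum(cnt >= 1 & cnt <= n - 1)
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  e1 <- c1 / a1
  e2 <- c2 / (a1 * a1 + a2)
  (bfPi(mat) - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Zeng et al. (2006) normalized H transcribed independently
bfFayWuH <- function(mat) {
  n <- ncol(mat)
  cnt <- rowSums(mat)
  cnt <- cnt[cnt >= 1 & cnt <= n - 1]
  S <- length(cnt)
  if (S == 0) return(NA_real_)
  thetaPi <- sum(2 * cnt * (n - cnt)) / (n * (n - 1))
  thetaL <- sum(cnt) / (n - 1)
  an <- sum(1 / (1:(n - 1)))
  bn <- sum(1 / (1:(n - 1))^2)
  bn1 <- sum(1 / (1:n)^2)
  th <- S / an
  th2 <- S * (S - 1) / (an^2 + bn)
  v <- th * (n - 2) / (6 * (n - 1)) +
    th2 * (18 * n^2 * (3 * n + 2) * bn1 -
             (88 * n^3 + 9 * n^2 - 13 * n + 6)) / (9 * n * (n - 1)^2)
  (thetaPi - thetaL) / sqrt(v)
}

# Hudson FST via explicit pair loops (two groups)
bfHudsonFst <- function(mat, groups) {
  gs <- unique(groups)
  pairDiffs <- function(cols1, cols2) {
    tot <- 0; np <- 0
    for (i in cols1) for (j in cols2) {
      tot <- tot + sum(mat[, i] != mat[, j]); np <- np + 1
    }
    c(tot, np)
  }
  withinMeans <- sapply(gs, function(g) {
    idx <- which(groups == g)
    tot <- 0; np <- 0
    for (i in seq_along(idx)[-length(idx)])
      for (j in (i + 1):length(idx)) {
        tot <- tot + sum(mat[, idx[i]] != mat[, idx[j]]); np <- np + 1
      }
    tot / np
  })
  b <- pairDiffs(which(groups == gs[1]), which(groups == gs[2]))
  1 - mean(withinMeans) / (b[1] / b[2])
}

# Kendall tau-b from explicit concordant/discordant pair enumeration
bfKendallTau <- function(x, y) {
  n <- length(x)
  C <- D <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) C <- C + 1
    else D <- D + 1
  }
  n0 <- choose(n, 2)
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# NG86 oracle: independent recursive implementation with seqinr's genetic
# code (a code path disjoint from the package's Biostrings-based one)
orTranslate <- function(codon)
  seqinr::translate(strsplit(tolower(codon), "")[[1]])

orSynSites <- function(codon) {
  aa <- orTranslate(codon)
  s <- 0
  for (pos in 1:3) for (nt in setdiff(c("A", "C", "G", "T"),
                                      substr(codon, pos, pos))) {
    alt <- codon
    substr(alt, pos, pos) <- nt
    if (orTranslate(alt) == aa) s <- s + 1 / 3
  }
  s
}

orPathCounts <- function(c1, c2, allowStop = FALSE) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(matrix(c(0, 0), 1))
  res <- NULL
  recur <- function(cur, remaining, ns, nn) {
    if (!length(remaining)) {
      res <<- rbind(res, c(nn, ns))
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      stopHit <- orTranslate(nxt) == "*"
      if (stopHit && !allowStop) next
      syn <- !stopHit && orTranslate(cur) != "*" &&
        orTranslate(cur) == orTranslate(nxt)
      recur(nxt, setdiff(remaining, p), ns + syn, nn + !syn)
    }
  }
  recur(c1, pos, 0, 0)
  res
}

orDnDs <- function(seqA, seqB) {
  sp <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  ca <- sp(seqA); cb <- sp(seqB)
  Ss <- (sum(sapply(ca, orSynSites)) + sum(sapply(cb, orSynSites))) / 2
  Ns <- 3 * length(ca) - Ss
  Nd <- Sd <- 0
  for (i in which(ca != cb)) {
    paths <- orPathCounts(ca[i], cb[i])
    if (is.null(paths)) paths <- orPathCounts(ca[i], cb[i], TRUE)
    Nd <- Nd + mean(paths[, 1]); Sd <- Sd + mean(paths[, 2])
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(dN = jc(Nd / Ns), dS = if (Ss > 0) jc(Sd / Ss) else NA_real_,
       Nd = Nd, Sd = Sd, Nsites = Ns, Ssites = Ss)
}

# random 0/1 site matrix with every row polymorphic
randomSiteMatrix <- function(S, n) {
  m <- matrix(0L, S, n)
  for (s in seq_len(S)) {
    i <- sample(1:(n - 1), 1)
    m[s, sample(n, i)] <- 1L
  }
  m
}

# wrap a 0/1 matrix as a two-allele character alignment (+ outgroup = the
# ancestral "A" state)
matToAlignment <- function(mat, name = "toy", outgroup = TRUE) {
  n <- ncol(mat)
  seqs <- matrix("A", n, nrow(mat))
  seqs[t(mat) == 1L] <- "G"
  rownames(seqs) <- sprintf("s%02d", seq_len(n))
  new("LocusAlignment", name = name, seqs = seqs,
      outgroup = if (outgroup) rep("A", nrow(mat)) else character(0))
}

randomCodonSeq <- function(nCodons) {
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   names(which(Biostrings::GENETIC_CODE == "*")))
  paste(sample(sense, nCodons, replace = TRUE), collapse = "")
}

mutateCodonSeq <- function(seq, nMut) {
  v <- strsplit(seq, "")[[1]]
  for (k in seq_len(nMut)) {
    repeat {
      i <- sample(length(v), 1)
      nt <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
      old <- v[i]
      v[i] <- nt
      cod <- paste(v[(3 * ((i - 1) %/% 3) + 1):(3 * ((i - 1) %/% 3) + 3)],
                   collapse = "")
      if (Biostrings::GENETIC_CODE[[cod]] != "*") break
      v[i] <- old
    }
  }
  paste(v, collapse = "")
}
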