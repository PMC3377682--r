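#' @include AllClasses.R io.R
NULL

# Watterson/Tajima constants for sample size n
.tajimaConstants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# Reduce a character alignment to usable biallelic columns.
# Returns a 0/1 matrix (sites x samples; 1 = derived when an outgroup
# orients the site upstream, otherwise an arbitrary but fixed allele),
# plus bookkeeping on dropped columns.
.biallelicMatrix <- function(alignment) {
  s <- alignment@seqs
  nN <- colSums(s == "N") > 0
  rows <- list()
  dropped <- 0L
  for (j in which(!nN)) {
    al <- unique(s[, j])
    if (length(al) == 2)
      rows[[length(rows) + 1L]] <- as.integer(s[, j] == al[2])
    else if (length(al) > 2) dropped <- dropped + 1L
  }
  mat <- if (length(rows)) do.call(rbind, rows)
         else matrix(integer(0), 0, nrow(s))
  list(mat = mat, nMultiallelic = dropped, nMissing = sum(nN),
       ids = rownames(s), L = ncol(s))
}

# SFS-side statistics from a 0/1 site matrix, optionally on a column subset.
# Sites monomorphic within the subset are ignored.
.sfsStats <- function(mat, idx = NULL) {
  if (!is.null(idx)) mat <- mat[, idx, drop = FALSE]
  n <- ncol(mat)
  i <- rowSums(mat)
  i <- i[i >= 1 & i <= n - 1]
  S <- length(i)
  k <- .tajimaConstants(n)
  thetaW <- S / k$a1
  pi <- sum(2 * i * (n - i)) / (n * (n - 1))
  D <- if (S == 0) NA_real_
       else (pi - thetaW) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  list(S = S, thetaW = thetaW, pi = pi, D = D, n = n)
}

# Normalized Fay-Wu H from oriented derived counts (Zeng et al. 2006
# normalization, with thetaW and S(S-1)/(a1^2+a2) plugged in for theta and
# theta^2).
.fayWuStats <- function(mat, idx = NULL) {
  if (!is.null(idx)) mat <- mat[, idx, drop = FALSE]
  n <- ncol(mat)
  i <- rowSums(mat)
  i <- i[i >= 1 & i <= n - 1]
  S <- length(i)
  if (S == 0)
    return(list(S = 0L, thetaPi = 0, thetaL = 0, H = NA_real_,
                Hraw = NA_real_))
  thetaPi <- sum(2 * i * (n - i)) / (n * (n - 1))
  thetaL <- sum(i) / (n - 1)
  an <- sum(1 / seq_len(n - 1))
  bn <- sum(1 / seq_len(n - 1)^2)
  bn1 <- bn + 1 / n^2
  theta <- S / an
  theta2 <- S * (S - 1) / (an^2 + bn)
  v <- (n - 2) / (6 * (n - 1)) * theta +
    (18 * n^2 * (3 * n + 2) * bn1 - (88 * n^3 + 9 * n^2 - 13 * n + 6)) /
      (9 * n * (n - 1)^2) * theta2
  list(S = S, thetaPi = thetaPi, thetaL = thetaL,
       H = (thetaPi - thetaL) / sqrt(v), Hraw = thetaPi - thetaL)
}

# Mean pairwise difference components for Hudson's FST on a state matrix
# (any integer/character coding; differences counted per column pair).
.pairDiffComponents <- function(mat, groups) {
  groups <- as.character(groups)
  gl <- split(seq_len(ncol(mat)), groups)
  ng <- lengths(gl)
  states <- unique(as.vector(mat))
  cnt <- lapply(gl, function(idx) {
    m <- mat[, idx, drop = FALSE]
    matrix(vapply(states, function(a) rowSums(m == a), numeric(nrow(mat))),
           nrow = nrow(mat))
  })
  within <- vapply(seq_along(gl), function(g) {
    if (ng[g] < 2) return(NA_real_)
    cg <- cnt[[g]]
    sum(ng[g]^2 - rowSums(cg^2)) / 2 / choose(ng[g], 2)
  }, 0)
  names(within) <- names(gl)
  if (length(gl) < 2)
    return(list(within = within, Hb = NA_real_,
                HwPooled = unname(within[1])))
  pairs <- utils::combn(seq_along(gl), 2)
  btw_diffs <- 0
  btw_pairs <- 0
  for (p in seq_len(ncol(pairs))) {
    g <- pairs[1, p]; h <- pairs[2, p]
    btw_diffs <- btw_diffs + sum(ng[g] * ng[h] -
                                   rowSums(cnt[[g]] * cnt[[h]]))
    btw_pairs <- btw_pairs + ng[g] * ng[h]
  }
  w_diffs <- sum(vapply(seq_along(gl), function(g)
    sum(ng[g]^2 - rowSums(cnt[[g]]^2)) / 2, 0))
  w_pairs <- sum(choose(ng, 2))
  list(within = within, Hb = unname(btw_diffs / btw_pairs),
       HwPooled = if (w_pairs > 0) unname(w_diffs / w_pairs) else NA_real_)
}

#' Basic per-locus sequence polymorphism statistics
#'
#' Segregating sites S, Watterson's theta (per locus and per site),
#' nucleotide diversity pi (mean pairwise differences, per locus and per
#' site) and the number of distinct haplotypes K (exact string equality on
#' the gap-excluded alignment). Columns with N or more than two alleles are
#' excluded from S, theta and pi.
#'
#' @param alignment a gap-excluded \linkS4class{LocusAlignment}.
#' @return list with S, thetaW, thetaWSite, pi, piSite, K, n, L.
#' @export
seqStats <- function(alignment) {
  stopifnot(is(alignment, "LocusAlignment"))
  n <- nrow(alignment@seqs)
  if (n < 2) stop("need at least 2 sequences")
  b <- .biallelicMatrix(alignment)
  st <- .sfsStats(b$mat)
  K <- length(unique(apply(alignment@seqs, 1, paste, collapse = "")))
  list(S = st$S, thetaW = st$thetaW, thetaWSite = st$thetaW / b$L,
       pi = st$pi, piSite = st$pi / b$L, K = K, n = n, L = b$L)
}

#' Tajima's D
#'
#' \eqn{D = (\pi - \theta_w)/\sqrt{e_1 S + e_2 S(S-1)}} with the Tajima
#' (1989) constants. Returns NA (flagged undefined) when S = 0.
#'
#' @param x a gap-excluded \linkS4class{LocusAlignment}, an
#'   \linkS4class{OrientedAlignment}, or a 0/1 site matrix (sites x
#'   samples).
#' @param idx optional column (sample) subset.
#' @return Tajima's D, or NA when no site segregates.
#' @export
tajimaD <- function(x, idx = NULL) {
  mat <- .asSiteMatrix(x)
  .sfsStats(mat, idx)$D
}

.asSiteMatrix <- function(x) {
  if (is(x, "LocusAlignment")) .biallelicMatrix(x)$mat
  else if (is(x, "OrientedAlignment")) x@mat
  else if (is.matrix(x)) x
  else stop("unsupported input type")
}

#' Normalized Fay and Wu's H
#'
#' \eqn{H = (\theta_\pi - \theta_L)/\sqrt{Var}} with
#' \eqn{\theta_L = \sum_i i\,\xi_i/(n-1)} computed from outgroup-oriented
#' derived-allele counts and the variance of Zeng et al. (2006). Strongly
#' negative values indicate an excess of high-frequency derived alleles.
#'
#' @param x an \linkS4class{OrientedAlignment} (or oriented 0/1 matrix).
#' @param idx optional column (sample) subset; orientation is performed
#'   once on the full alignment and subsets inherit it.
#' @return normalized H, or NA when no orientable site segregates.
#' @export
fayWuHNorm <- function(x, idx = NULL) {
  mat <- if (is(x, "OrientedAlignment")) x@mat
         else if (is.matrix(x)) x
         else stop("H requires oriented input (see orientAlleles)")
  .fayWuStats(mat, idx)$H
}

#' Hudson's FST for sequences
#'
#' \eqn{F_{ST} = 1 - H_w/H_b} with \eqn{H_w} the mean within-group pairwise
#' difference count (averaged over the two groups) and \eqn{H_b} the mean
#' between-group pairwise difference count. Negative values are permitted.
#' With more than two groups all within-group pairs and all between-group
#' pairs are pooled.
#'
#' @param x a gap-excluded \linkS4class{LocusAlignment},
#'   \linkS4class{OrientedAlignment}, or a site matrix.
#' @param grouping group label per sample (in the object's sample order).
#' @return list with value, Hw, Hb and the groups compared; value is NA
#'   (flagged undefined) when Hb = 0.
#' @export
hudsonFst <- function(x, grouping) {
  mat <- .asSiteMatrix(x)
  grouping <- as.character(grouping)
  stopifnot(length(grouping) == ncol(mat))
  tab <- table(grouping)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 groups with >= 2 sequences each")
  comp <- .pairDiffComponents(mat, grouping)
  Hw <- unname(if (length(tab) == 2) mean(comp$within) else comp$HwPooled)
  value <- if (comp$Hb == 0) NA_real_ else unname(1 - Hw / comp$Hb)
  list(estimator = "hudson_seq", value = value, Hw = Hw, Hb = comp$Hb,
       groups = names(tab))
}

# Weir & Cockerham (1984) variance components for one allele at one locus.
# freqs: matrix pops x 2 columns (p, h) with n per pop; returns c(a, b, c).
.wcComponents <- function(nInd, p, h) {
  r <- length(nInd)
  nbar <- mean(nInd)
  nc <- (r * nbar - sum(nInd^2) / (r * nbar)) / (r - 1)
  pbar <- sum(nInd * p) / (r * nbar)
  s2 <- sum(nInd * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(nInd * h) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r -
                              hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                hbar * (2 * nbar - 1) / (4 * nbar))
  c(a = a, b = b, c = hbar / 2)
}

#' Microsatellite summary statistics
#'
#' Mean number of alleles across loci per group, the multi-locus
#' Weir-Cockerham (1984) FST and the shared-allele distance
#' \eqn{D_{AS} = 1 - } mean proportion of alleles shared between
#' cross-group individual pairs.
#'
#' @param ssrLoci list of \linkS4class{MicrosatLocus}.
#' @param grouping named group label per individual (names = sample ids) or
#'   a data.frame with columns id and group.
#' @return list with meanAlleles (per group), fstWC and das.
#' @export
microsatStats <- function(ssrLoci, grouping) {
  if (is.data.frame(grouping))
    grouping <- setNames(grouping$group, grouping$id)
  stopifnot(length(ssrLoci) >= 1)
  gset <- sort(unique(grouping))
  meanA <- setNames(numeric(length(gset)), gset)
  for (g in gset)
    meanA[g] <- mean(vapply(ssrLoci, function(ms) {
      ids <- intersect(rownames(ms@genotypes), names(grouping)[grouping == g])
      length(unique(as.vector(ms@genotypes[ids, ])))
    }, 0))
  num <- den <- 0
  nMono <- 0L
  for (ms in ssrLoci) {
    ids <- intersect(rownames(ms@genotypes), names(grouping))
    gr <- grouping[ids]
    geno <- ms@genotypes[ids, , drop = FALSE]
    alleles <- sort(unique(as.vector(geno)))
    if (length(alleles) < 2) {
      nMono <- nMono + 1L
      next
    }
    nInd <- vapply(gset, function(g) sum(gr == g), 0)
    for (a in alleles) {
      p <- vapply(gset, function(g) {
        gg <- geno[gr == g, , drop = FALSE]
        mean(gg == a)
      }, 0)
      h <- vapply(gset, function(g) {
        gg <- geno[gr == g, , drop = FALSE]
        mean(xor(gg[, 1] == a, gg[, 2] == a))
      }, 0)
      abc <- .wcComponents(nInd, p, h)
      num <- num + abc[1]
      den <- den + sum(abc)
    }
  }
  if (nMono > 0)
    warning(sprintf("%d locus/loci monomorphic in all groups excluded from FST",
                    nMono))
  fst <- if (den > 0) num / den else NA_real_
  # shared-allele distance over cross-group individual pairs
  ids <- names(grouping)
  shared <- 0
  npair <- 0
  pairsBetween <- which(outer(grouping, grouping, "!=") &
                          upper.tri(matrix(0, length(ids), length(ids))),
                        arr.ind = TRUE)
  for (ms in ssrLoci) {
    geno <- ms@genotypes[ids, , drop = FALSE]
    g1 <- geno[pairsBetween[, 1], , drop = FALSE]
    g2 <- geno[pairsBetween[, 2], , drop = FALSE]
    ps <- (pmin((g1[, 1] == g2[, 1]) + (g1[, 1] == g2[, 2]), 1) +
             pmin((g1[, 2] == g2[, 1]) + (g1[, 2] == g2[, 2]), 1) +
             pmin((g2[, 1] == g1[, 1]) + (g2[, 1] == g1[, 2]), 1) +
             pmin((g2[, 2] == g1[, 1]) + (g2[, 2] == g1[, 2]), 1)) / 4
    shared <- shared + sum(ps)
    npair <- npair + nrow(pairsBetween)
  }
  list(meanAlleles = meanA, fstWC = unname(fst), das = 1 - shared / npair)
}

.SUMMARY_STAT_NAMES <- c("ssr_meanA_West", "ssr_meanA_East", "ssr_fst_wc",
                         "ssr_das", "seq_hap_West", "seq_hap_East",
                         "seq_hap_pooled", "seq_S_pooled", "seq_fst_hudson")

# Summary vector from raw pieces: a list of per-locus state matrices for the
# sequence control loci (columns ordered West then East) and a list of
# genotype matrices for the SSR loci, plus the individual grouping.
.summaryVectorFrom <- function(seqMats, seqGroups, ssrLoci, grouping) {
  hapW <- hapE <- hapP <- Spool <- numeric(length(seqMats))
  wD <- wP <- bD <- bP <- 0
  for (i in seq_along(seqMats)) {
    mat <- seqMats[[i]]
    gr <- seqGroups[[i]]
    seg <- apply(mat, 1, function(r) length(unique(r)) > 1)
    mat <- mat[seg, , drop = FALSE]
    Spool[i] <- nrow(mat)
    key <- apply(mat, 2, paste, collapse = "\r")
    hapP[i] <- length(unique(key))
    hapW[i] <- length(unique(key[gr == "West"]))
    hapE[i] <- length(unique(key[gr == "East"]))
    comp <- .pairDiffComponents(mat, gr)
    nW <- sum(gr == "West"); nE <- sum(gr == "East")
    wD <- wD + comp$within["West"] * choose(nW, 2) +
      comp$within["East"] * choose(nE, 2)
    wP <- wP + choose(nW, 2) + choose(nE, 2)
    bD <- bD + comp$Hb * nW * nE
    bP <- bP + nW * nE
  }
  if (bD == 0) stop("undefined sequence FST (no between-group differences)")
  fstSeq <- 1 - (wD / wP) / (bD / bP)
  ssr <- microsatStats(ssrLoci, grouping)
  if (is.na(ssr$fstWC)) stop("undefined SSR FST (all loci monomorphic)")
  out <- c(ssr$meanAlleles["West"], ssr$meanAlleles["East"], ssr$fstWC,
           ssr$das, mean(hapW), mean(hapE), mean(hapP), mean(Spool), fstSeq)
  names(out) <- .SUMMARY_STAT_NAMES
  if (anyNA(out)) stop("undefined entry in summary statistic vector")
  out
}

#' The fixed-order ABC summary statistic vector
#'
#' Nine numbers in fixed order, computed from the control loci only: the
#' mean number of alleles across SSR loci in each population, the
#' Weir-Cockerham SSR FST, the shared-allele distance, the mean number of
#' distinct haplotypes per population and pooled across sequence loci, the
#' mean number of segregating sites (pooled), and the multi-locus Hudson
#' FST for sequences. Undefined entries raise an error, since ABC distances
#' require complete vectors.
#'
#' @param bundle a \linkS4class{StudyBundle} with at least one SSR and one
#'   sequence control locus.
#' @return named numeric vector of length 9.
#' @export
abcSummaryVector <- function(bundle) {
  reg <- bundle@registry
  ctrl <- reg$name[reg$kind == "control_seq"]
  if (!length(ctrl) || !length(bundle@ssrLoci))
    stop("need >= 1 sequence control locus and >= 1 SSR locus")
  grouping <- setNames(bundle@samples$group, bundle@samples$id)
  seqMats <- list()
  seqGroups <- list()
  for (nm in ctrl) {
    al <- excludeGapSites(bundle@seqLoci[[nm]])
    b <- .biallelicMatrix(al)
    seqMats[[nm]] <- b$mat
    seqGroups[[nm]] <- unname(grouping[b$ids])
  }
  .summaryVectorFrom(seqMats, seqGroups, bundle@ssrLoci, grouping)
}
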