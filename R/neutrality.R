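#' @include AllClasses.R abc.R
NULL

#' Resample joint parameter draws from an ABC posterior
#'
#' Draws rows of the adjusted particle matrix with replacement,
#' proportionally to the Epanechnikov weights.
#'
#' @param posterior an \linkS4class{ABCPosterior}.
#' @param n number of draws.
#' @return parameter matrix with n rows.
#' @export
resamplePosterior <- function(posterior, n) {
  w <- posterior@weights
  if (!nrow(posterior@adjusted)) stop("empty posterior")
  if (all(w == 0)) stop("all-zero weights")
  idx <- sample.int(nrow(posterior@adjusted), n, replace = TRUE, prob = w)
  posterior@adjusted[idx, , drop = FALSE]
}

#' Simulated null distribution of neutrality statistics for one gene
#'
#' For each posterior parameter draw one infinite-sites locus of the
#' gene's length is simulated under the divergence model, derived states
#' are flipped at the gene's estimated misorientation rate, and Tajima's
#' D, normalized Fay-Wu H (pooled, West, East and optionally per color
#' group via subsampling the observed color composition), the West-East
#' Hudson FST, the color-group FST and the pooled Watterson theta
#' (per-locus units) are recorded.
#'
#' @param gene gene name.
#' @param L locus length in sites.
#' @param draws parameter matrix from \code{\link{resamplePosterior}}
#'   (one simulation per row).
#' @param m misorientation rate applied to the simulated derived states.
#' @param nW,nE simulated sample sizes (haploid sequences) per population.
#' @param colorComp optional color composition: a data.frame with columns
#'   color, West, East giving how many sequences of each color group come
#'   from each geographic population.
#' @return a \linkS4class{NullDistribution}; statistics that are undefined
#'   in a given simulation (no segregating site in the relevant subset)
#'   are NA and are dropped per statistic at test time.
#' @export
geneNullDistribution <- function(gene, L, draws, m = 0, nW, nE,
                                 colorComp = NULL) {
  nSims <- nrow(draws)
  cols <- c("thetaW", "D_pooled", "H_pooled", "D_West", "H_West",
            "D_East", "H_East", "fst_geo")
  if (!is.null(colorComp)) {
    if (any(colorComp$West > nW) || any(colorComp$East > nE))
      stop("color composition exceeds simulated sample sizes")
    cols <- c(cols, paste0("D_", colorComp$color),
              paste0("H_", colorComp$color), "fst_color")
  }
  out <- matrix(NA_real_, nSims, length(cols),
                dimnames = list(NULL, cols))
  gr <- rep(c("West", "East"), c(nW, nE))
  iW <- seq_len(nW)
  iE <- nW + seq_len(nE)
  for (s in seq_len(nSims)) {
    params <- .rowParams(draws[s, ])
    mat <- .simSeqInf(params, nW, nE, L)
    if (nrow(mat) && m > 0) {
      flip <- runif(nrow(mat)) < m
      mat[flip, ] <- 1L - mat[flip, , drop = FALSE]
    }
    sf <- .sfsStats(mat)
    out[s, "thetaW"] <- sf$thetaW
    out[s, "D_pooled"] <- sf$D
    out[s, "H_pooled"] <- .fayWuStats(mat)$H
    out[s, "D_West"] <- .sfsStats(mat, iW)$D
    out[s, "H_West"] <- .fayWuStats(mat, iW)$H
    out[s, "D_East"] <- .sfsStats(mat, iE)$D
    out[s, "H_East"] <- .fayWuStats(mat, iE)$H
    if (nrow(mat)) {
      comp <- .pairDiffComponents(mat, gr)
      out[s, "fst_geo"] <- if (comp$Hb > 0)
        1 - mean(comp$within) / comp$Hb else NA_real_
    }
    if (!is.null(colorComp)) {
      pw <- sample(iW)
      pe <- sample(iE)
      colGr <- rep(NA_character_, nW + nE)
      oW <- oE <- 0L
      for (ci in seq_len(nrow(colorComp))) {
        take <- c(if (colorComp$West[ci] > 0)
                    pw[oW + seq_len(colorComp$West[ci])],
                  if (colorComp$East[ci] > 0)
                    pe[oE + seq_len(colorComp$East[ci])])
        oW <- oW + colorComp$West[ci]
        oE <- oE + colorComp$East[ci]
        colGr[take] <- colorComp$color[ci]
        if (length(take) >= 2) {
          out[s, paste0("D_", colorComp$color[ci])] <-
            .sfsStats(mat, take)$D
          out[s, paste0("H_", colorComp$color[ci])] <-
            .fayWuStats(mat, take)$H
        }
      }
      keep <- !is.na(colGr)
      if (nrow(mat) && sum(keep) >= 2) {
        comp <- .pairDiffComponents(mat[, keep, drop = FALSE],
                                    colGr[keep])
        out[s, "fst_color"] <- if (!is.na(comp$Hb) && comp$Hb > 0)
          1 - comp$HwPooled / comp$Hb else NA_real_
      }
    }
  }
  new("NullDistribution", gene = gene, stats = out,
      config = list(L = L, m = m, nW = nW, nE = nE,
                    colorComp = colorComp, nSims = nSims))
}

.nullColumn <- function(null, statistic) {
  if (is(null, "NullDistribution")) {
    if (!statistic %in% colnames(null@stats))
      stop(sprintf("statistic '%s' not in null distribution", statistic))
    null@stats[, statistic]
  } else as.numeric(null)
}

#' Monte-Carlo rank test against a simulated null
#'
#' Uses the pseudo-count rank \eqn{r = (\#\{sim \le obs\} + 1)/(n + 1)},
#' so p-values are never 0. The one-tailed test targets low values (the H
#' convention); the two-tailed p is \eqn{\min(1, 2\min(r, 1-r))}.
#'
#' @param observed observed statistic value.
#' @param null a \linkS4class{NullDistribution} column name via
#'   \code{statistic}, or a numeric vector of simulated values.
#' @param tail "two_tailed" or "one_tailed_low".
#' @param statistic column to use when \code{null} is a
#'   \linkS4class{NullDistribution}.
#' @return list with observed, p, tail and nUsed.
#' @export
rankTest <- function(observed, null, tail = c("two_tailed",
                                              "one_tailed_low"),
                     statistic = "D_pooled") {
  tail <- match.arg(tail)
  if (is.na(observed)) stop("undefined observed statistic")
  vals <- .nullColumn(null, statistic)
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("empty null distribution")
  r <- (sum(vals <= observed) + 1) / (length(vals) + 1)
  q <- (sum(vals >= observed) + 1) / (length(vals) + 1)
  p <- if (tail == "one_tailed_low") r else min(1, 2 * min(r, q))
  list(observed = observed, p = p, tail = tail, nUsed = length(vals))
}

#' Theta-matched FST rank test
#'
#' FST depends on the mutation rate, so the observed FST is ranked only
#' against simulated datasets whose pooled Watterson theta (per-locus
#' units) lies within \code{window} of the gene's observed theta.
#'
#' @param observedFst observed FST.
#' @param observedThetaW observed pooled Watterson theta (per locus).
#' @param null a \linkS4class{NullDistribution} carrying a thetaW column.
#' @param window matching half-width (same units as theta); default 1.5.
#' @param statistic FST column to test ("fst_geo" or "fst_color").
#' @return list with observed, p, tail, nUsed (the matched count).
#' @export
fstThetaMatchedTest <- function(observedFst, observedThetaW, null,
                                window = 1.5, statistic = "fst_geo") {
  stopifnot(is(null, "NullDistribution"))
  theta <- null@stats[, "thetaW"]
  fst <- .nullColumn(null, statistic)
  keep <- !is.na(fst) & !is.na(theta) &
    abs(theta - observedThetaW) <= window
  if (!any(keep)) stop("no matched simulations")
  rankTest(observedFst, fst[keep], tail = "two_tailed")
}

#' Color-group rank test
#'
#' Ranks an observed per-color-group statistic against null simulations in
#' which the stated numbers of sequences were subsampled from the
#' simulated Western and Eastern populations (the observed color
#' composition).
#'
#' @param observed observed statistic for the color group.
#' @param null a \linkS4class{NullDistribution} built with a
#'   \code{colorComp}.
#' @param statistic "D" or "H".
#' @param color color-group name.
#' @param tail passed to \code{\link{rankTest}}.
#' @return list with observed, p, tail and nUsed.
#' @export
colorGroupTest <- function(observed, null, statistic = c("D", "H"),
                           color, tail = c("two_tailed",
                                           "one_tailed_low")) {
  statistic <- match.arg(statistic)
  rankTest(observed, null, tail = match.arg(tail),
           statistic = paste0(statistic, "_", color))
}

# Observed color composition (sequence counts per color split by group).
.colorComposition <- function(samples) {
  comp <- do.call(rbind, lapply(.COLORS, function(cl) data.frame(
    color = cl,
    West = sum(samples$color == cl & samples$group == "West"),
    East = sum(samples$color == cl & samples$group == "East"),
    stringsAsFactors = FALSE)))
  comp[comp$West + comp$East > 0, , drop = FALSE]
}

#' Run all per-gene neutrality tests of a study
#'
#' For every candidate gene: computes the observed Tajima's D and
#' normalized Fay-Wu H on the pooled sample, the geographic groups and the
#' color groups, the West-East and color-group FST and the pooled
#' Watterson theta; estimates the per-gene misorientation rate from the
#' outgroup; simulates the gene's null distribution from posterior
#' parameter draws; and ranks every observed statistic in its null
#' (two-tailed for D and FST, one-tailed-low for H; FST tests are
#' theta-matched within \code{thetaWindow}).
#'
#' @param bundle a \linkS4class{StudyBundle}.
#' @param posterior an \linkS4class{ABCPosterior} for the control-locus
#'   divergence model.
#' @param nSims simulations per gene.
#' @param thetaWindow FST theta-matching half-width (per-locus units).
#' @param colorTests include color-group tests.
#' @return list with \code{dh} (per sample-set D/H table), \code{fst}
#'   (per-gene FST table), \code{pvals} (long p-value table feeding the
#'   pathway analysis) and \code{nulls} (per-gene
#'   \linkS4class{NullDistribution}s).
#' @export
neutralityTests <- function(bundle, posterior, nSims = 2000,
                            thetaWindow = 1.5, colorTests = TRUE) {
  reg <- bundle@registry
  genes <- reg$name[reg$kind == "candidate"]
  samples <- bundle@samples
  comp <- if (colorTests) .colorComposition(samples) else NULL
  dh <- list()
  fstTab <- list()
  pvals <- list()
  nulls <- list()
  for (g in genes) {
    al <- excludeGapSites(bundle@seqLoci[[g]])
    hasOg <- length(al@outgroup) > 0
    b <- .biallelicMatrix(al)
    grouping <- setNames(samples$group, samples$id)[b$ids]
    colorOf <- setNames(samples$color, samples$id)[b$ids]
    m <- 0
    orient <- NULL
    if (hasOg) {
      m <- estimateMisorientation(al)@m
      orient <- orientAlleles(al)
    }
    nW <- sum(grouping == "West")
    nE <- sum(grouping == "East")
    draws <- resamplePosterior(posterior, nSims)
    null <- geneNullDistribution(g, b$L, draws, m = m, nW = nW, nE = nE,
                                 colorComp = comp)
    nulls[[g]] <- null
    thetaObs <- .sfsStats(b$mat)$thetaW
    sets <- list(pooled = seq_along(b$ids),
                 West = which(grouping == "West"),
                 East = which(grouping == "East"))
    if (colorTests)
      for (ci in seq_len(nrow(comp)))
        sets[[comp$color[ci]]] <- which(colorOf == comp$color[ci])
    for (setName in names(sets)) {
      idx <- sets[[setName]]
      Dobs <- tajimaD(b$mat, idx)
      Hobs <- if (hasOg) {
        oidx <- match(b$ids[idx], orient@sampleIds)
        fayWuHNorm(orient, oidx)
      } else NA_real_
      nullSet <- if (setName == "pooled") "pooled" else setName
      pD <- if (!is.na(Dobs))
        tryCatch(rankTest(Dobs, null,
                          statistic = paste0("D_", nullSet))$p,
                 error = function(e) NA_real_) else NA_real_
      pH <- if (!is.na(Hobs))
        tryCatch(rankTest(Hobs, null, tail = "one_tailed_low",
                          statistic = paste0("H_", nullSet))$p,
                 error = function(e) NA_real_) else NA_real_
      dh[[length(dh) + 1L]] <- data.frame(
        gene = g, sampleSet = setName, n = length(idx), D = Dobs, pD = pD,
        H = Hobs, pH = pH, stringsAsFactors = FALSE)
      if (!is.na(pD))
        pvals[[length(pvals) + 1L]] <- data.frame(
          gene = g, statistic = "D", sampleSet = setName, p = pD,
          stringsAsFactors = FALSE)
      if (!is.na(pH))
        pvals[[length(pvals) + 1L]] <- data.frame(
          gene = g, statistic = "H", sampleSet = setName, p = pH,
          stringsAsFactors = FALSE)
    }
    fstGeoObs <- hudsonFst(b$mat, grouping)$value
    geo <- tryCatch(fstThetaMatchedTest(fstGeoObs, thetaObs, null,
                                        window = thetaWindow,
                                        statistic = "fst_geo"),
                    error = function(e) list(p = NA_real_, nUsed = 0L))
    fstColObs <- NA_real_
    colRes <- list(p = NA_real_, nUsed = 0L)
    if (colorTests && length(unique(colorOf)) >= 2) {
      compCol <- .pairDiffComponents(b$mat, colorOf)
      fstColObs <- if (!is.na(compCol$Hb) && compCol$Hb > 0)
        1 - compCol$HwPooled / compCol$Hb else NA_real_
      if (!is.na(fstColObs))
        colRes <- tryCatch(fstThetaMatchedTest(fstColObs, thetaObs, null,
                                               window = thetaWindow,
                                               statistic = "fst_color"),
                           error = function(e)
                             list(p = NA_real_, nUsed = 0L))
    }
    fstTab[[length(fstTab) + 1L]] <- data.frame(
      gene = g, thetaW = thetaObs, fstGeo = fstGeoObs, pGeo = geo$p,
      nGeo = geo$nUsed, fstColor = fstColObs, pColor = colRes$p,
      nColor = colRes$nUsed, misorientation = m, stringsAsFactors = FALSE)
    if (!is.na(geo$p))
      pvals[[length(pvals) + 1L]] <- data.frame(
        gene = g, statistic = "FST", sampleSet = "geographic", p = geo$p,
        stringsAsFactors = FALSE)
    if (!is.na(colRes$p))
      pvals[[length(pvals) + 1L]] <- data.frame(
        gene = g, statistic = "FST", sampleSet = "color", p = colRes$p,
        stringsAsFactors = FALSE)
  }
  list(dh = do.call(rbind, dh), fst = do.call(rbind, fstTab),
       pvals = do.call(rbind, pvals), nulls = nulls)
}
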