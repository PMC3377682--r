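#' @include AllClasses.R divsim.R sumstats.R
NULL

.PARAM_NAMES <- c("NW", "NE", "NAnc", "Td", "muSeq", "muSSR", "pSSR")
.LOG_PARAMS <- c("NW", "NE", "NAnc", "muSeq", "muSSR")

#' Default priors for the divergence model
#'
#' Log-uniform priors on the population sizes and both mutation rates
#' (weakly informative, spanning plant-typical values), uniform on the
#' geometric step parameter, and a truncated normal on the divergence
#' time: \eqn{T_d \sim N(500, 100)} truncated to [350, 750] generations.
#'
#' @param Td overrides for the Td marginal, a list with mean, sd, lower,
#'   upper.
#' @return a \linkS4class{PriorSpec}.
#' @export
defaultPriors <- function(Td = list(mean = 500, sd = 100, lower = 350,
                                    upper = 750)) {
  new("PriorSpec", marginals = list(
    NW = list(dist = "loguniform", lower = 1e2, upper = 1e5),
    NE = list(dist = "loguniform", lower = 1e2, upper = 1e5),
    NAnc = list(dist = "loguniform", lower = 1e2, upper = 1e5),
    Td = list(dist = "truncnorm", mean = Td$mean, sd = Td$sd,
              lower = Td$lower, upper = Td$upper),
    muSeq = list(dist = "loguniform", lower = 1e-9, upper = 1e-7),
    muSSR = list(dist = "loguniform", lower = 1e-5, upper = 1e-3),
    pSSR = list(dist = "uniform", lower = 0, upper = 0.9)))
}

#' Point-mass priors at given parameter values
#'
#' @param params a \linkS4class{DivergenceModelParams}.
#' @return a \linkS4class{PriorSpec} of fixed marginals.
#' @export
fixedPriors <- function(params) {
  v <- vapply(.PARAM_NAMES, function(p) slot(params, p), 0)
  new("PriorSpec", marginals = lapply(setNames(as.list(v), .PARAM_NAMES),
                                      function(x) list(dist = "fixed",
                                                       value = x)))
}

.sampleMarginal <- function(m, n) {
  switch(m$dist,
    fixed = rep(m$value, n),
    uniform = runif(n, m$lower, m$upper),
    loguniform = {
      if (m$lower <= 0) stop("loguniform needs a positive lower bound")
      exp(runif(n, log(m$lower), log(m$upper)))
    },
    truncnorm = {
      # inverse-CDF sampling honours the truncation exactly
      plo <- pnorm(m$lower, m$mean, m$sd)
      phi <- pnorm(m$upper, m$mean, m$sd)
      qnorm(runif(n, plo, phi), m$mean, m$sd)
    },
    stop(sprintf("unknown prior family '%s'", m$dist)))
}

.priorSupport <- function(priors) {
  t(vapply(priors@marginals, function(m) {
    if (m$dist == "fixed") c(m$value, m$value) else c(m$lower, m$upper)
  }, numeric(2)))
}

#' Draw i.i.d. samples from the prior
#'
#' @param priors a \linkS4class{PriorSpec}.
#' @param n number of draws.
#' @return matrix n x 7 with columns NW, NE, NAnc, Td, muSeq, muSSR, pSSR.
#' @export
samplePrior <- function(priors, n) {
  stopifnot(n >= 1)
  for (m in priors@marginals)
    if (m$dist != "fixed" && m$lower > m$upper) stop("invalid prior bounds")
  out <- vapply(.PARAM_NAMES, function(p)
    .sampleMarginal(priors@marginals[[p]], n), numeric(n))
  matrix(out, nrow = n, dimnames = list(NULL, .PARAM_NAMES))
}

.rowParams <- function(row) {
  new("DivergenceModelParams", NW = row[["NW"]], NE = row[["NE"]],
      NAnc = row[["NAnc"]], Td = row[["Td"]], muSeq = row[["muSeq"]],
      muSSR = row[["muSSR"]], pSSR = row[["pSSR"]])
}

#' Derive the simulation template from an observed bundle
#'
#' Records everything the reference-table simulator must mirror from the
#' observed data: sample sizes per population (haploid sequences and
#' diploid individuals), sequence control-locus lengths, and each SSR
#' locus's motif and allele range.
#'
#' @param bundle a \linkS4class{StudyBundle}.
#' @return a template list consumed by \code{\link{simulateReferenceTable}}.
#' @export
bundleTemplate <- function(bundle) {
  sm <- bundle@samples
  reg <- bundle@registry
  ctrl <- reg[reg$kind == "control_seq", , drop = FALSE]
  ssr <- reg[reg$kind == "control_ssr", , drop = FALSE]
  list(nW = sum(sm$group == "West"), nE = sum(sm$group == "East"),
       seqLens = setNames(ctrl$length, ctrl$name),
       ssr = data.frame(name = ssr$name, motif = ssr$motif,
                        aMin = ssr$alleleMin, aMax = ssr$alleleMax,
                        stringsAsFactors = FALSE))
}

# Mean-alleles / WC-FST / shared-allele-distance engine on raw genotype
# matrices (rows ordered West first), used by both the observed-data path
# and the simulator hot loop.
.ssrSummaryFast <- function(genos, nW, nE, pairIdx) {
  nLoc <- length(genos)
  mw <- me <- numeric(nLoc)
  num <- den <- 0
  nInd <- c(nW, nE)
  shared <- 0
  for (l in seq_len(nLoc)) {
    g <- genos[[l]]
    gw <- g[seq_len(nW), , drop = FALSE]
    ge <- g[nW + seq_len(nE), , drop = FALSE]
    mw[l] <- length(unique(as.vector(gw)))
    me[l] <- length(unique(as.vector(ge)))
    alleles <- unique(as.vector(g))
    if (length(alleles) >= 2) {
      for (a in alleles) {
        p <- c(mean(gw == a), mean(ge == a))
        h <- c(mean(xor(gw[, 1] == a, gw[, 2] == a)),
               mean(xor(ge[, 1] == a, ge[, 2] == a)))
        abc <- .wcComponents(nInd, p, h)
        num <- num + abc[1]
        den <- den + sum(abc)
      }
    }
    g1 <- g[pairIdx[, 1], , drop = FALSE]
    g2 <- g[pairIdx[, 2], , drop = FALSE]
    shared <- shared +
      sum((pmin((g1[, 1] == g2[, 1]) + (g1[, 1] == g2[, 2]), 1) +
             pmin((g1[, 2] == g2[, 1]) + (g1[, 2] == g2[, 2]), 1) +
             pmin((g2[, 1] == g1[, 1]) + (g2[, 1] == g1[, 2]), 1) +
             pmin((g2[, 2] == g1[, 1]) + (g2[, 2] == g1[, 2]), 1)) / 4)
  }
  if (den <= 0) stop("undefined SSR FST (all simulated loci monomorphic)")
  list(meanA = c(West = mean(mw), East = mean(me)), fst = num / den,
       das = 1 - shared / (nrow(pairIdx) * nLoc))
}

# One reference-table row: simulate the control loci under `params` with
# the template's shapes and return the 9 summary statistics.
.simulateSummaryRow <- function(params, template) {
  nW <- template$nW
  nE <- template$nE
  gr <- rep(c("West", "East"), c(nW, nE))
  seqMats <- lapply(template$seqLens, function(L) {
    sim <- .simSeqJC(params, nW, nE, L, outTime = 0)
    if (length(sim$pos) == 0) matrix(0L, 0, nW + nE) else sim$states
  })
  genos <- lapply(seq_len(nrow(template$ssr)), function(i)
    .simSSRmat(params, nW, nE,
               c(template$ssr$aMin[i], template$ssr$aMax[i])))
  if (is.null(template$pairIdx)) {
    pairIdx <- as.matrix(expand.grid(seq_len(nW), nW + seq_len(nE)))
    template$pairIdx <- pairIdx
  }
  ssr <- .ssrSummaryFast(genos, nW, nE, template$pairIdx)
  hapW <- hapE <- hapP <- Spool <- numeric(length(seqMats))
  wD <- wP <- bD <- bP <- 0
  for (i in seq_along(seqMats)) {
    mat <- seqMats[[i]]
    if (nrow(mat)) {
      seg <- vapply(seq_len(nrow(mat)),
                    function(r) length(unique(mat[r, ])) > 1, TRUE)
      mat <- mat[seg, , drop = FALSE]
    }
    Spool[i] <- nrow(mat)
    key <- apply(mat, 2, paste, collapse = "\r")
    hapP[i] <- length(unique(key))
    hapW[i] <- length(unique(key[seq_len(nW)]))
    hapE[i] <- length(unique(key[nW + seq_len(nE)]))
    comp <- .pairDiffComponents(mat, gr)
    wD <- wD + comp$within["West"] * choose(nW, 2) +
      comp$within["East"] * choose(nE, 2)
    wP <- wP + choose(nW, 2) + choose(nE, 2)
    bD <- bD + comp$Hb * nW * nE
    bP <- bP + nW * nE
  }
  if (bD == 0) stop("undefined sequence FST in simulation")
  out <- c(ssr$meanA["West"], ssr$meanA["East"], ssr$fst, ssr$das,
           mean(hapW), mean(hapE), mean(hapP), mean(Spool),
           1 - (wD / wP) / (bD / bP))
  names(out) <- .SUMMARY_STAT_NAMES
  out
}

#' Simulate the ABC reference table
#'
#' One summary-statistic vector per parameter draw, simulated under the
#' divergence model with Jukes-Cantor sequence mutation and generalized
#' stepwise microsatellite mutation, mirroring the observed data's shapes.
#' Rows whose statistics are undefined (e.g. no between-group sequence
#' difference) are re-simulated under the same draw, up to 50 attempts.
#'
#' @param draws parameter matrix from \code{\link{samplePrior}}.
#' @param template from \code{\link{bundleTemplate}}.
#' @param priors the \linkS4class{PriorSpec} the draws came from. When a
#'   draw keeps producing undefined statistics (a corner of the prior where
#'   every locus is monomorphic), the draw itself is replaced by a fresh
#'   prior sample after 10 attempts; with \code{NULL} such a row is fatal
#'   after 50 attempts.
#' @param progress print a progress line every 1000 rows.
#' @return a \linkS4class{ReferenceTable}.
#' @export
simulateReferenceTable <- function(draws, template, priors = NULL,
                                   progress = FALSE) {
  n <- nrow(draws)
  template$pairIdx <- as.matrix(expand.grid(seq_len(template$nW),
                                            template$nW +
                                              seq_len(template$nE)))
  stats <- matrix(NA_real_, n, length(.SUMMARY_STAT_NAMES),
                  dimnames = list(NULL, .SUMMARY_STAT_NAMES))
  retries <- 0L
  redraws <- 0L
  for (i in seq_len(n)) {
    row <- NULL
    for (att in seq_len(50L)) {
      if (att > 10L && !is.null(priors)) {
        draws[i, ] <- samplePrior(priors, 1)
        redraws <- redraws + 1L
      }
      row <- tryCatch(.simulateSummaryRow(.rowParams(draws[i, ]),
                                          template),
                      error = function(e) NULL)
      if (!is.null(row)) break
      retries <- retries + 1L
    }
    if (is.null(row))
      stop(sprintf("row %d failed after 50 attempts", i))
    stats[i, ] <- row
    if (progress && i %% 1000 == 0)
      message(sprintf("  reference table: %d/%d", i, n))
  }
  if (retries > 0)
    message(sprintf(
      "re-simulated %d undefined row attempt(s) (%d draws replaced)",
      retries, redraws))
  new("ReferenceTable", params = draws, stats = stats)
}

#' Rejection ABC with local linear regression adjustment
#'
#' Accepts the \code{tolerance} proportion of draws nearest the observed
#' vector (Euclidean distance on MAD-standardized statistics), weights them
#' with an Epanechnikov kernel in distance (the boundary particle gets
#' weight 0), and adjusts each parameter by a weighted linear regression on
#' the centered statistics. Positive parameters are regressed on the log
#' scale and back-transformed; adjusted particles are clamped to the prior
#' support.
#'
#' @param observed observed summary vector (same order as the table).
#' @param table a \linkS4class{ReferenceTable}.
#' @param tolerance acceptance proportion in (0, 1].
#' @param priors the \linkS4class{PriorSpec} used for the draws (for
#'   support clamping); \code{NULL} skips clamping.
#' @return an \linkS4class{ABCPosterior}.
#' @export
abcFit <- function(observed, table, tolerance = 1e-2, priors = NULL) {
  stopifnot(tolerance > 0, tolerance <= 1)
  stats <- table@stats
  if (nrow(stats) < 1 / tolerance)
    stop("table rows must be >= 1/tolerance")
  scale <- apply(stats, 2, mad)
  zero <- scale == 0
  scale[zero] <- apply(stats[, zero, drop = FALSE], 2, sd)
  use <- scale > 0
  z <- sweep(stats[, use, drop = FALSE], 2, observed[use], "-")
  z <- sweep(z, 2, scale[use], "/")
  d <- sqrt(rowSums(z^2))
  nacc <- ceiling(tolerance * nrow(stats))
  ord <- order(d)[seq_len(nacc)]
  delta <- max(d[ord])
  w <- if (delta > 0) 1 - (d[ord] / delta)^2 else rep(1, nacc)
  if (sum(w) == 0) w <- rep(1, nacc)
  raw <- table@params[ord, , drop = FALSE]
  trans <- raw
  logp <- intersect(.LOG_PARAMS, colnames(trans))
  for (p in logp) trans[, p] <- log(trans[, p])
  X <- z[ord, , drop = FALSE]
  keep <- if (nacc > 1) apply(X, 2, var) > 0 else rep(FALSE, ncol(X))
  regressionUsed <- FALSE
  adjusted <- trans
  if (any(keep) && nacc > sum(keep) + 2) {
    Xk <- cbind(1, X[, keep, drop = FALSE])
    fit <- tryCatch(lm.wfit(Xk, trans, w), error = function(e) NULL)
    if (!is.null(fit) && fit$rank == ncol(Xk) &&
        !anyNA(fit$coefficients)) {
      cf <- fit$coefficients
      if (is.null(dim(cf)))
        cf <- matrix(cf, ncol = 1,
                     dimnames = list(NULL, colnames(trans)))
      B <- cf[-1, , drop = FALSE]
      adjusted <- trans - X[, keep, drop = FALSE] %*% B
      regressionUsed <- TRUE
    }
  }
  if (!regressionUsed)
    warning("singular regression design; falling back to rejection only")
  for (p in logp) adjusted[, p] <- exp(adjusted[, p])
  if (!is.null(priors)) {
    supp <- .priorSupport(priors)
    for (p in intersect(colnames(adjusted), rownames(supp)))
      adjusted[, p] <- pmin(pmax(adjusted[, p], supp[p, 1]), supp[p, 2])
  }
  new("ABCPosterior", raw = raw, adjusted = adjusted, weights = w / sum(w),
      tolerance = tolerance, obs = observed,
      regressionUsed = regressionUsed)
}

#' Posterior predictive model check
#'
#' Simulates \code{nPred} datasets from posterior parameter resamples,
#' then (a) projects prior, posterior-predictive and observed statistic
#' vectors onto the first two principal components of the prior-simulated
#' statistics and (b) reports a two-tailed rank p-value of each observed
#' statistic within its posterior-predictive distribution.
#'
#' @param posterior an \linkS4class{ABCPosterior}.
#' @param template from \code{\link{bundleTemplate}}.
#' @param table the prior \linkS4class{ReferenceTable} (defines the PCA
#'   space).
#' @param nPred number of posterior-predictive simulations (>= 100).
#' @return list with \code{rank} (data.frame statistic/observed/p),
#'   \code{pca} (list of projected coordinates, or NULL when the prior
#'   statistic covariance is degenerate) and \code{pred} (the predictive
#'   statistic matrix).
#' @export
posteriorPredictiveCheck <- function(posterior, template, table,
                                     nPred = 500) {
  stopifnot(nPred >= 100)
  template$pairIdx <- as.matrix(expand.grid(seq_len(template$nW),
                                            template$nW +
                                              seq_len(template$nE)))
  draws <- resamplePosterior(posterior, nPred)
  pred <- matrix(NA_real_, nPred, length(.SUMMARY_STAT_NAMES),
                 dimnames = list(NULL, .SUMMARY_STAT_NAMES))
  for (i in seq_len(nPred)) {
    row <- NULL
    for (att in seq_len(50L)) {
      row <- tryCatch(.simulateSummaryRow(.rowParams(draws[i, ]),
                                          template),
                      error = function(e) NULL)
      if (!is.null(row)) break
    }
    if (is.null(row)) stop("posterior predictive simulation failed")
    pred[i, ] <- row
  }
  obs <- posterior@obs
  pr <- vapply(seq_along(obs), function(j) {
    r <- (sum(pred[, j] <= obs[j]) + 1) / (nPred + 1)
    min(1, 2 * min(r, 1 - r))
  }, 0)
  rank <- data.frame(statistic = .SUMMARY_STAT_NAMES, observed = obs,
                     p = pr, stringsAsFactors = FALSE)
  pca <- NULL
  sdev <- apply(table@stats, 2, sd)
  if (all(is.finite(sdev)) && sum(sdev > 0) >= 2) {
    pc <- prcomp(table@stats[, sdev > 0, drop = FALSE], scale. = TRUE)
    proj <- function(m) predict(pc, m[, sdev > 0, drop = FALSE])[, 1:2,
                                                                 drop = FALSE]
    pca <- list(prior = proj(table@stats), predictive = proj(pred),
                observed = proj(matrix(obs, 1,
                                       dimnames = list(NULL, names(obs)))))
  }
  list(rank = rank, pca = pca, pred = pred)
}
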