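#' @include AllClasses.R sumstats.R
NULL

#' Polymorphism and divergence counts for HKA tests
#'
#' From a gap-excluded alignment with an outgroup: the number of
#' comparable sites L (plain A/C/G/T in every ingroup row and the
#' outgroup), the number of segregating sites S among those, and the
#' number of fixed differences D (ingroup monomorphic for an allele
#' differing from the outgroup).
#'
#' @param alignment a gap-excluded \linkS4class{LocusAlignment} with an
#'   outgroup.
#' @param siteClass optionally restrict to columns annotated "exon" or
#'   "intron" (requires the alignment's siteClass).
#' @return data.frame row with locus, n, S, D, L.
#' @export
hkaCounts <- function(alignment, siteClass = NULL) {
  stopifnot(is(alignment, "LocusAlignment"))
  if (!length(alignment@outgroup)) stop("HKA needs an outgroup")
  s <- alignment@seqs
  og <- alignment@outgroup
  keep <- og %in% .NUC &
    colSums(!(s == "A" | s == "C" | s == "G" | s == "T")) == 0
  if (!is.null(siteClass)) {
    if (!length(alignment@siteClass))
      stop("alignment has no site annotation")
    keep <- keep & alignment@siteClass == siteClass
  }
  if (!any(keep)) stop("no comparable sites")
  s <- s[, keep, drop = FALSE]
  og <- og[keep]
  nal <- apply(s, 2, function(col) length(unique(col)))
  seg <- nal > 1
  fixedDiff <- !seg & s[1, ] != og
  data.frame(locus = alignment@name, n = nrow(s), S = sum(seg),
             D = sum(fixedDiff), L = sum(keep), stringsAsFactors = FALSE)
}

.an <- function(n) sum(1 / seq_len(n - 1))
.bn <- function(n) sum(1 / seq_len(n - 1)^2)

# Moment estimation of (theta_i * L_i) and T from S and D counts under
# neutrality: S_i + D_i = lambda_i (a_i + T + 1) per locus and
# sum(S_i) = sum(lambda_i a_i). Single outgroup sequence, species-size
# ratio fixed at 1 so E[D_i] = lambda_i (T + 1).
.hkaMoments <- function(S, D, a) {
  f <- function(T) sum(S) - sum(a * (S + D) / (a + T + 1))
  lo <- -0.999
  hi <- 10
  while (f(hi) < 0 && hi < 1e6) hi <- hi * 10
  T <- if (f(lo) >= 0) lo else uniroot(f, c(lo, hi), tol = 1e-12)$root
  lambda <- (S + D) / (a + T + 1)
  list(T = T, lambda = lambda)
}

#' Classic pairwise HKA test
#'
#' Compares the polymorphism-to-divergence ratio of two loci. Parameters
#' are estimated by the standard moment equations; the statistic is
#' \eqn{\chi^2 = \sum (obs - exp)^2 / Var} over the four observed counts,
#' with \eqn{Var(S) = E[S] + (\theta L)^2 b_n} and
#' \eqn{Var(D) = E[D] + (\theta L)^2}, referred to a chi-square with 1
#' degree of freedom.
#'
#' @param countsA,countsB rows from \code{\link{hkaCounts}} (or any list
#'   with n, S, D, L).
#' @return list with chisq, p, T (divergence estimate, coalescent units)
#'   and thetaL (per-locus theta estimates).
#' @export
pairwiseHKA <- function(countsA, countsB) {
  S <- c(countsA$S, countsB$S)
  D <- c(countsA$D, countsB$D)
  n <- c(countsA$n, countsB$n)
  if (any(n < 2)) stop("need n >= 2 at both loci")
  a <- vapply(n, .an, 0)
  b <- vapply(n, .bn, 0)
  mom <- .hkaMoments(S, D, a)
  ES <- mom$lambda * a
  ED <- mom$lambda * (mom$T + 1)
  if (any(ES <= 0) || any(ED <= 0)) stop("zero expected counts")
  varS <- ES + mom$lambda^2 * b
  varD <- ED + mom$lambda^2
  chisq <- sum((S - ES)^2 / varS) + sum((D - ED)^2 / varD)
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE),
       T = mom$T, thetaL = mom$lambda)
}

# Profile log-likelihood of the ML-HKA model: S_i ~ Pois(k_i lambda_i a_i),
# D_i ~ Pois(lambda_i (T + (1 + k_i)/2)); lambda_i maximized analytically.
.mlhkaLogLik <- function(T, k, S, D, a) {
  m <- T + (1 + k) / 2
  lambda <- (S + D) / (k * a + m)
  ll <- 0
  for (i in seq_along(S)) {
    mu1 <- k[i] * lambda[i] * a[i]
    mu2 <- lambda[i] * m[i]
    ll <- ll + (if (S[i] > 0) S[i] * log(mu1) else 0) - mu1 +
      (if (D[i] > 0) D[i] * log(mu2) else 0) - mu2
  }
  ll
}

#' Maximum-likelihood HKA test
#'
#' Poisson likelihood over loci for the polymorphism and divergence
#' counts, with a per-locus selection parameter k multiplying the
#' population-scaled mutation rate in the polymorphism expectation and
#' the ingroup half of the divergence expectation
#' (\eqn{E[D_i] = \theta_i L_i (T + (1+k_i)/2)}). The neutral model fixes
#' every k at 1; the likelihood-ratio statistic has as many degrees of
#' freedom as selected loci. Per-locus theta and the divergence time T
#' are profiled out analytically; T and the selected k are maximized
#' numerically from multiple starts (the neutral optimum is always one
#' start, so LRT >= 0 by construction).
#'
#' @param counts data.frame from rbinding \code{\link{hkaCounts}} rows.
#' @param selected locus names granted a free selection parameter.
#' @param nStarts random optimizer restarts.
#' @return an \linkS4class{MLHKAFit}.
#' @export
mlHKA <- function(counts, selected = character(0), nStarts = 5L) {
  if (nrow(counts) < 2) stop("need at least 2 loci")
  if (!all(selected %in% counts$locus))
    stop("selected loci must appear in counts")
  S <- counts$S
  D <- counts$D
  a <- vapply(counts$n, .an, 0)
  nloc <- nrow(counts)
  selIdx <- match(selected, counts$locus)
  # neutral fit: 1-D profile maximization over log T
  nll0 <- function(lt) -.mlhkaLogLik(exp(lt), rep(1, nloc), S, D, a)
  opt0 <- optimize(nll0, c(-12, 12), tol = 1e-10)
  T0 <- exp(opt0$minimum)
  ll0 <- -opt0$objective
  if (!length(selected)) {
    m <- T0 + 1
    lambda <- (S + D) / (a + m)
    return(new("MLHKAFit", theta = setNames(lambda / counts$L, counts$locus),
               Tdiv = T0, k = setNames(rep(1, nloc), counts$locus),
               selected = character(0), logLik = ll0, logLik0 = ll0,
               lrt = 0, df = 0L, converged = TRUE))
  }
  nll <- function(x) {
    k <- rep(1, nloc)
    k[selIdx] <- exp(x[-1])
    -.mlhkaLogLik(exp(x[1]), k, S, D, a)
  }
  starts <- list(c(log(T0), rep(0, length(selIdx))))
  # crude data-driven start: polymorphism/divergence ratio vs the rest
  ratio <- (S[selIdx] + 0.5) / (a[selIdx] * ((D[selIdx] + 0.5) / (T0 + 1)))
  starts[[2]] <- c(log(T0), log(pmin(pmax(ratio, 1e-2), 1e2)))
  for (s in seq_len(max(0, nStarts - 2)))
    starts[[2 + s]] <- c(log(T0) + rnorm(1, 0, 0.5),
                         rnorm(length(selIdx), 0, 1))
  best <- NULL
  conv <- FALSE
  for (x0 in starts) {
    fit <- tryCatch(optim(x0, nll, method = "L-BFGS-B",
                          lower = rep(c(-12, -7), c(1, length(selIdx))),
                          upper = rep(c(12, 7), c(1, length(selIdx))),
                          control = list(factr = 1e4, maxit = 500)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      conv <- fit$convergence == 0
    }
  }
  if (is.null(best)) stop("ML-HKA optimization failed from every start")
  ll1 <- max(-best$value, ll0)
  k <- setNames(rep(1, nloc), counts$locus)
  k[selIdx] <- exp(best$par[-1])
  T1 <- exp(best$par[1])
  m <- T1 + (1 + k) / 2
  lambda <- (S + D) / (k * a + m)
  new("MLHKAFit", theta = setNames(lambda / counts$L, counts$locus),
      Tdiv = T1, k = k, selected = selected, logLik = ll1, logLik0 = ll0,
      lrt = max(0, 2 * (ll1 - ll0)), df = length(selected),
      converged = conv)
}
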