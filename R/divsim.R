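#' @include AllClasses.R
NULL

#' Construct the divergence-model parameter vector
#'
#' @param NW,NE,NAnc effective sizes (diploid individuals) of the Western,
#'   Eastern and ancestral populations.
#' @param Td divergence time in generations.
#' @param muSeq sequence mutation rate (substitutions/site/generation).
#' @param muSSR microsatellite mutation rate (mutations/locus/generation).
#' @param pSSR geometric step parameter of the generalized stepwise model.
#' @return a \linkS4class{DivergenceModelParams}.
#' @export
divergenceModelParams <- function(NW, NE, NAnc, Td, muSeq, muSSR = 5e-4,
                                  pSSR = 0.22) {
  new("DivergenceModelParams", NW = NW, NE = NE, NAnc = NAnc, Td = Td,
      muSeq = muSeq, muSSR = muSSR, pSSR = pSSR)
}

#' Per-locus simulation configuration
#'
#' @param nW,nE samples per population (haploid sequences or diploid
#'   individuals depending on the locus type).
#' @param L locus length in sites (sequence loci).
#' @param mode "infinite_sites" or "jukes_cantor".
#' @param outTime outgroup divergence time in generations (0 = none; only
#'   honoured in jukes_cantor mode).
#' @return a validated configuration list.
#' @export
simConfig <- function(nW, nE, L = 1000L, mode = c("infinite_sites",
                                                  "jukes_cantor"),
                      outTime = 0) {
  mode <- match.arg(mode)
  if (nW + nE < 2) stop("need at least 2 samples in total")
  if (L < 1) stop("L must be >= 1")
  list(nW = as.integer(nW), nE = as.integer(nE), L = as.integer(L),
       mode = mode, outTime = outTime)
}

# fast paths -----------------------------------------------------------

# One sequence is sampled per diploid individual, so a population of N
# individuals holds 2N exchangeable gene copies; the same 2N applies to the
# diploid microsatellites (2 copies per individual). This is the single
# scaling convention used everywhere.
.geneCopies <- function(params) {
  c(W = 2 * params@NW, E = 2 * params@NE, A = 2 * params@NAnc)
}

.simSeqInf <- function(params, nW, nE, L) {
  g <- .geneCopies(params)
  .cpp_sim_seq_infsites(nW, nE, g["W"], g["E"], g["A"], params@Td,
                        params@muSeq * L)
}

.simSeqJC <- function(params, nW, nE, L, outTime = 0) {
  g <- .geneCopies(params)
  .cpp_sim_seq_jc(nW, nE, g["W"], g["E"], g["A"], params@Td, params@muSeq,
                  L, outTime)
}

.simSSRmat <- function(params, nIndW, nIndE, alleleRange) {
  g <- .geneCopies(params)
  founder <- as.integer(round(mean(alleleRange)))
  .cpp_sim_ssr(nIndW, nIndE, g["W"], g["E"], g["A"], params@Td,
               params@muSSR, params@pSSR, alleleRange[1], alleleRange[2],
               founder)
}

.simIds <- function(nW, nE) c(sprintf("W%02d", seq_len(nW)),
                              sprintf("E%02d", seq_len(nE)))

# public simulators ----------------------------------------------------

#' Simulate one sequence locus under the divergence model
#'
#' The genealogy is a standard coalescent within each population back to
#' \code{Td}, after which lineages coalesce in the ancestral population.
#' Mutations fall on branches as a Poisson process with rate
#' \code{muSeq * L} per generation. In \code{infinite_sites} mode every
#' mutation occupies a fresh column and the true derived states are known,
#' so the result is an \linkS4class{OrientedAlignment}. In
#' \code{jukes_cantor} mode a random ancestral sequence evolves under the
#' JC substitution matrix (recurrent hits possible) and the result is a
#' \linkS4class{LocusAlignment}, with an outgroup row when
#' \code{config$outTime > 0}.
#'
#' @param params a \linkS4class{DivergenceModelParams}.
#' @param config a \code{\link{simConfig}}.
#' @param name locus name for the returned object.
#' @return an \linkS4class{OrientedAlignment} (infinite_sites) or a
#'   \linkS4class{LocusAlignment} (jukes_cantor).
#' @export
simulateSequenceLocus <- function(params, config, name = "simlocus") {
  stopifnot(is(params, "DivergenceModelParams"))
  validObject(params)
  if (config$mode == "infinite_sites") {
    mat <- .simSeqInf(params, config$nW, config$nE, config$L)
    i <- rowSums(mat)
    mat <- mat[i >= 1 & i <= ncol(mat) - 1, , drop = FALSE]
    new("OrientedAlignment", name = name, mat = mat,
        sampleIds = .simIds(config$nW, config$nE), nUnorientable = 0L)
  } else {
    sim <- .simSeqJC(params, config$nW, config$nE, config$L,
                     config$outTime)
    .jcToAlignment(sim, config, name)
  }
}

# Expand a sparse JC simulation (mutated columns only) to a full character
# alignment over a random constant background.
.jcToAlignment <- function(sim, config, name) {
  n <- config$nW + config$nE
  og <- config$outTime > 0
  back <- sample(.NUC, config$L, replace = TRUE)
  seqs <- matrix(rep(back, each = n), nrow = n)
  ogseq <- back
  if (length(sim$pos)) {
    st <- matrix(.NUC[sim$states + 1L], nrow = length(sim$pos))
    seqs[, sim$pos] <- t(st[, seq_len(n), drop = FALSE])
    if (og) ogseq[sim$pos] <- st[, n + 1L]
  }
  rownames(seqs) <- .simIds(config$nW, config$nE)
  new("LocusAlignment", name = name, seqs = seqs,
      outgroup = if (og) ogseq else character(0))
}

#' Simulate one diploid microsatellite locus
#'
#' Generalized stepwise mutation on the two-population coalescent: step
#' sizes are 1 + Geometric(1 - pSSR), direction equiprobable, and alleles
#' are reflected into the observed allele range (the simulated data reuse
#' the motif size and allele range of the matching observed locus).
#'
#' @param params a \linkS4class{DivergenceModelParams}.
#' @param config a \code{\link{simConfig}} (nW/nE are diploid individuals).
#' @param motif repeat motif size in bp.
#' @param alleleRange length-2 (min, max) repeat count.
#' @param name locus name.
#' @return a \linkS4class{MicrosatLocus}.
#' @export
simulateMicrosatLocus <- function(params, config, motif = 2L,
                                  alleleRange = c(10L, 40L),
                                  name = "simssr") {
  stopifnot(is(params, "DivergenceModelParams"))
  if (diff(alleleRange) < 1) stop("allele range width must be >= 2 states")
  g <- .simSSRmat(params, config$nW, config$nE, alleleRange)
  rownames(g) <- .simIds(config$nW, config$nE)
  MicrosatLocus(name, g, motif = motif, alleleRange = alleleRange)
}

#' Flip derived/ancestral assignments at a given misorientation rate
#'
#' Each polymorphic site's derived state is independently exchanged with
#' the ancestral one with probability m, emulating orientation errors
#' caused by mutation on the outgroup lineage. Used when building the
#' simulated null distributions for H.
#'
#' @param oriented an \linkS4class{OrientedAlignment}.
#' @param m misorientation probability in [0, 1].
#' @return an \linkS4class{OrientedAlignment} with flipped sites.
#' @export
applyMisorientation <- function(oriented, m) {
  stopifnot(is(oriented, "OrientedAlignment"), m >= 0, m <= 1)
  mat <- oriented@mat
  if (nrow(mat) && m > 0) {
    flip <- runif(nrow(mat)) < m
    mat[flip, ] <- 1L - mat[flip, , drop = FALSE]
  }
  new("OrientedAlignment", name = oriented@name, mat = mat,
      sampleIds = oriented@sampleIds,
      nUnorientable = oriented@nUnorientable)
}
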