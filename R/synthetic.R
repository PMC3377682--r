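#' @include AllClasses.R divsim.R io.R
NULL

.CANDIDATE_GENES <- c("IPI", "PDS", "CRTISO", "LCYB1", "LCYE", "CHXE",
                      "ZEP")

# Default locus registry of the emulated study: 7 candidate genes with
# pathway positions (PDS length matches the 911 comparable sites of the
# emulated locus), 3 anonymous sequence control loci and 17 dinucleotide
# microsatellites.
.defaultRegistry <- function() {
  cand <- data.frame(
    name = .CANDIDATE_GENES, kind = "candidate",
    length = c(600, 911, 1000, 700, 900, 800, 700),
    position = unname(.DEFAULT_POSITIONS[.CANDIDATE_GENES]),
    motif = NA_integer_, alleleMin = NA_integer_,
    alleleMax = NA_integer_, stringsAsFactors = FALSE)
  ctrl <- data.frame(
    name = c("B1D", "JW3D", "SB4A"), kind = "control_seq",
    length = c(550, 600, 650), position = NA_real_, motif = NA_integer_,
    alleleMin = NA_integer_, alleleMax = NA_integer_,
    stringsAsFactors = FALSE)
  ssr <- data.frame(
    name = sprintf("SSR%02d", 1:17), kind = "control_ssr", length = 2,
    position = NA_real_, motif = 2L,
    alleleMin = rep(c(8L, 10L, 12L), length.out = 17),
    alleleMax = rep(c(30L, 36L, 44L), length.out = 17),
    stringsAsFactors = FALSE)
  rbind(cand, ctrl, ssr)
}

# 46 cultivars: 24 Western / 22 Eastern, five root-color groups.
.defaultSamples <- function() {
  west <- data.frame(
    id = sprintf("W%02d", 1:24), group = "West",
    color = rep(c("white", "yellow", "orange", "red", "purple"),
                c(4, 4, 12, 1, 3)), stringsAsFactors = FALSE)
  east <- data.frame(
    id = sprintf("E%02d", 1:22), group = "East",
    color = rep(c("white", "yellow", "orange", "red", "purple"),
                c(2, 6, 6, 5, 3)), stringsAsFactors = FALSE)
  rbind(west, east)
}

#' Define a synthetic study scenario
#'
#' The default scenario emulates the structure of a crop resequencing
#' study: 46 individuals in two geographic populations (24/22) with five
#' root-color groups, 7 candidate genes, 3 sequence control loci, 17
#' microsatellites and a deep outgroup. Default true parameters:
#' N = 2e4 for all three populations, Td = 500 generations,
#' mu_seq = 5e-8, mu_SSR = 5e-4, P_SSR = 0.22. Default regimes plant a
#' sweep at PDS (c = 6) and balancing selection at CRTISO, LCYB1 and
#' LCYE (LCYB1's allelic classes correlated with root color), all other
#' candidates neutral.
#'
#' @param seed mandatory integer seed.
#' @param params true \linkS4class{DivergenceModelParams}.
#' @param regimes named regime vector over candidate genes.
#' @param outTime outgroup divergence in generations (default 2.4e6,
#'   about 0.24 substitutions/site at the default mutation rate).
#' @param sweepC coalescent-time contraction of the sweep regime.
#' @param balAge balanced-split age in units of 2*NAnc generations.
#' @param colorAssoc class-color association probability at
#'   color-associated balanced genes.
#' @return a \linkS4class{SyntheticScenario}.
#' @export
syntheticScenario <- function(seed,
                              params = divergenceModelParams(
                                NW = 2e4, NE = 2e4, NAnc = 2e4, Td = 500,
                                muSeq = 5e-8, muSSR = 5e-4, pSSR = 0.22),
                              regimes = c(IPI = "neutral", PDS = "sweep",
                                          CRTISO = "balancing",
                                          LCYB1 = "balancing",
                                          LCYE = "balancing",
                                          CHXE = "neutral",
                                          ZEP = "neutral"),
                              outTime = 2.4e6, sweepC = 6, balAge = 12,
                              colorAssoc = 0.8) {
  new("SyntheticScenario", params = params, regimes = regimes,
      samples = .defaultSamples(), registry = .defaultRegistry(),
      outTime = outTime, sweepC = sweepC, balAge = balAge,
      colorAssoc = colorAssoc, seed = as.integer(seed))
}

# -- R-side genealogy machinery (regimes are composed here) ------------

# 1-based genealogy list: parent (0 = none), time, root, tips 1..n.
.rGenealogy <- function(nW, nE, gW, gE, gA, Td) {
  g <- .cpp_sim_genealogy(nW, nE, gW, gE, gA, Td)
  list(parent = g$parent + 1L, time = g$time, root = g$root + 1L,
       n = g$n)
}

# Graft the genealogies of two allelic classes onto a common ancestor at
# ageGen generations; members1/members2 give the global tip index of each
# class member (class trees are simulated on their members only).
.balancedGenealogy <- function(nW, nE, gW, gE, gA, Td, members1, ageGen) {
  n <- nW + nE
  members2 <- setdiff(seq_len(n), members1)
  grp <- rep(c("West", "East"), c(nW, nE))
  simClass <- function(members) {
    if (length(members) == 1)
      return(list(parent = 0L, time = 0, root = 1L, n = 1L,
                  map = members))
    mW <- members[grp[members] == "West"]
    mE <- members[grp[members] == "East"]
    g <- .rGenealogy(length(mW), length(mE), gW, gE, gA, Td)
    list(parent = g$parent, time = g$time, root = g$root, n = g$n,
         map = c(mW, mE))
  }
  c1 <- simClass(members1)
  c2 <- simClass(members2)
  # global node ids: tips 1..n, then class-1 internals, class-2 internals,
  # then the joining ancestor
  off1 <- n
  off2 <- n + max(0L, c1$n - 1L)
  nn <- n + max(0L, c1$n - 1L) + max(0L, c2$n - 1L) + 1L
  top <- nn
  parent <- integer(nn)
  time <- numeric(nn)
  relabel <- function(cl, off) {
    vapply(seq_along(cl$parent), function(v) {
      if (v <= cl$n) cl$map[v] else off + (v - cl$n)
    }, 0L)
  }
  lab1 <- relabel(c1, off1)
  lab2 <- relabel(c2, off2)
  for (v in seq_along(c1$parent)) {
    gv <- lab1[v]
    parent[gv] <- if (c1$parent[v] == 0L) 0L else lab1[c1$parent[v]]
    time[gv] <- c1$time[v]
  }
  for (v in seq_along(c2$parent)) {
    gv <- lab2[v]
    parent[gv] <- if (c2$parent[v] == 0L) 0L else lab2[c2$parent[v]]
    time[gv] <- c2$time[v]
  }
  age <- max(ageGen, 1.05 * max(time), Td * 1.05)
  r1 <- lab1[c1$root]
  r2 <- lab2[c2$root]
  parent[r1] <- top
  parent[r2] <- top
  parent[top] <- 0L
  time[top] <- age
  list(parent = parent, time = time, root = top, n = n)
}

# Drop Jukes-Cantor mutations on an arbitrary genealogy and expand to a
# full character alignment; an outgroup lineage is anchored above the
# root at outTime generations when outTime > 0. Returns the sequence
# matrix (tips x L) plus the outgroup character vector (or NULL).
.dropJC <- function(gen, mu, L, outTime = 0) {
  parent <- gen$parent
  time <- gen$time
  n <- gen$n
  og <- outTime > 0
  if (og) {
    tEff <- max(outTime, time[gen$root] * 1.0000001 + 1e-9)
    tipOut <- length(parent) + 1L
    top <- length(parent) + 2L
    parent <- c(parent, top, 0L)
    parent[gen$root] <- top
    time <- c(time, 0, tEff)
    root <- top
  } else root <- gen$root
  nn <- length(parent)
  blen <- numeric(nn)
  hasPar <- parent > 0L
  blen[hasPar] <- time[parent[hasPar]] - time[hasPar]
  tot <- sum(blen)
  M <- rpois(1, mu * L * tot)
  back <- sample(.NUC, L, replace = TRUE)
  seqs <- matrix(rep(back, each = n), nrow = n)
  ogseq <- if (og) back else NULL
  if (M > 0) {
    br <- sample.int(nn, M, replace = TRUE, prob = blen)
    pos <- sample.int(L, M, replace = TRUE)
    tmut <- time[br] + runif(M) * blen[br]
    children <- split(seq_len(nn), parent)
    children <- children[names(children) != "0"]
    kids <- vector("list", nn)
    kids[as.integer(names(children))] <- children
    for (p in unique(pos)) {
      sel <- which(pos == p)
      byBranch <- split(tmut[sel], br[sel])
      state <- integer(nn)
      state[root] <- sample.int(4, 1)
      stack <- root
      while (length(stack)) {
        v <- stack[length(stack)]
        stack <- stack[-length(stack)]
        if (v != root) {
          b <- state[parent[v]]
          muts <- byBranch[[as.character(v)]]
          if (!is.null(muts))
            for (k in seq_len(length(muts)))
              b <- (b - 1L + sample.int(3, 1)) %% 4L + 1L
          state[v] <- b
        }
        if (!is.null(kids[[v]])) stack <- c(stack, kids[[v]])
      }
      seqs[, p] <- .NUC[state[seq_len(n)]]
      if (og) ogseq[p] <- .NUC[state[tipOut]]
    }
  }
  list(seqs = seqs, outgroup = ogseq)
}

#' Generate one candidate gene under a selection regime
#'
#' \code{neutral}: a plain divergence-model genealogy. \code{sweep}:
#' within-species coalescent times contracted by the factor
#' \code{sweepC} (all three population sizes scaled by 1/c), reducing
#' diversity while the outgroup divergence is untouched. \code{balancing}:
#' the sample is split into two allelic classes whose genealogies join
#' only at \code{balAge * 2 * NAnc} generations, creating the excess of
#' intermediate-frequency variants that balancing selection maintains;
#' at color-associated genes class membership is correlated with the
#' focal root color.
#'
#' @param scenario a \linkS4class{SyntheticScenario}.
#' @param gene candidate gene name.
#' @param regime overrides the scenario's regime for this gene.
#' @param focalColor color correlated with the balanced classes.
#' @return a \linkS4class{LocusAlignment} with an outgroup row.
#' @export
generateCandidateGene <- function(scenario, gene, regime = NULL,
                                  focalColor = "orange") {
  reg <- scenario@registry
  i <- match(gene, reg$name)
  if (is.na(i)) stop(sprintf("gene '%s' not in registry", gene))
  if (reg$kind[i] != "candidate")
    stop(sprintf("'%s' is not a candidate gene", gene))
  if (is.null(regime))
    regime <- if (gene %in% names(scenario@regimes))
      scenario@regimes[[gene]] else "neutral"
  if (!regime %in% c("neutral", "sweep", "balancing"))
    stop(sprintf("unknown regime '%s'", regime))
  p <- scenario@params
  sm <- scenario@samples
  nW <- sum(sm$group == "West")
  nE <- sum(sm$group == "East")
  L <- reg$length[i]
  gc <- .geneCopies(p)
  gen <- switch(regime,
    neutral = .rGenealogy(nW, nE, gc["W"], gc["E"], gc["A"], p@Td),
    sweep = .rGenealogy(nW, nE, gc["W"] / scenario@sweepC,
                        gc["E"] / scenario@sweepC,
                        gc["A"] / scenario@sweepC, p@Td),
    balancing = {
      pr <- ifelse(sm$color == focalColor, scenario@colorAssoc, 0.5)
      cls1 <- which(runif(nrow(sm)) < pr)
      if (length(cls1) < 1) cls1 <- 1L
      if (length(cls1) >= nrow(sm)) cls1 <- cls1[-length(cls1)]
      .balancedGenealogy(nW, nE, gc["W"], gc["E"], gc["A"], p@Td, cls1,
                         ageGen = scenario@balAge * 2 * p@NAnc)
    })
  sim <- .dropJC(gen, p@muSeq, L, scenario@outTime)
  rownames(sim$seqs) <- sm$id
  new("LocusAlignment", name = gene, seqs = sim$seqs,
      outgroup = sim$outgroup)
}

#' Generate the control loci of a scenario
#'
#' Simulates the 3 sequence control loci (with outgroup) and the 17
#' microsatellites from the scenario's true parameters and wraps them
#' with the sample sheet into a \linkS4class{StudyBundle} whose registry
#' contains only control loci.
#'
#' @param scenario a \linkS4class{SyntheticScenario}.
#' @param seed optional seed (default: the scenario's).
#' @return a \linkS4class{StudyBundle}.
#' @export
generateControlLoci <- function(scenario, seed = scenario@seed) {
  set.seed(seed)
  p <- scenario@params
  sm <- scenario@samples
  reg <- scenario@registry
  nW <- sum(sm$group == "West")
  nE <- sum(sm$group == "East")
  ctrl <- reg[reg$kind == "control_seq", , drop = FALSE]
  seqLoci <- list()
  for (i in seq_len(nrow(ctrl))) {
    gen <- .rGenealogy(nW, nE, 2 * p@NW, 2 * p@NE, 2 * p@NAnc, p@Td)
    sim <- .dropJC(gen, p@muSeq, ctrl$length[i], scenario@outTime)
    rownames(sim$seqs) <- sm$id
    seqLoci[[ctrl$name[i]]] <- new("LocusAlignment", name = ctrl$name[i],
                                   seqs = sim$seqs,
                                   outgroup = sim$outgroup)
  }
  ssrReg <- reg[reg$kind == "control_ssr", , drop = FALSE]
  ssrLoci <- list()
  for (i in seq_len(nrow(ssrReg))) {
    g <- .simSSRmat(p, nW, nE, c(ssrReg$alleleMin[i], ssrReg$alleleMax[i]))
    rownames(g) <- sm$id
    ssrLoci[[ssrReg$name[i]]] <- MicrosatLocus(
      ssrReg$name[i], g, motif = ssrReg$motif[i],
      alleleRange = c(ssrReg$alleleMin[i], ssrReg$alleleMax[i]))
  }
  bundle <- new("StudyBundle", seqLoci = seqLoci, ssrLoci = ssrLoci,
                samples = sm,
                registry = reg[reg$kind != "candidate", , drop = FALSE])
  validObject(bundle)
  bundle
}

#' Generate a complete synthetic study bundle
#'
#' Control loci plus every candidate gene under its scenario regime, with
#' the full registry.
#'
#' @param scenario a \linkS4class{SyntheticScenario}.
#' @return a \linkS4class{StudyBundle}.
#' @export
generateStudyBundle <- function(scenario) {
  bundle <- generateControlLoci(scenario)
  reg <- scenario@registry
  genes <- reg$name[reg$kind == "candidate"]
  cand <- list()
  for (j in seq_along(genes)) {
    set.seed((scenario@seed + 7919L * j) %% .Machine$integer.max)
    cand[[genes[j]]] <- generateCandidateGene(scenario, genes[j])
  }
  new("StudyBundle", seqLoci = c(cand, bundle@seqLoci),
      ssrLoci = bundle@ssrLoci, samples = bundle@samples, registry = reg)
}

#' Generate ortholog codon alignments with a dN/dS gradient
#'
#' Star-phylogeny codon evolution for a panel of taxa: single-nucleotide
#' substitutions are proposed per branch at a constant rate, changes
#' creating stop codons are rejected, synonymous changes are always
#' accepted and nonsynonymous changes are accepted with probability
#' omega. The default omegas give each gene the purifying-selection level
#' typical of its pathway position.
#'
#' @param genes gene names.
#' @param omegas named acceptance probabilities for nonsynonymous changes.
#' @param nTaxa number of taxa.
#' @param nCodons codons per gene.
#' @param branchRate expected proposed substitutions per nucleotide site
#'   per branch.
#' @return named list of \linkS4class{CodonAlignment}s.
#' @export
generateOrthologAlignments <- function(genes = .CANDIDATE_GENES,
                                       omegas = c(IPI = 0.052,
                                                  PDS = 0.067,
                                                  CRTISO = 0.062,
                                                  LCYB1 = 0.040,
                                                  LCYE = 0.088,
                                                  CHXE = 0.061,
                                                  ZEP = 0.091),
                                       nTaxa = 7, nCodons = 250,
                                       branchRate = 0.45) {
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   names(which(Biostrings::GENETIC_CODE == "*")))
  out <- list()
  for (g in genes) {
    omega <- if (g %in% names(omegas)) omegas[[g]] else 0.1
    anc <- sample(sense, nCodons, replace = TRUE)
    taxa <- sprintf("taxon%02d", seq_len(nTaxa))
    seqs <- setNames(character(nTaxa), taxa)
    for (t in seq_len(nTaxa)) {
      cod <- anc
      M <- rpois(1, branchRate * 3 * nCodons)
      for (k in seq_len(M)) {
        ci <- sample.int(nCodons, 1)
        pos <- sample.int(3, 1)
        cur <- cod[ci]
        nt <- sample(setdiff(.NUC, substr(cur, pos, pos)), 1)
        alt <- cur
        substr(alt, pos, pos) <- nt
        if (.isStop(alt)) next
        if (.translate1(alt) == .translate1(cur) || runif(1) < omega)
          cod[ci] <- alt
      }
      seqs[t] <- paste(cod, collapse = "")
    }
    out[[g]] <- codonAlignment(g, seqs)
  }
  out
}
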