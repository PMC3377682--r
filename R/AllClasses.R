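#' @useDynLib divergeScan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats median mad sd var rnorm runif rpois rbinom rexp qnorm
#'   pnorm dnorm pchisq optim optimize cor.test kruskal.test wilcox.test
#'   ks.test prcomp quantile weighted.mean rgeom setNames complete.cases
#' @importFrom utils read.delim write.table head
NULL

.GROUPS <- c("West", "East")
.COLORS <- c("white", "yellow", "orange", "red", "purple")
.NUC <- c("A", "C", "G", "T")
.ALPHABET <- c(.NUC, "-", "N")

#' Per-locus multiple alignment of haploid sequences
#'
#' Holds one gene's alignment: one row per sampled individual (haploid
#' sampling, one sequence each), an optional outgroup row kept separately,
#' and an optional exon/intron annotation per column. Entries are single
#' upper-case characters over A, C, G, T, -, N.
#'
#' @slot name locus name.
#' @slot seqs character matrix, samples x sites, rownames are sample ids.
#' @slot outgroup character vector of per-site outgroup states (length
#'   \code{ncol(seqs)}) or \code{character(0)} when no outgroup is available.
#' @slot siteClass optional per-column annotation ("exon"/"intron"),
#'   \code{character(0)} when absent.
#' @export
setClass("LocusAlignment",
  slots = c(name = "character", seqs = "matrix", outgroup = "character",
            siteClass = "character"),
  prototype = prototype(name = NA_character_, outgroup = character(0),
                        siteClass = character(0)))

setValidity("LocusAlignment", function(object) {
  s <- object@seqs
  if (!is.character(s)) return("seqs must be a character matrix")
  if (is.null(rownames(s))) return("seqs must have sample ids as rownames")
  if (anyDuplicated(rownames(s))) return("duplicate sequence labels")
  if (!all(s %in% .ALPHABET))
    return(sprintf("invalid character(s) in alignment '%s'", object@name))
  if (length(object@outgroup)) {
    if (length(object@outgroup) != ncol(s))
      return("outgroup length differs from alignment length")
    if (!all(object@outgroup %in% .ALPHABET))
      return("invalid character(s) in outgroup")
  }
  if (length(object@siteClass) && length(object@siteClass) != ncol(s))
    return("siteClass length differs from alignment length")
  TRUE
})

#' Diploid microsatellite locus
#'
#' @slot name locus name.
#' @slot motif repeat motif size in bp.
#' @slot alleleRange integer of length 2, minimum and maximum repeat count.
#' @slot genotypes integer matrix, individuals x 2 (two alleles as repeat
#'   counts), rownames are sample ids.
#' @export
setClass("MicrosatLocus",
  slots = c(name = "character", motif = "integer", alleleRange = "integer",
            genotypes = "matrix"))

setValidity("MicrosatLocus", function(object) {
  g <- object@genotypes
  if (ncol(g) != 2) return("genotypes must have two allele columns (diploid)")
  if (is.null(rownames(g))) return("genotypes must have sample ids as rownames")
  if (length(object@alleleRange) != 2 || diff(object@alleleRange) < 0)
    return("alleleRange must be (min, max) with min <= max")
  ok <- g >= object@alleleRange[1] & g <= object@alleleRange[2]
  if (!all(ok | is.na(g)))
    return(sprintf("allele out of range at locus '%s'", object@name))
  TRUE
})

#' All observed inputs of a study in one validated container
#'
#' @slot seqLoci named list of \linkS4class{LocusAlignment} (candidate genes
#'   and sequence control loci).
#' @slot ssrLoci named list of \linkS4class{MicrosatLocus} (control loci).
#' @slot samples data.frame with columns id, group (West/East) and color
#'   (white/yellow/orange/red/purple).
#' @slot registry data.frame with columns name, kind (candidate, control_seq,
#'   control_ssr), length and position (pathway position, candidates only).
#' @export
setClass("StudyBundle",
  slots = c(seqLoci = "list", ssrLoci = "list", samples = "data.frame",
            registry = "data.frame"))

setValidity("StudyBundle", function(object) {
  sm <- object@samples
  need <- c("id", "group", "color")
  if (!all(need %in% names(sm)))
    return("samples needs columns id, group, color")
  if (anyDuplicated(sm$id)) return("duplicate sample ids")
  bad <- !sm$group %in% .GROUPS
  if (any(bad))
    return(sprintf("unknown group '%s' for sample '%s'",
                   sm$group[bad][1], sm$id[bad][1]))
  bad <- !sm$color %in% .COLORS
  if (any(bad))
    return(sprintf("unknown color '%s' for sample '%s'",
                   sm$color[bad][1], sm$id[bad][1]))
  reg <- object@registry
  if (!all(c("name", "kind", "length") %in% names(reg)))
    return("registry needs columns name, kind, length")
  if (!all(reg$kind %in% c("candidate", "control_seq", "control_ssr")))
    return("registry kind must be candidate/control_seq/control_ssr")
  if (any(reg$length <= 0)) return("registry lengths must be positive")
  cand <- reg$kind == "candidate"
  if (any(cand) && (!"position" %in% names(reg) ||
                    anyNA(reg$position[cand])))
    return("candidate loci need a pathway position index")
  for (al in object@seqLoci) {
    unknown <- setdiff(rownames(al@seqs), sm$id)
    if (length(unknown))
      return(sprintf("sequence label '%s' at locus '%s' matches no sample",
                     unknown[1], al@name))
  }
  for (ms in object@ssrLoci) {
    unknown <- setdiff(rownames(ms@genotypes), sm$id)
    if (length(unknown))
      return(sprintf("genotype id '%s' at locus '%s' matches no sample",
                     unknown[1], ms@name))
  }
  TRUE
})

#' Outgroup-oriented polymorphic sites
#'
#' The product of \code{\link{orientAlleles}} or of the infinite-sites
#' simulator: a 0/1 matrix of derived states at orientable biallelic sites,
#' plus the number of sites that could not be oriented (outgroup carrying a
#' third state or a gap).
#'
#' @slot name locus name.
#' @slot mat integer matrix, sites x samples, 1 = derived allele.
#' @slot sampleIds sample id per column.
#' @slot nUnorientable number of polymorphic sites excluded from orientation.
#' @export
setClass("OrientedAlignment",
  slots = c(name = "character", mat = "matrix", sampleIds = "character",
            nUnorientable = "integer"),
  prototype = prototype(name = NA_character_, nUnorientable = 0L))

setValidity("OrientedAlignment", function(object) {
  m <- object@mat
  if (nrow(m) > 0) {
    i <- rowSums(m)
    if (any(i < 1 | i > ncol(m) - 1))
      return("derived counts must lie in 1..n-1 at every site")
    if (!all(m %in% c(0L, 1L))) return("mat must be 0/1")
  }
  if (length(object@sampleIds) != ncol(m))
    return("sampleIds must match the number of columns")
  TRUE
})

#' Parameters of the two-population divergence model
#'
#' Effective sizes are numbers of diploid individuals; internally the
#' coalescent uses 2N gene copies for both sequence loci (one sequence
#' sampled per individual of a diploid population) and microsatellites
#' (two alleles per individual).
#'
#' @slot NW,NE,NAnc effective sizes of the Western, Eastern and ancestral
#'   populations (individuals).
#' @slot Td divergence time in generations.
#' @slot muSeq sequence mutation rate, substitutions/site/generation.
#' @slot muSSR microsatellite mutation rate, mutations/locus/generation.
#' @slot pSSR geometric step-size parameter of the generalized stepwise
#'   model, in [0, 1).
#' @export
setClass("DivergenceModelParams",
  slots = c(NW = "numeric", NE = "numeric", NAnc = "numeric", Td = "numeric",
            muSeq = "numeric", muSSR = "numeric", pSSR = "numeric"))

setValidity("DivergenceModelParams", function(object) {
  if (object@NW < 1 || object@NE < 1 || object@NAnc < 1)
    return("population sizes must be >= 1")
  if (object@Td < 0) return("Td must be >= 0")
  if (object@muSeq < 0 || object@muSSR < 0) return("mutation rates must be >= 0")
  if (object@pSSR < 0 || object@pSSR >= 1) return("pSSR must be in [0, 1)")
  TRUE
})

#' Prior specification for the divergence model parameters
#'
#' One marginal per parameter; supported families are \code{"loguniform"},
#' \code{"uniform"}, \code{"truncnorm"} and \code{"fixed"}.
#'
#' @slot marginals named list of marginal specifications.
#' @export
setClass("PriorSpec", slots = c(marginals = "list"))

#' ABC reference table
#'
#' @slot params matrix of parameter draws (one row per simulation).
#' @slot stats matrix of summary statistics, same row order.
#' @export
setClass("ReferenceTable", slots = c(params = "matrix", stats = "matrix"))

setValidity("ReferenceTable", function(object) {
  if (nrow(object@params) != nrow(object@stats))
    return("params and stats must have the same number of rows")
  if (anyNA(object@stats)) return("undefined summary statistics in table")
  TRUE
})

#' Rejection + local-linear-regression ABC posterior
#'
#' @slot raw accepted parameter draws before adjustment.
#' @slot adjusted regression-adjusted particles, re-truncated to the prior
#'   support.
#' @slot weights Epanechnikov kernel weights, normalized to sum to 1.
#' @slot tolerance acceptance proportion used.
#' @slot obs the observed summary-statistic vector.
#' @slot regressionUsed FALSE when a singular design forced plain rejection.
#' @export
setClass("ABCPosterior",
  slots = c(raw = "matrix", adjusted = "matrix", weights = "numeric",
            tolerance = "numeric", obs = "numeric",
            regressionUsed = "logical"))

setValidity("ABCPosterior", function(object) {
  if (any(object@weights < 0)) return("weights must be >= 0")
  if (abs(sum(object@weights) - 1) > 1e-8)
    return("weights must be normalized")
  if (nrow(object@raw) != nrow(object@adjusted))
    return("raw and adjusted particle counts differ")
  TRUE
})

#' Per-gene simulated null distribution of neutrality statistics
#'
#' @slot gene gene name.
#' @slot stats matrix with one row per retained simulation; columns hold the
#'   statistics (D/H pooled and per subset, FST, thetaW, ...).
#' @slot config list recording the sample configuration and settings used.
#' @export
setClass("NullDistribution",
  slots = c(gene = "character", stats = "matrix", config = "list"))

#' Maximum-likelihood HKA fit
#'
#' @slot theta per-locus theta estimates (per site, free model).
#' @slot Tdiv divergence time estimate in coalescent units.
#' @slot k selection parameters (1 for unselected loci).
#' @slot selected names of the loci with a free k.
#' @slot logLik,logLik0 log-likelihood of the selection and neutral models.
#' @slot lrt likelihood-ratio statistic 2*(logLik - logLik0).
#' @slot df degrees of freedom (number of selected loci).
#' @slot converged optimizer convergence flag.
#' @export
setClass("MLHKAFit",
  slots = c(theta = "numeric", Tdiv = "numeric", k = "numeric",
            selected = "character", logLik = "numeric", logLik0 = "numeric",
            lrt = "numeric", df = "integer", converged = "logical"))

#' In-frame codon alignment of orthologous coding sequences
#'
#' @slot gene gene name.
#' @slot seqs named character vector of equal-length in-frame coding
#'   sequences (one per taxon), no internal stop codons.
#' @export
setClass("CodonAlignment", slots = c(gene = "character", seqs = "character"))

setValidity("CodonAlignment", function(object) {
  s <- object@seqs
  if (length(s) < 2) return("need at least two taxa")
  if (is.null(names(s))) return("sequences must be named by taxon")
  L <- unique(nchar(s))
  if (length(L) != 1) return("sequences must be equal length")
  if (L %% 3 != 0) return("length must be divisible by 3")
  for (i in seq_along(s)) {
    cod <- .splitCodons(s[[i]])
    full <- !grepl("[^ACGT]", cod)
    if (any(.isStop(cod[full])))
      return(sprintf("internal stop codon in '%s'", names(s)[i]))
  }
  TRUE
})

#' Synthetic study scenario
#'
#' Defines the true demographic parameters, the per-candidate-gene selection
#' regime, the sample composition and the outgroup depth used by the
#' synthetic-data generator.
#'
#' @slot params true \linkS4class{DivergenceModelParams}.
#' @slot regimes named character vector over candidate genes, values in
#'   neutral/sweep/balancing.
#' @slot samples sample sheet (id, group, color) for the simulated
#'   individuals.
#' @slot registry locus registry (candidates, sequence controls, SSR
#'   controls) with lengths, motifs and allele ranges.
#' @slot outTime outgroup divergence time in generations.
#' @slot sweepC coalescent-time contraction factor of the sweep regime.
#' @slot balAge age of the balanced allelic split, in units of 2*NAnc
#'   generations.
#' @slot colorAssoc probability that a balanced-class-1 individual is
#'   assigned the focal color at a color-associated gene (0.5 = none).
#' @slot seed integer seed the generator was declared with.
#' @export
setClass("SyntheticScenario",
  slots = c(params = "DivergenceModelParams", regimes = "character",
            samples = "data.frame", registry = "data.frame",
            outTime = "numeric", sweepC = "numeric", balAge = "numeric",
            colorAssoc = "numeric", seed = "integer"))

setValidity("SyntheticScenario", function(object) {
  cand <- object@registry$name[object@registry$kind == "candidate"]
  if (!all(names(object@regimes) %in% cand))
    return("regimes are only defined for candidate loci")
  if (!all(object@regimes %in% c("neutral", "sweep", "balancing")))
    return("regime must be neutral, sweep or balancing")
  if (length(object@seed) != 1 || is.na(object@seed))
    return("a seed is mandatory")
  TRUE
})
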