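#' @rdname StudyBundle-class
#' @param x a \linkS4class{StudyBundle}.
#' @export
setGeneric("seqLoci", function(x) standardGeneric("seqLoci"))

#' @rdname StudyBundle-class
#' @export
setGeneric("ssrLoci", function(x) standardGeneric("ssrLoci"))

#' @rdname StudyBundle-class
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname StudyBundle-class
#' @export
setGeneric("registry", function(x) standardGeneric("registry"))

#' @rdname StudyBundle-class
#' @export
setGeneric("locusNames", function(x) standardGeneric("locusNames"))

#' Number of sampled sequences / individuals
#' @param x an alignment-like object.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Derived-allele counts of the oriented sites
#' @param x an \linkS4class{OrientedAlignment}.
#' @export
setGeneric("derivedCounts", function(x) standardGeneric("derivedCounts"))

setMethod("seqLoci", "StudyBundle", function(x) x@seqLoci)
setMethod("ssrLoci", "StudyBundle", function(x) x@ssrLoci)
setMethod("sampleInfo", "StudyBundle", function(x) x@samples)
setMethod("registry", "StudyBundle", function(x) x@registry)
setMethod("locusNames", "StudyBundle",
          function(x) c(names(x@seqLoci), names(x@ssrLoci)))
setMethod("nSamples", "LocusAlignment", function(x) nrow(x@seqs))
setMethod("nSamples", "OrientedAlignment", function(x) ncol(x@mat))
setMethod("nSamples", "StudyBundle", function(x) nrow(x@samples))
setMethod("derivedCounts", "OrientedAlignment",
          function(x) as.integer(rowSums(x@mat)))

setMethod("show", "LocusAlignment", function(object) {
  cat(sprintf("LocusAlignment '%s': %d sequences x %d sites%s\n",
              object@name, nrow(object@seqs), ncol(object@seqs),
              if (length(object@outgroup)) " (+outgroup)" else ""))
})

setMethod("show", "MicrosatLocus", function(object) {
  cat(sprintf(
    "MicrosatLocus '%s': %d diploid individuals, motif %d bp, alleles %d-%d\n",
    object@name, nrow(object@genotypes), object@motif,
    object@alleleRange[1], object@alleleRange[2]))
})

setMethod("show", "StudyBundle", function(object) {
  reg <- object@registry
  cat(sprintf("StudyBundle: %d samples (%s)\n", nrow(object@samples),
              paste(sprintf("%s=%d", .GROUPS,
                            tabulate(factor(object@samples$group, .GROUPS),
                                     2)), collapse = ", ")))
  cat(sprintf("  loci: %d candidate, %d sequence control, %d SSR control\n",
              sum(reg$kind == "candidate"), sum(reg$kind == "control_seq"),
              sum(reg$kind == "control_ssr")))
  cat(sprintf("  colors: %s\n",
              paste(sprintf("%s=%d", .COLORS,
                            tabulate(factor(object@samples$color, .COLORS),
                                     5)), collapse = ", ")))
})

setMethod("show", "OrientedAlignment", function(object) {
  cat(sprintf(
    "OrientedAlignment '%s': %d oriented sites, n = %d (%d unorientable)\n",
    object@name, nrow(object@mat), ncol(object@mat), object@nUnorientable))
})

setMethod("show", "DivergenceModelParams", function(object) {
  cat("Two-population divergence model\n")
  cat(sprintf("  N_W = %.4g, N_E = %.4g, N_A = %.4g individuals\n",
              object@NW, object@NE, object@NAnc))
  cat(sprintf("  T_d = %.4g generations\n", object@Td))
  cat(sprintf("  mu_seq = %.3g /site/gen, mu_SSR = %.3g /locus/gen, P_SSR = %.3g\n",
              object@muSeq, object@muSSR, object@pSSR))
})

setMethod("show", "ABCPosterior", function(object) {
  cat(sprintf(
    "ABCPosterior: %d accepted particles (tolerance %.3g)%s\n",
    nrow(object@adjusted), object@tolerance,
    if (object@regressionUsed) ", regression-adjusted"
    else ", rejection only"))
  q <- t(apply(object@adjusted, 2, function(p)
    c(mean = weighted.mean(p, object@weights),
      quantile(p, c(0.025, 0.975)))))
  print(signif(q, 4))
})

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf("NullDistribution '%s': %d simulations, statistics: %s\n",
              object@gene, nrow(object@stats),
              paste(colnames(object@stats), collapse = ", ")))
})

setMethod("show", "MLHKAFit", function(object) {
  cat(sprintf("MLHKAFit: %d loci, T = %.4g coalescent units\n",
              length(object@theta), object@Tdiv))
  if (length(object@selected)) {
    cat(sprintf("  selected: %s\n",
                paste(sprintf("%s (k = %.3g)", object@selected,
                              object@k[object@selected]), collapse = ", ")))
    cat(sprintf("  LRT = %.4g, df = %d, P = %.3g\n", object@lrt, object@df,
                pchisq(object@lrt, object@df, lower.tail = FALSE)))
  } else cat("  neutral fit (all k = 1)\n")
})

setMethod("show", "SyntheticScenario", function(object) {
  cat(sprintf("SyntheticScenario (seed %d): %d samples\n", object@seed,
              nrow(object@samples)))
  reg <- object@registry
  cand <- reg$name[reg$kind == "candidate"]
  cat(sprintf("  regimes: %s\n",
              paste(sprintf("%s=%s", cand, object@regimes[cand]),
                    collapse = ", ")))
})
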