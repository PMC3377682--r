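#' @include AllClasses.R abc.R neutrality.R hka.R pathway.R dnds.R
NULL

.defaultPipelineConfig <- function() {
  list(abcSims = 10000L, tolerance = 1e-2, nullSims = 2000L,
       thetaWindow = 1.5, nPred = 200L, seed = 1L, colorTests = TRUE,
       positions = NULL, outDir = NULL)
}

#' Run the full selection-scan study end to end
#'
#' Stages: observed summary statistics on the control loci; ABC fit of the
#' divergence model (reference table + local linear regression); posterior
#' predictive model check; per-candidate-gene null distributions and rank
#' tests (pooled, geographic and color sample sets; theta-matched FST);
#' pairwise HKA over all candidate pairs and single-gene ML-HKA fits;
#' pathway-position correlation and location tests; and, when ortholog
#' codon alignments are supplied, the pairwise dN/dS table with its own
#' position correlations. All randomness is governed by
#' \code{config$seed}; a rerun with the same config is identical.
#'
#' @param bundle a \linkS4class{StudyBundle}.
#' @param config list overriding any of: abcSims, tolerance, nullSims,
#'   thetaWindow, nPred, seed, colorTests, positions (named overrides),
#'   outDir (writes TSV outputs and a manifest when non-NULL).
#' @param orthologAlignments optional list of
#'   \linkS4class{CodonAlignment}s for the dN/dS stage.
#' @param priors a \linkS4class{PriorSpec}.
#' @param quiet suppress stage messages.
#' @return list with observedStats, posterior, check, neutrality, hka,
#'   pathway, dnds (NULL when not run) and manifest.
#' @export
runFullStudy <- function(bundle, config = list(),
                         orthologAlignments = NULL,
                         priors = defaultPriors(), quiet = FALSE) {
  cfg <- utils::modifyList(.defaultPipelineConfig(), config)
  say <- function(...) if (!quiet) message(sprintf(...))
  set.seed(cfg$seed)
  stage <- function(name, expr) {
    say("[%s]", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  observed <- stage("summary statistics", abcSummaryVector(bundle))
  template <- bundleTemplate(bundle)
  abcStage <- stage("abc fit", {
    draws <- samplePrior(priors, cfg$abcSims)
    tab <- simulateReferenceTable(draws, template, priors = priors,
                                  progress = !quiet)
    list(tab = tab,
         post = abcFit(observed, tab, tolerance = cfg$tolerance,
                       priors = priors))
  })
  posterior <- abcStage$post
  check <- stage("model check",
                 posteriorPredictiveCheck(posterior, template,
                                          abcStage$tab,
                                          nPred = cfg$nPred))
  neut <- stage("neutrality tests",
                neutralityTests(bundle, posterior, nSims = cfg$nullSims,
                                thetaWindow = cfg$thetaWindow,
                                colorTests = cfg$colorTests))
  reg <- bundle@registry
  genes <- reg$name[reg$kind == "candidate"]
  hasOg <- vapply(genes, function(g)
    length(bundle@seqLoci[[g]]@outgroup) > 0, TRUE)
  hka <- NULL
  if (all(hasOg)) {
    hka <- stage("hka", {
      counts <- do.call(rbind, lapply(genes, function(g)
        hkaCounts(excludeGapSites(bundle@seqLoci[[g]]))))
      prs <- utils::combn(genes, 2)
      pw <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
        r <- pairwiseHKA(counts[counts$locus == prs[1, i], ],
                         counts[counts$locus == prs[2, i], ])
        data.frame(locusA = prs[1, i], locusB = prs[2, i],
                   chisq = r$chisq, p = r$p, stringsAsFactors = FALSE)
      }))
      ml <- do.call(rbind, lapply(genes, function(g) {
        fit <- mlHKA(counts, selected = g)
        data.frame(locus = g, k = unname(fit@k[g]), lrt = fit@lrt,
                   df = fit@df,
                   p = pchisq(fit@lrt, fit@df, lower.tail = FALSE),
                   stringsAsFactors = FALSE)
      }))
      list(counts = counts, pairwise = pw, ml = ml)
    })
  } else say("[hka] skipped: outgroup missing for %s",
             paste(genes[!hasOg], collapse = ", "))
  pathway <- stage("pathway", {
    pos <- pathwayPositions(genes, overrides = cfg$positions)
    corr <- pathwayCorrelation(neut$pvals, pos)
    loc <- groupLocationTests(neut$pvals)
    list(positions = pos, correlation = corr, locationTests = loc)
  })
  dnds <- NULL
  if (!is.null(orthologAlignments)) {
    dnds <- stage("dnds", {
      tab <- dndsTable(orthologAlignments)
      pos <- pathway$positions[tab$gene]
      corr <- do.call(rbind, lapply(c("omega", "dN", "dS"), function(v) {
        ok <- !is.na(tab[[v]])
        kt <- kendallTau(pos[ok], tab[[v]][ok])
        data.frame(measure = v, tau = kt$tau, p = kt$p, n = sum(ok),
                   stringsAsFactors = FALSE)
      }))
      list(table = tab, correlation = corr)
    })
  }
  manifest <- list(package = "divergeScan",
                   version = as.character(utils::packageVersion(
                     "divergeScan")),
                   config = cfg[c("abcSims", "tolerance", "nullSims",
                                  "thetaWindow", "nPred", "seed",
                                  "colorTests")],
                   nSamples = nrow(bundle@samples),
                   loci = nrow(reg))
  out <- list(observedStats = observed, posterior = posterior,
              check = check, neutrality = neut, hka = hka,
              pathway = pathway, dnds = dnds, manifest = manifest)
  if (!is.null(cfg$outDir)) .writeStudyOutputs(out, cfg$outDir)
  out
}

.writeStudyOutputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wt(out$neutrality$dh, "tajima_faywu.tsv")
  wt(out$neutrality$fst, "fst_tests.tsv")
  wt(out$neutrality$pvals, "neutrality_pvalues.tsv")
  wt(out$check$rank, "model_check_ranks.tsv")
  post <- cbind(as.data.frame(out$posterior@adjusted),
                weight = out$posterior@weights)
  wt(post, "abc_posterior.tsv")
  wt(out$pathway$correlation, "pathway_correlation.tsv")
  if (!is.null(out$hka)) {
    wt(out$hka$counts, "hka_counts.tsv")
    wt(out$hka$pairwise, "hka_pairwise.tsv")
    wt(out$hka$ml, "hka_ml.tsv")
  }
  if (!is.null(out$dnds)) {
    wt(out$dnds$table, "dnds_pairwise.tsv")
    wt(out$dnds$correlation, "dnds_correlation.tsv")
  }
  yaml::write_yaml(out$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
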