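#' @include AllClasses.R
NULL

# Default ordinal positions along the carotenoid biosynthesis chain,
# counted in enzymes from the most upstream gene; a gene catalysing
# several steps is indexed at its most upstream one, which places the two
# lycopene cyclases at the same level.
.DEFAULT_POSITIONS <- c(IPI = 1, PDS = 2, CRTISO = 3, LCYB1 = 4, LCYE = 4,
                        CHXE = 5, ZEP = 6)
.UPSTREAM_GENES <- c("IPI", "PDS", "CRTISO")
.DOWNSTREAM_GENES <- c("LCYB1", "LCYE", "CHXE", "ZEP")

#' Pathway position indexes for the candidate genes
#'
#' Ordinal positions relative to the most upstream enzyme. Defaults cover
#' the seven carotenoid biosynthesis genes (with LCYB1 and LCYE tied);
#' other gene sets fall back to registry order. Overrides replace default
#' values; an override that breaks the canonical relative order only
#' triggers a warning, since users may model a different pathway.
#'
#' @param genes character vector of candidate gene names.
#' @param overrides named numeric vector of replacement indexes.
#' @return named numeric vector of positions.
#' @export
pathwayPositions <- function(genes, overrides = NULL) {
  pos <- .DEFAULT_POSITIONS[genes]
  names(pos) <- genes
  unknown <- is.na(pos)
  if (any(unknown)) pos[unknown] <- seq_len(sum(unknown)) +
      max(0, pos[!unknown])
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), genes)
    if (length(bad)) stop(sprintf("override for unknown gene '%s'", bad[1]))
    pos[names(overrides)] <- overrides
    known <- intersect(names(.DEFAULT_POSITIONS), genes)
    if (length(known) > 1) {
      ref <- .DEFAULT_POSITIONS[known]
      if (any(sign(outer(pos[known], pos[known], "-")) !=
                sign(outer(ref, ref, "-"))))
        warning("overrides change the canonical relative gene order")
    }
  }
  pos
}

#' Kendall's rank correlation
#'
#' Tie-corrected tau (tau-b) with the p-value of \code{stats::cor.test}:
#' exact for n <= 30 without ties, normal approximation with tie
#' correction otherwise.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with tau and p.
#' @export
kendallTau <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("tau undefined for an all-tied vector")
  ct <- suppressWarnings(cor.test(x, y, method = "kendall"))
  list(tau = unname(ct$estimate), p = ct$p.value)
}

#' Correlate neutrality-test p-values with pathway position
#'
#' Pools every p-value (pooled, geographic and color sample sets) per gene
#' and computes Kendall's tau between p-values and the genes' pathway
#' positions, globally and per statistic.
#'
#' @param pvals long data.frame with columns gene, statistic, p (the
#'   \code{pvals} element of \code{\link{neutralityTests}}).
#' @param positions named positions from \code{\link{pathwayPositions}}.
#' @return data.frame with statistic ("all" first), tau, p and the number
#'   of p-values used.
#' @export
pathwayCorrelation <- function(pvals, positions) {
  pvals <- pvals[!is.na(pvals$p), , drop = FALSE]
  pvals$pos <- positions[pvals$gene]
  out <- list()
  kt <- kendallTau(pvals$pos, pvals$p)
  out[[1]] <- data.frame(statistic = "all", tau = kt$tau, p = kt$p,
                         n = nrow(pvals), stringsAsFactors = FALSE)
  for (st in unique(pvals$statistic)) {
    sub <- pvals[pvals$statistic == st, , drop = FALSE]
    kt <- tryCatch(kendallTau(sub$pos, sub$p), error = function(e)
      list(tau = NA_real_, p = NA_real_))
    out[[length(out) + 1L]] <- data.frame(statistic = st, tau = kt$tau,
                                          p = kt$p, n = nrow(sub),
                                          stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Location tests of p-values across genes and pathway halves
#'
#' Kruskal-Wallis rank-sum test for heterogeneity of the pooled p-value
#' distributions across genes, and a Wilcoxon rank-sum test comparing
#' genes upstream of the central metabolic node against genes downstream
#' of it. Midranks handle the ties that pooled p-value vectors contain by
#' construction.
#'
#' @param pvals long data.frame with columns gene and p.
#' @param upstream,downstream gene sets on either side of the node;
#'   defaults are the three genes upstream of lycopene and the four genes
#'   downstream of it.
#' @param alternative for the Wilcoxon test ("two.sided" by default;
#'   "greater" tests upstream p-values exceeding downstream ones).
#' @return list with kruskal (statistic, df, p) and wilcoxon (statistic,
#'   p, alternative).
#' @export
groupLocationTests <- function(pvals, upstream = .UPSTREAM_GENES,
                               downstream = .DOWNSTREAM_GENES,
                               alternative = "two.sided") {
  pvals <- pvals[!is.na(pvals$p), , drop = FALSE]
  if (!nrow(pvals)) stop("empty p-value table")
  counts <- table(pvals$gene)
  if (length(counts) < 2 || any(counts < 1)) stop("need >= 2 gene groups")
  kw <- kruskal.test(pvals$p, factor(pvals$gene))
  up <- pvals$p[pvals$gene %in% upstream]
  down <- pvals$p[pvals$gene %in% downstream]
  if (!length(up) || !length(down))
    stop("empty upstream or downstream group")
  wt <- suppressWarnings(wilcox.test(up, down,
                                     alternative = alternative))
  list(kruskal = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p = kw$p.value),
       wilcoxon = list(statistic = unname(wt$statistic), p = wt$p.value,
                       alternative = alternative))
}
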