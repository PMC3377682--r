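#' @include AllClasses.R
NULL

.splitCodons <- function(s) {
  n <- nchar(s)
  substring(s, seq(1, n, 3), seq(3, n, 3))
}

.GC <- NULL
.geneticCode <- function() {
  if (is.null(.GC))
    utils::assignInMyNamespace(".GC", Biostrings::GENETIC_CODE)
  .GC
}

.isStop <- function(codons) unname(.geneticCode()[codons] == "*")

.translate1 <- function(codon) unname(.geneticCode()[codon])

# Nei-Gojobori (1986) synonymous site fraction of one codon: at each of the
# three positions, the fraction of the three possible single-nucleotide
# changes that preserve the amino acid (changes to stop codons are not
# synonymous).
.codonSynSites <- local({
  cache <- new.env(parent = emptyenv())
  function(codon) {
    if (!is.null(cache[[codon]])) return(cache[[codon]])
    aa <- .translate1(codon)
    s <- 0
    for (pos in 1:3) {
      for (nt in setdiff(.NUC, substr(codon, pos, pos))) {
        alt <- codon
        substr(alt, pos, pos) <- nt
        if (.translate1(alt) == aa) s <- s + 1 / 3
      }
    }
    cache[[codon]] <- s
    s
  }
})

#' Construct a CodonAlignment
#'
#' @param gene gene name.
#' @param seqs named character vector of equal-length in-frame coding
#'   sequences.
#' @return a \linkS4class{CodonAlignment}.
#' @export
codonAlignment <- function(gene, seqs) {
  new("CodonAlignment", gene = as.character(gene),
      seqs = toupper(unlist(seqs)))
}

#' Read a codon alignment from FASTA
#'
#' A thin reader that validates frame (length divisible by 3, no internal
#' stop codons); alignments are expected to arrive trimmed to the coding
#' sequence.
#'
#' @param path FASTA file.
#' @param gene gene name (defaults to the file name).
#' @return a \linkS4class{CodonAlignment}.
#' @export
readCodonAlignment <- function(path,
                               gene = sub("\\.[^.]*$", "", basename(path))) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  codonAlignment(gene, seqs)
}

#' NG86 synonymous and nonsynonymous site counts
#'
#' @param seq an in-frame coding sequence (string).
#' @return named vector with N (nonsynonymous) and S (synonymous) site
#'   counts; each codon contributes 3 sites in total. Codons containing
#'   non-ACGT characters are skipped.
#' @export
ng86SiteCounts <- function(seq) {
  cod <- .splitCodons(toupper(seq))
  cod <- cod[!grepl("[^ACGT]", cod)]
  if (any(.isStop(cod))) stop("stop codon encountered")
  Ssites <- sum(vapply(cod, .codonSynSites, 0))
  c(N = 3 * length(cod) - Ssites, S = Ssites)
}

# All orderings of the changed positions between two codons.
.permList <- list(NULL, list(1L),
                  list(c(1L, 2L), c(2L, 1L)),
                  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

# Synonymous/nonsynonymous difference counts between two codons, averaged
# with equal weight over all single-step mutational paths that avoid stop
# codons. When every path passes through a stop, all paths are used and
# steps into or out of a stop count as nonsynonymous.
.codonPairDiffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0) return(c(Nd = 0, Sd = 0))
  paths <- lapply(.permList[[nd + 1L]], function(ord) pos[ord])
  eval_path <- function(ord, allowStop) {
    cur <- c1
    nS <- nN <- 0
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!allowStop && .isStop(nxt)) return(NULL)
      if (!.isStop(cur) && !.isStop(nxt) &&
          .translate1(cur) == .translate1(nxt)) nS <- nS + 1
      else nN <- nN + 1
      cur <- nxt
    }
    c(nN, nS)
  }
  res <- Filter(Negate(is.null), lapply(paths, eval_path,
                                        allowStop = FALSE))
  if (!length(res)) res <- lapply(paths, eval_path, allowStop = TRUE)
  avg <- Reduce(`+`, res) / length(res)
  c(Nd = avg[1], Sd = avg[2])
}

#' Pairwise NG86 dN/dS
#'
#' Nei-Gojobori (1986) counting: synonymous/nonsynonymous site totals
#' averaged between the two sequences, difference counts averaged with
#' equal weight over the single-step mutational paths of multi-difference
#' codons (paths through stop codons excluded), and the Jukes-Cantor-style
#' correction \eqn{d = -\frac{3}{4}\ln(1 - \frac{4}{3} p)}. Saturated
#' proportions (p >= 3/4) and zero synonymous sites yield flagged
#' undefined (NA) rates; omega is NA whenever dS is undefined or 0.
#'
#' @param seqA,seqB equal-length in-frame coding sequences (strings).
#' @return list with dN, dS, omega, Nsites, Ssites, Nd, Sd, codons.
#' @export
pairwiseDnDs <- function(seqA, seqB) {
  ca <- .splitCodons(toupper(seqA))
  cb <- .splitCodons(toupper(seqB))
  if (length(ca) != length(cb)) stop("sequences must be equal length")
  ok <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  ca <- ca[ok]
  cb <- cb[ok]
  if (any(.isStop(ca)) || any(.isStop(cb)))
    stop("stop codon encountered")
  sA <- sum(vapply(ca, .codonSynSites, 0))
  sB <- sum(vapply(cb, .codonSynSites, 0))
  Ssites <- (sA + sB) / 2
  Nsites <- 3 * length(ca) - Ssites
  Nd <- Sd <- 0
  for (i in which(ca != cb)) {
    d <- .codonPairDiffs(ca[i], cb[i])
    Nd <- Nd + d["Nd"]
    Sd <- Sd + d["Sd"]
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  dN <- if (Nsites > 0) jc(Nd / Nsites) else NA_real_
  dS <- if (Ssites > 0) jc(Sd / Ssites) else NA_real_
  omega <- if (is.na(dS) || dS == 0 || is.na(dN)) NA_real_ else dN / dS
  list(dN = unname(dN), dS = unname(dS), omega = omega,
       Nsites = unname(Nsites), Ssites = unname(Ssites),
       Nd = unname(Nd), Sd = unname(Sd), codons = length(ca))
}

#' All pairwise dN/dS values of one or more codon alignments
#'
#' @param alignments a \linkS4class{CodonAlignment} or list of them.
#' @return data.frame with gene, taxonA, taxonB, dN, dS, omega (one row
#'   per unordered taxon pair per gene).
#' @export
dndsTable <- function(alignments) {
  if (is(alignments, "CodonAlignment")) alignments <- list(alignments)
  rows <- list()
  for (al in alignments) {
    taxa <- names(al@seqs)
    prs <- utils::combn(taxa, 2)
    for (p in seq_len(ncol(prs))) {
      r <- pairwiseDnDs(al@seqs[[prs[1, p]]], al@seqs[[prs[2, p]]])
      rows[[length(rows) + 1L]] <- data.frame(
        gene = al@gene, taxonA = prs[1, p], taxonB = prs[2, p],
        dN = r$dN, dS = r$dS, omega = r$omega, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
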