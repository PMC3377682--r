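#' @include AllClasses.R
NULL

setClass("OrientationEstimate", slots = c(m = "numeric", d = "numeric"))

setValidity("OrientationEstimate", function(object) {
  if (object@m < 0 || object@m > 1) return("m must lie in [0, 1]")
  if (object@d < 0) return("d must be >= 0")
  TRUE
})

setMethod("show", "OrientationEstimate", function(object) {
  cat(sprintf(
    "OrientationEstimate: misorientation rate m = %.4g (outgroup divergence d = %.4g subst/site)\n",
    object@m, object@d))
})

#' Construct a LocusAlignment
#'
#' @param name locus name.
#' @param seqs a named character vector of equal-length sequences, or a
#'   character matrix (samples x sites) with sample ids as rownames.
#' @param outgroup a single outgroup sequence (string) or per-site character
#'   vector; \code{character(0)} (default) for none.
#' @param siteClass optional per-column "exon"/"intron" annotation.
#' @return a \linkS4class{LocusAlignment}.
#' @export
LocusAlignment <- function(name, seqs, outgroup = character(0),
                           siteClass = character(0)) {
  if (!is.matrix(seqs)) {
    L <- unique(nchar(seqs))
    if (length(L) != 1)
      stop(sprintf("ragged alignment at locus '%s'", name))
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- names(seqs)
    seqs <- m
  } else {
    seqs[] <- toupper(seqs)
  }
  if (length(outgroup) == 1 && nchar(outgroup[1]) > 1)
    outgroup <- strsplit(toupper(outgroup), "")[[1]]
  else if (length(outgroup))
    outgroup <- toupper(outgroup)
  new("LocusAlignment", name = as.character(name), seqs = seqs,
      outgroup = outgroup, siteClass = siteClass)
}

#' Construct a MicrosatLocus
#'
#' @param name locus name.
#' @param genotypes integer matrix (individuals x 2) of repeat counts with
#'   sample ids as rownames.
#' @param motif repeat motif size in bp.
#' @param alleleRange length-2 integer (min, max) repeat count; defaults to
#'   the observed range.
#' @return a \linkS4class{MicrosatLocus}.
#' @export
MicrosatLocus <- function(name, genotypes, motif = 2L,
                          alleleRange = range(genotypes, na.rm = TRUE)) {
  storage.mode(genotypes) <- "integer"
  new("MicrosatLocus", name = as.character(name), motif = as.integer(motif),
      alleleRange = as.integer(alleleRange), genotypes = genotypes)
}

.readFastaMatrix <- function(path, name) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(seqs)))
    stop(sprintf("duplicate labels in '%s'", path))
  og <- character(0)
  is_og <- tolower(names(seqs)) == "outgroup"
  if (any(is_og)) {
    og <- seqs[is_og][1]
    seqs <- seqs[!is_og]
  }
  LocusAlignment(name, seqs, outgroup = og)
}

#' Read and validate all observed study inputs
#'
#' Reads the per-locus FASTA alignments (the outgroup row, when present, is
#' named \code{outgroup}), the diploid microsatellite genotype table, the
#' sample metadata and the locus registry, and returns them as a validated
#' \linkS4class{StudyBundle}. Readers tolerate CRLF line endings and
#' lower-case nucleotides.
#'
#' @param fastaPaths named character vector of FASTA paths, one per sequence
#'   locus, names matching the registry.
#' @param genotypePath TSV with columns id, locus, allele1, allele2 (repeat
#'   counts).
#' @param metadataPath TSV with columns id, group, color.
#' @param registryPath YAML list of loci, each with name, kind
#'   (candidate/control_seq/control_ssr), length, and for candidates a
#'   position, for SSR loci a motif and allele_min/allele_max.
#' @param quiet suppress the per-group/color count message.
#' @return a \linkS4class{StudyBundle}.
#' @export
readStudyBundle <- function(fastaPaths, genotypePath, metadataPath,
                            registryPath, quiet = FALSE) {
  for (p in c(fastaPaths, genotypePath, metadataPath, registryPath))
    if (!file.exists(p)) stop(sprintf("file not found: '%s'", p))
  samples <- read.delim(metadataPath, stringsAsFactors = FALSE)
  reg <- .registryFrame(yaml::read_yaml(registryPath))
  seqNames <- reg$name[reg$kind %in% c("candidate", "control_seq")]
  missing <- setdiff(seqNames, names(fastaPaths))
  if (length(missing))
    stop(sprintf("no FASTA path given for locus '%s'", missing[1]))
  seqLoci <- lapply(seqNames, function(nm)
    .readFastaMatrix(fastaPaths[[nm]], nm))
  names(seqLoci) <- seqNames
  geno <- read.delim(genotypePath, stringsAsFactors = FALSE)
  need <- c("id", "locus", "allele1", "allele2")
  if (!all(need %in% names(geno)))
    stop("genotype table needs columns id, locus, allele1, allele2")
  ssrNames <- reg$name[reg$kind == "control_ssr"]
  ssrLoci <- lapply(ssrNames, function(nm) {
    rows <- geno[geno$locus == nm, , drop = FALSE]
    if (!nrow(rows)) stop(sprintf("no genotypes for SSR locus '%s'", nm))
    g <- as.matrix(rows[, c("allele1", "allele2")])
    rownames(g) <- rows$id
    i <- match(nm, reg$name)
    MicrosatLocus(nm, g, motif = reg$motif[i],
                  alleleRange = c(reg$alleleMin[i], reg$alleleMax[i]))
  })
  names(ssrLoci) <- ssrNames
  bundle <- new("StudyBundle", seqLoci = seqLoci, ssrLoci = ssrLoci,
                samples = samples, registry = reg)
  validObject(bundle)
  if (!quiet)
    message(sprintf(
      "read %d samples (%s; %s), %d sequence loci, %d SSR loci",
      nrow(samples),
      paste(sprintf("%s=%d", .GROUPS,
                    tabulate(factor(samples$group, .GROUPS), 2)),
            collapse = "/"),
      paste(sprintf("%s=%d", .COLORS,
                    tabulate(factor(samples$color, .COLORS), 5)),
            collapse = "/"),
      length(seqLoci), length(ssrLoci)))
  bundle
}

.registryFrame <- function(y) {
  if (is.data.frame(y)) return(y)
  reg <- do.call(rbind, lapply(y, function(e) data.frame(
    name = e$name, kind = e$kind, length = as.numeric(e$length),
    position = if (!is.null(e$position)) as.numeric(e$position) else NA_real_,
    motif = if (!is.null(e$motif)) as.integer(e$motif) else NA_integer_,
    alleleMin = if (!is.null(e$allele_min)) as.integer(e$allele_min)
                else NA_integer_,
    alleleMax = if (!is.null(e$allele_max)) as.integer(e$allele_max)
                else NA_integer_,
    stringsAsFactors = FALSE)))
  rownames(reg) <- NULL
  reg
}

#' Write a StudyBundle to the on-disk exchange formats
#'
#' Emits exactly the formats \code{\link{readStudyBundle}} consumes: one
#' FASTA per sequence locus (outgroup row last, labelled \code{outgroup}),
#' a genotype TSV, a sample metadata TSV and a YAML registry.
#'
#' @param bundle a \linkS4class{StudyBundle}.
#' @param dir output directory, created if needed.
#' @return the directory, invisibly.
#' @export
writeStudyBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (al in bundle@seqLoci) {
    seqs <- apply(al@seqs, 1, paste, collapse = "")
    if (length(al@outgroup))
      seqs <- c(seqs, outgroup = paste(al@outgroup, collapse = ""))
    ss <- Biostrings::BStringSet(seqs)
    Biostrings::writeXStringSet(ss, file.path(dir,
                                              paste0(al@name, ".fasta")))
  }
  geno <- do.call(rbind, lapply(bundle@ssrLoci, function(ms) data.frame(
    id = rownames(ms@genotypes), locus = ms@name,
    allele1 = ms@genotypes[, 1], allele2 = ms@genotypes[, 2],
    stringsAsFactors = FALSE)))
  if (is.null(geno))
    geno <- data.frame(id = character(0), locus = character(0),
                       allele1 = integer(0), allele2 = integer(0))
  write.table(geno, file.path(dir, "genotypes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bundle@samples, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  reg <- bundle@registry
  y <- lapply(seq_len(nrow(reg)), function(i) {
    e <- list(name = reg$name[i], kind = reg$kind[i],
              length = unname(reg$length[i]))
    if (!is.na(reg$position[i])) e$position <- unname(reg$position[i])
    if (!is.na(reg$motif[i])) e$motif <- unname(reg$motif[i])
    if (!is.na(reg$alleleMin[i])) {
      e$allele_min <- unname(reg$alleleMin[i])
      e$allele_max <- unname(reg$alleleMax[i])
    }
    e
  })
  yaml::write_yaml(y, file.path(dir, "registry.yaml"))
  invisible(dir)
}

#' Paths of a written bundle directory, for re-reading
#'
#' @param dir a directory produced by \code{\link{writeStudyBundle}}.
#' @return list of arguments for \code{\link{readStudyBundle}}.
#' @export
bundlePaths <- function(dir) {
  reg <- .registryFrame(yaml::read_yaml(file.path(dir, "registry.yaml")))
  seqNames <- reg$name[reg$kind %in% c("candidate", "control_seq")]
  fp <- setNames(file.path(dir, paste0(seqNames, ".fasta")), seqNames)
  list(fastaPaths = fp, genotypePath = file.path(dir, "genotypes.tsv"),
       metadataPath = file.path(dir, "samples.tsv"),
       registryPath = file.path(dir, "registry.yaml"))
}

#' Remove alignment columns containing gaps
#'
#' Drops every column in which any ingroup row or the outgroup carries
#' \code{-}. All downstream statistics operate on gap-excluded alignments.
#'
#' @param alignment a \linkS4class{LocusAlignment}.
#' @return the alignment restricted to gap-free columns.
#' @export
excludeGapSites <- function(alignment) {
  stopifnot(is(alignment, "LocusAlignment"))
  gap <- colSums(alignment@seqs == "-") > 0
  if (length(alignment@outgroup))
    gap <- gap | alignment@outgroup == "-"
  keep <- !gap
  if (!any(keep))
    stop(sprintf("no sites remain at locus '%s' after gap exclusion",
                 alignment@name))
  new("LocusAlignment", name = alignment@name,
      seqs = alignment@seqs[, keep, drop = FALSE],
      outgroup = if (length(alignment@outgroup)) alignment@outgroup[keep]
                 else character(0),
      siteClass = if (length(alignment@siteClass))
                    alignment@siteClass[keep] else character(0))
}

#' Assign ancestral/derived states from the outgroup
#'
#' At each biallelic ingroup site where the outgroup carries one of the two
#' segregating alleles, the outgroup allele is taken as ancestral and the
#' derived-allele count is the number of ingroup copies of the other allele.
#' Sites where the outgroup carries a third state (or a gap/N) are counted
#' as unorientable and excluded from H. Columns with missing ingroup data
#' (N) or more than two ingroup states are dropped entirely.
#'
#' @param alignment a gap-excluded \linkS4class{LocusAlignment} with an
#'   outgroup.
#' @return an \linkS4class{OrientedAlignment}.
#' @export
orientAlleles <- function(alignment) {
  stopifnot(is(alignment, "LocusAlignment"))
  if (!length(alignment@outgroup))
    stop(sprintf("locus '%s' has no outgroup", alignment@name))
  if (any(alignment@seqs == "-") || any(alignment@outgroup == "-"))
    stop("alignment must be gap-excluded before orientation")
  s <- alignment@seqs
  n <- nrow(s)
  rows <- list()
  nUnor <- 0L
  for (j in seq_len(ncol(s))) {
    col <- s[, j]
    if (any(col == "N")) next
    al <- unique(col)
    if (length(al) != 2) next            # monomorphic or triallelic+
    og <- alignment@outgroup[j]
    if (!og %in% al) {
      nUnor <- nUnor + 1L
      next
    }
    derived <- setdiff(al, og)
    rows[[length(rows) + 1L]] <- as.integer(col == derived)
  }
  mat <- if (length(rows)) do.call(rbind, rows)
         else matrix(integer(0), 0, n)
  colnames(mat) <- NULL
  new("OrientedAlignment", name = alignment@name, mat = mat,
      sampleIds = rownames(s), nUnorientable = nUnor)
}

#' Estimate the ancestral-state misorientation rate
#'
#' The outgroup lineage itself mutates, so some "derived" assignments are
#' back-to-front. With Jukes-Cantor divergence d between ingroup and
#' outgroup, the probability that the orienting lineage changed state at a
#' site is \eqn{P = (3/4)(1 - e^{-4d/3})}, and a changed outgroup matches
#' the wrong ingroup allele one time in three, giving \eqn{m = P/3}
#' (ceiling 1/4 at saturation). The divergence d is the JC-corrected mean
#' proportion of differences between the outgroup and each ingroup
#' sequence over columns with plain A/C/G/T in both.
#'
#' @param alignment a gap-excluded \linkS4class{LocusAlignment} with an
#'   outgroup.
#' @return an \code{OrientationEstimate} with slots \code{m} and \code{d}.
#' @export
estimateMisorientation <- function(alignment) {
  stopifnot(is(alignment, "LocusAlignment"))
  if (!length(alignment@outgroup))
    stop(sprintf("locus '%s' has no outgroup", alignment@name))
  s <- alignment@seqs
  og <- alignment@outgroup
  usable <- og %in% .NUC & colSums(!(s == "A" | s == "C" | s == "G" |
                                       s == "T")) == 0
  if (!any(usable)) stop("zero comparable sites for outgroup divergence")
  sub <- s[, usable, drop = FALSE]
  ogv <- og[usable]
  p <- mean(vapply(seq_len(nrow(sub)),
                   function(i) mean(sub[i, ] != ogv), 0))
  p <- min(p, 0.7499)                    # keep below JC saturation
  d <- -0.75 * log(1 - 4 * p / 3)
  m <- (3 / 4) * (1 - exp(-4 * d / 3)) / 3
  new("OrientationEstimate", m = m, d = d)
}
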