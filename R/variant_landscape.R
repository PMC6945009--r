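#' Windowed variant-density track
#'
#' Counts SNVs and InDels separately in fixed-width windows (default 100 kb),
#' assigning each variant to the window containing its anchor position so
#' every variant is counted exactly once.
#'
#' @param variants a `GRanges` of variant records.
#' @param ref a [ReferenceIndex].
#' @param window window width in bp.
#' @return the genome windows as `GRanges` with metadata columns `snvCount`
#'   and `indelCount`.
#' @export
densityTrack <- function(variants, ref, window = 100000L) {
  chroms <- as.character(seqnames(variants))
  unknown <- setdiff(unique(chroms), as.character(chromNames(ref)))
  if (length(unknown))
    stop("variants on unknown chromosome(s): ", paste(unknown, collapse = ", "))
  if (length(variants) && any(start(variants) > chromLengths(ref)[chroms]))
    stop("variant position beyond chromosome end")
  win <- genomeWindows(ref, as.integer(window))
  anchor <- GRanges(chroms, IRanges(start(variants), width = 1L))
  win$snvCount <- GenomicRanges::countOverlaps(win,
    anchor[variants$vtype == "SNV"])
  win$indelCount <- GenomicRanges::countOverlaps(win,
    anchor[variants$vtype == "InDel"])
  win
}

# genomic interval affected by a variant: for deletions the deleted bases
# (after the VCF anchor base), for insertions the insertion point, for
# SNVs/MNVs the substituted bases
.affectedRanges <- function(variants) {
  m <- mcols(variants)
  isDel <- m$vtype == "InDel" & nchar(m$ref) > nchar(m$alt)
  st <- start(variants); en <- end(variants)
  st[isDel] <- st[isDel] + 1L
  isIns <- m$vtype == "InDel" & !isDel
  en[isIns] <- st[isIns]
  GRanges(seqnames(variants), IRanges(st, pmax(st, en)))
}

#' InDel length mod-3 bias inside vs outside coding sequence
#'
#' Frameshifts are selected against, so InDels inside coding sequence show
#' an enriched proportion of lengths divisible by 3.  This computes the
#' frame-preserving fraction among InDels overlapping CDS and among the
#' rest, and tests the difference with a two-sided two-proportion z test
#' (continuity-corrected), falling back to Fisher's exact test when any
#' contingency cell is below 10.
#'
#' @param variants a `GRanges` of variant records (InDels are selected
#'   internally).
#' @param genes a `GRangesList` of CDS intervals from [readGeneModels()].
#' @return a list: `pCds`, `pNoncds` (frame-preserving fractions, `NA` when
#'   a class is empty), `diff` (`pCds - pNoncds`), `nCds`, `nNoncds`,
#'   `test` (an `htest`, or `NULL` when skipped) and `method`.
#' @export
indelMod3Bias <- function(variants, genes) {
  ind <- variants[variants$vtype == "InDel" & variants$indelLen >= 1L]
  cds <- unlist(genes, use.names = FALSE)
  inside <- IRanges::overlapsAny(.affectedRanges(ind), cds)
  len <- ind$indelLen
  mod3 <- len %% 3L == 0L
  nCds <- sum(inside); nNon <- sum(!inside)
  pCds <- if (nCds) mean(mod3[inside]) else NA_real_
  pNon <- if (nNon) mean(mod3[!inside]) else NA_real_
  test <- NULL; method <- "skipped (empty class)"
  if (nCds > 0L && nNon > 0L) {
    x <- c(sum(mod3[inside]), sum(mod3[!inside]))
    n <- c(nCds, nNon)
    cells <- c(x, n - x)
    if (any(cells < 10L)) {
      test <- stats::fisher.test(rbind(x, n - x))
      method <- "fisher"
    } else {
      test <- suppressWarnings(stats::prop.test(x, n, correct = TRUE))
      method <- "prop.z"
    }
  }
  list(pCds = pCds, pNoncds = pNon, diff = pCds - pNon,
       nCds = nCds, nNoncds = nNon, test = test, method = method)
}

.STOPS <- c("TAA", "TAG", "TGA")

# spliced CDS sequence of one gene model in transcription orientation
.cdsSequence <- function(cds, chromSeq) {
  parts <- Biostrings::extractAt(chromSeq, ranges(cds))
  s <- unlist(parts)
  if (as.character(strand(cds))[1L] == "-")
    s <- Biostrings::reverseComplement(s)
  s
}

# 1-based position within the spliced CDS (transcription orientation) of a
# genomic position; NA when the position falls outside every CDS interval
.cdsCoordinate <- function(pos, cds) {
  minus <- as.character(strand(cds))[1L] == "-"
  o <- if (minus) order(-start(cds)) else order(start(cds))
  cds <- cds[o]
  offset <- 0L
  for (i in seq_along(cds)) {
    s <- start(cds)[i]; e <- end(cds)[i]
    if (pos >= s && pos <= e)
      return(offset + if (minus) e - pos + 1L else pos - s + 1L)
    offset <- offset + (e - s + 1L)
  }
  NA_integer_
}

.classifyOne <- function(pos, ref, alt, vtype, indelLen, cds, chromSeq,
                         indelMode) {
  strandMinus <- as.character(strand(cds))[1L] == "-"
  if (vtype == "InDel") {
    isDel <- nchar(ref) > nchar(alt)
    affected <- if (isDel) IRanges(pos + 1L, pos + indelLen)
                else IRanges(pos, pos)
    if (indelMode == "whole") {
      contrib <- indelLen
    } else if (isDel) {
      contrib <- sum(width(IRanges::intersect(affected, ranges(cds))))
    } else {
      # inserted bases land in CDS only when the insertion point is strictly
      # inside an interval (after the last base they fall outside)
      contrib <- if (any(pos >= start(cds) & pos < end(cds))) indelLen else 0L
    }
    return(if (contrib %% 3L != 0L) "frameshift" else "other")
  }
  if (vtype != "SNV") return("other")
  cdsPos <- .cdsCoordinate(pos, cds)
  if (is.na(cdsPos)) return("other")
  # honor the phase of the transcription-first interval
  firstIdx <- if (strandMinus) which.max(end(cds)) else which.min(start(cds))
  ph <- cds$phase[firstIdx]
  if (!is.null(ph) && !is.na(ph) && ph > 0L) cdsPos <- cdsPos - as.integer(ph)
  if (cdsPos < 1L) return("other")
  cdsSeq <- .cdsSequence(cds, chromSeq)
  if (!is.null(ph) && !is.na(ph) && ph > 0L)
    cdsSeq <- Biostrings::subseq(cdsSeq, as.integer(ph) + 1L)
  len <- length(cdsSeq)
  nCodons <- len %/% 3L
  codonIdx <- (cdsPos - 1L) %/% 3L + 1L
  if (codonIdx > nCodons) return("other")
  codon <- as.character(Biostrings::subseq(cdsSeq, (codonIdx - 1L) * 3L + 1L,
                                           codonIdx * 3L))
  within <- (cdsPos - 1L) %% 3L + 1L
  base <- if (strandMinus)
    as.character(Biostrings::complement(Biostrings::DNAString(alt)))
  else alt
  newCodon <- codon
  substr(newCodon, within, within) <- base
  refStop <- codon %in% .STOPS
  newStop <- newCodon %in% .STOPS
  if (codonIdx < nCodons && newStop && !refStop) return("stop_gained")
  if (codonIdx == nCodons && refStop && !newStop) return("stop_lost")
  "other"
}

#' Classify the coding effect of variants
#'
#' Minimal effect classification into the high-impact classes relevant to
#' gene disruption: `frameshift` (CDS-overlapping InDel whose length
#' contribution to the CDS is not divisible by 3), `stop_gained` (SNV
#' creating an in-frame stop codon before the annotated stop), `stop_lost`
#' (SNV destroying the annotated stop codon) and `other` for everything
#' else, including variants outside any CDS.  Minus-strand genes are
#' evaluated on the reverse complement with coordinates mapped accordingly.
#'
#' @param variants a `GRanges` of variant records.
#' @param genes a `GRangesList` of CDS intervals from [readGeneModels()].
#' @param refSeqs a named `DNAStringSet` of chromosome sequences.
#' @param indelMode `"overlap"` counts only the CDS-overlapping portion of
#'   an InDel towards the frame; `"whole"` uses the full InDel length
#'   whenever it touches CDS.
#' @return a `data.frame` with one row per variant: `effect` and `geneId`
#'   (`NA` when no CDS is hit).  Genes whose CDS length is not divisible by
#'   3 trigger a warning; classification proceeds on the available frame.
#' @export
classifyEffects <- function(variants, genes, refSeqs,
                            indelMode = c("overlap", "whole")) {
  indelMode <- match.arg(indelMode)
  cdsAll <- unlist(genes, use.names = FALSE)
  cdsAll$geneId <- rep(names(genes), lengths(genes))
  badFrame <- tapply(width(cdsAll), cdsAll$geneId, sum) %% 3L != 0L
  if (any(badFrame))
    warning("CDS length not divisible by 3 for gene(s): ",
            paste(names(badFrame)[badFrame], collapse = ", "),
            "; classifying on the available frame")
  affected <- .affectedRanges(variants)
  hits <- GenomicRanges::findOverlaps(affected, cdsAll)
  geneHit <- rep(NA_character_, length(variants))
  firstHit <- !duplicated(S4Vectors::queryHits(hits))
  geneHit[S4Vectors::queryHits(hits)[firstHit]] <-
    cdsAll$geneId[S4Vectors::subjectHits(hits)[firstHit]]
  m <- mcols(variants)
  effect <- rep("other", length(variants))
  todo <- which(!is.na(geneHit))
  for (i in todo) {
    gid <- geneHit[i]
    chromSeq <- refSeqs[[as.character(seqnames(variants))[i]]]
    effect[i] <- .classifyOne(start(variants)[i], m$ref[i], m$alt[i],
                              m$vtype[i], m$indelLen[i], genes[[gid]],
                              chromSeq, indelMode)
  }
  data.frame(effect = effect, geneId = geneHit)
}
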