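#' @import methods
#' @importFrom S4Vectors metadata metadata<- mcols mcols<- DataFrame
#' @importFrom GenomeInfoDb Seqinfo seqnames seqlevels seqlengths seqinfo
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

#' Reference coordinate frame: chromosomes, N-gaps, centromeres
#'
#' A `ReferenceIndex` holds the chromosome names and lengths of a reference
#' assembly together with the intervals of ambiguous bases (N-gaps) and,
#' optionally, centromere point positions.  It is the shared coordinate frame
#' for every windowed track the package produces.  N-gaps matter because long
#' N-stretches cannot be covered by mapped reads and therefore masquerade as
#' deletions in depth data ("pseudo low-coverage regions").
#'
#' @slot seqinfo a [GenomeInfoDb::Seqinfo] with unique chromosome names and
#'   lengths.
#' @slot nGaps a [GenomicRanges::GRanges] of maximal N-runs (1-based, closed,
#'   the Bioconductor convention); sorted and disjoint per chromosome.
#' @slot centromeres a `GRanges` of centromere positions (width-1 ranges);
#'   may be empty.
#'
#' @seealso [readReference()]
#' @export
setClass("ReferenceIndex",
  slots = c(seqinfo = "Seqinfo", nGaps = "GRanges", centromeres = "GRanges"))

setValidity("ReferenceIndex", function(object) {
  si <- object@seqinfo
  if (anyDuplicated(seqnames(si)))
    return("duplicate chromosome names")
  g <- object@nGaps
  if (length(g)) {
    if (!all(as.character(seqnames(g)) %in% seqnames(si)))
      return("N-gap on unknown chromosome")
    lens <- seqlengths(si)[as.character(seqnames(g))]
    if (any(start(g) < 1L) || any(end(g) > lens))
      return("N-gap outside chromosome bounds")
    byc <- split(g, seqnames(g))
    for (i in seq_along(byc)) {
      x <- byc[[i]]
      if (length(x) > 1L) {
        o <- order(start(x))
        if (any(start(x)[o][-1L] <= end(x)[o][-length(x)]))
          return("N-gaps overlap")
      }
    }
  }
  TRUE
})

#' @describeIn ReferenceIndex chromosome names
#' @param x,object a `ReferenceIndex`
#' @export
chromNames <- function(x) seqnames(x@seqinfo)

#' @describeIn ReferenceIndex named vector of chromosome lengths (bp)
#' @export
chromLengths <- function(x) seqlengths(x@seqinfo)

#' @describeIn ReferenceIndex `GRanges` of N-gap intervals
#' @export
nGaps <- function(x) x@nGaps

#' @describeIn ReferenceIndex `GRanges` of centromere positions
#' @export
centromeres <- function(x) x@centromeres

setMethod("show", "ReferenceIndex", function(object) {
  cat("ReferenceIndex with", length(seqnames(object@seqinfo)),
      "chromosome(s),", sum(as.numeric(seqlengths(object@seqinfo))), "bp total\n")
  cat("  N-gaps:", length(object@nGaps), "interval(s),",
      sum(width(object@nGaps)), "bp\n")
  if (length(object@centromeres))
    cat("  centromeres:", length(object@centromeres), "position(s)\n")
})

#' Hard-filter thresholds for SNV and InDel calls
#'
#' Container for the GATK-style hard-filter rules applied to raw variant
#' calls.  A record is *removed* when an annotation falls strictly beyond a
#' threshold (e.g. QD < 2.0), so boundary values are kept.  Defaults follow
#' the GATK developer recommendations for germline hard filtering: SNVs fail
#' on QD < 2, FS > 60 or MQ < 40; InDels on QD < 2 or FS > 200, with an
#' additional length cutoff (100 bp) and a minimum read support of five.
#'
#' @slot snvQdMin,snvFsMax,snvMqMin SNV thresholds on QD, FS, MQ.
#' @slot indelQdMin,indelFsMax InDel thresholds on QD and FS.
#' @slot indelMaxLen maximum InDel length in bp.
#' @slot minSupport minimum read support for any variant.
#' @slot supportField `"AD"` (default) counts support as `adRef + adAlt`;
#'   `"DP"` uses the raw site depth instead.
#'
#' @seealso [filterConfig()], [filterVariants()]
#' @export
setClass("FilterConfig",
  slots = c(snvQdMin = "numeric", snvFsMax = "numeric", snvMqMin = "numeric",
            indelQdMin = "numeric", indelFsMax = "numeric",
            indelMaxLen = "numeric", minSupport = "numeric",
            supportField = "character"))

setValidity("FilterConfig", function(object) {
  v <- c(object@snvQdMin, object@snvFsMax, object@snvMqMin,
         object@indelQdMin, object@indelFsMax, object@indelMaxLen,
         object@minSupport)
  if (any(!is.finite(v)) || any(v <= 0))
    return("all thresholds must be finite and > 0")
  if (!object@supportField %in% c("AD", "DP"))
    return("supportField must be 'AD' or 'DP'")
  TRUE
})

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig\n")
  cat(sprintf("  SNV:   QD >= %g, FS <= %g, MQ >= %g\n",
              object@snvQdMin, object@snvFsMax, object@snvMqMin))
  cat(sprintf("  InDel: QD >= %g, FS <= %g, length <= %g bp\n",
              object@indelQdMin, object@indelFsMax, object@indelMaxLen))
  cat(sprintf("  support >= %g reads (%s)\n",
              object@minSupport, object@supportField))
})

#' Reference-allele-frequency spectrum
#'
#' Histogram of reference-allele frequencies (AD_ref / (AD_ref + AD_alt))
#' over the usable SNVs of a region.  Uniform bins on \[0, 1\]; a value of
#' exactly 1 is assigned to the last bin so the counts always sum to the
#' number of contributing variants.
#'
#' @slot binEdges numeric vector of `nBins + 1` monotone edges spanning 0..1.
#' @slot counts integer per-bin counts.
#' @slot regionLabel `"global"` or a segment identifier.
#'
#' @seealso [buildSpectrum()], [detectPeaks()]
#' @export
setClass("AFSpectrum",
  slots = c(binEdges = "numeric", counts = "integer", regionLabel = "character"))

setValidity("AFSpectrum", function(object) {
  if (length(object@counts) != length(object@binEdges) - 1L)
    return("length(counts) must equal length(binEdges) - 1")
  if (is.unsorted(object@binEdges, strictly = TRUE))
    return("binEdges must be strictly increasing")
  if (abs(object@binEdges[1L]) > 1e-12 ||
      abs(object@binEdges[length(object@binEdges)] - 1) > 1e-12)
    return("binEdges must span [0, 1]")
  if (any(object@counts < 0L)) return("negative bin count")
  TRUE
})

#' @describeIn AFSpectrum per-bin counts
#' @param x,object an `AFSpectrum`
#' @export
spectrumCounts <- function(x) x@counts

#' @describeIn AFSpectrum bin edges
#' @export
spectrumBinEdges <- function(x) x@binEdges

setMethod("show", "AFSpectrum", function(object) {
  cat(sprintf("AFSpectrum '%s': %d bins, %d variants\n", object@regionLabel,
              length(object@counts), sum(object@counts)))
})

#' Inferred ploidy and haplophase composition of a region
#'
#' Result of allele-frequency-based ploidy inference.  For a k-ploid region
#' heterozygous sites cluster at allele frequencies i/k; the call records the
#' selected k, the detected spectrum peaks, and the haplophase composition
#' implied by the dominant peak: `nRefLike` reference-like copies plus
#' `nDivergent` divergent copies, summing to the ploidy.
#'
#' @slot regionLabel `"global"` or a segment identifier.
#' @slot ploidy selected copy number k (>= 2).
#' @slot peaks `data.frame` with columns `location`, `height`, `prominence`,
#'   `mode` (the assigned expected mode i/k), locations strictly increasing.
#' @slot nRefLike,nDivergent haplophase composition.
#' @slot fitScore penalized mean squared peak-to-mode distance of the
#'   selected model (lower is better).
#' @slot ambiguous `TRUE` when a competing k scored within tolerance.
#'
#' @seealso [inferPloidy()], [segmentPloidy()]
#' @export
setClass("PloidyCall",
  slots = c(regionLabel = "character", ploidy = "integer",
            peaks = "data.frame", nRefLike = "integer", nDivergent = "integer",
            fitScore = "numeric", ambiguous = "logical"))

setValidity("PloidyCall", function(object) {
  if (object@ploidy < 2L) return("ploidy must be >= 2")
  if (object@nRefLike + object@nDivergent != object@ploidy)
    return("nRefLike + nDivergent must equal ploidy")
  if (nrow(object@peaks) > 1L &&
      is.unsorted(object@peaks$location, strictly = TRUE))
    return("peak locations must be strictly increasing")
  TRUE
})

#' @describeIn PloidyCall inferred ploidy (integer)
#' @param x,object a `PloidyCall`
#' @export
ploidy <- function(x) x@ploidy

#' @describeIn PloidyCall detected peaks with assigned modes
#' @export
ploidyPeaks <- function(x) x@peaks

#' @describeIn PloidyCall number of reference-like haplophases
#' @export
nRefLike <- function(x) x@nRefLike

#' @describeIn PloidyCall number of divergent haplophases
#' @export
nDivergent <- function(x) x@nDivergent

setMethod("show", "PloidyCall", function(object) {
  cat(sprintf("PloidyCall '%s': ploidy %d (%d reference-like + %d divergent)%s\n",
              object@regionLabel, object@ploidy, object@nRefLike,
              object@nDivergent, if (object@ambiguous) " [ambiguous]" else ""))
  if (nrow(object@peaks))
    cat("  peaks at", paste(sprintf("%.3f", object@peaks$location),
                            collapse = ", "), "\n")
})
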