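#' Reference-allele frequencies of usable SNVs
#'
#' For each kept SNV the reference-allele frequency is
#' `adRef / (adRef + adAlt)`.  Sites where the sample is invariant and only
#' the reference assembly deviates (reference allele essentially absent from
#' the reads) carry no ploidy signal and are excluded: any value below
#' `invariantCutoff` is dropped, as are sites with no informative reads or
#' support below `minSupport`.
#'
#' @param variants a `GRanges` of kept variant records.
#' @param minSupport minimum `adRef + adAlt`.
#' @param invariantCutoff frequencies below this are excluded.
#' @param includeIndels also use InDel records (allele-depth frequencies are
#'   best defined for SNVs, so the default is SNVs only).
#' @return a numeric vector of frequencies in \[0, 1\].
#' @export
refAF <- function(variants, minSupport = 5, invariantCutoff = 0.05,
                  includeIndels = FALSE) {
  m <- mcols(variants)
  use <- if (includeIndels) m$vtype %in% c("SNV", "InDel") else m$vtype == "SNV"
  supp <- m$adRef + m$adAlt
  use <- use & supp >= max(minSupport, 1L)
  af <- m$adRef[use] / supp[use]
  af[af >= invariantCutoff]
}

#' Build an allele-frequency spectrum
#'
#' Histogram over uniform bins on \[0, 1\]; a value of exactly 1 falls into
#' the last bin, so counts always sum to the number of input frequencies.
#'
#' @param afs numeric vector of frequencies in \[0, 1\].
#' @param nBins number of bins.
#' @param regionLabel label stored with the spectrum.
#' @return an [AFSpectrum].
#' @export
buildSpectrum <- function(afs, nBins = 100L, regionLabel = "global") {
  if (length(afs) == 0L) stop("no usable SNVs for region '", regionLabel, "'")
  if (any(afs < 0 | afs > 1)) stop("allele frequencies must lie in [0, 1]")
  bin <- pmin(floor(afs * nBins) + 1L, as.integer(nBins))
  new("AFSpectrum", binEdges = seq(0, 1, length.out = nBins + 1L),
      counts = tabulate(bin, nbins = nBins), regionLabel = regionLabel)
}

# moving average with shrinking edge windows
.smoothCounts <- function(counts, bw) {
  half <- (as.integer(bw) - 1L) %/% 2L
  n <- length(counts)
  vapply(seq_len(n), function(i)
    mean(counts[max(1L, i - half):min(n, i + half)]), numeric(1))
}

# peak prominence as in the classic topographic definition: drop from the
# peak to the higher of the two bracketing saddles (minimum between the peak
# and the nearest higher point, or the signal edge)
.prominence <- function(s, i) {
  base <- function(idx) {
    if (!length(idx)) return(min(s[i], min(s)))
    m <- s[i]
    for (j in idx) {
      if (s[j] > s[i]) return(m)
      m <- min(m, s[j])
    }
    m
  }
  left <- base(rev(seq_len(i - 1L)))
  right <- base(seq(i + 1L, length(s))[seq_len(max(0L, length(s) - i))])
  s[i] - max(left, right)
}

#' Detect peaks in an allele-frequency spectrum
#'
#' Counts are smoothed by a centered moving average; local maxima whose
#' prominence reaches `minProminenceFrac` of the smoothed maximum are
#' reported as (bin center, smoothed height), sorted by location.  Peaks
#' within `edgeExclude` of 0 or 1 are dropped (they reflect invariant or
#' homozygous sites, not heterozygous allele balance).
#'
#' @param spectrum an [AFSpectrum].
#' @param smoothBw moving-average width in bins.
#' @param minProminenceFrac prominence threshold as a fraction of the
#'   smoothed maximum.
#' @param edgeExclude half-width of the excluded zones at 0 and 1.
#' @return a `data.frame` with columns `location`, `height`, `prominence`;
#'   zero rows when nothing exceeds the prominence threshold.
#' @export
detectPeaks <- function(spectrum, smoothBw = 3L, minProminenceFrac = 0.05,
                        edgeExclude = 0.03) {
  stopifnot(is(spectrum, "AFSpectrum"))
  s <- .smoothCounts(spectrum@counts, smoothBw)
  n <- length(s)
  centers <- (spectrum@binEdges[-1L] + spectrum@binEdges[-(n + 1L)]) / 2
  # local maxima; plateaus contribute their first bin
  prev <- c(-Inf, s[-n]); nxt <- c(s[-1L], -Inf)
  cand <- which(s > prev & s >= nxt)
  if (!length(cand)) return(data.frame(location = numeric(0),
                                       height = numeric(0),
                                       prominence = numeric(0)))
  prom <- vapply(cand, function(i) .prominence(s, i), numeric(1))
  keep <- prom >= minProminenceFrac * max(s) &
    centers[cand] > edgeExclude & centers[cand] < 1 - edgeExclude
  out <- data.frame(location = centers[cand[keep]], height = s[cand[keep]],
                    prominence = prom[keep])
  out[order(out$location), , drop = FALSE]
}

#' Infer ploidy and haplophase composition from allele frequencies
#'
#' For a k-ploid region, heterozygous sites are expected at reference-allele
#' frequencies i/k (i = 1..k-1).  Each candidate k in 2..`kMax` is scored by
#' the mean squared distance of the detected spectrum peaks to their nearest
#' expected mode, plus a complexity penalty `lambda * k` that prefers the
#' simplest model explaining the peaks (mode sets are nested across k, e.g.
#' every k=2 mode is also a k=4 mode).  The haplophase composition follows
#' from the dominant peak: if the highest peak sits at mode i/k, sites
#' heterozygous in exactly one haplophase class show i reference copies, so
#' the region carries i reference-like and k - i divergent haplophases.
#'
#' @param afs numeric vector of reference-allele frequencies.
#' @param kMax largest ploidy considered.
#' @param minSites minimum number of usable frequencies.
#' @param lambda complexity penalty per copy.
#' @param regionLabel label for the call.
#' @param nBins,smoothBw,minProminenceFrac,edgeExclude passed to
#'   [buildSpectrum()] / [detectPeaks()].
#' @param scoreTol two candidate k within this score tolerance are resolved
#'   to the smaller k and flagged ambiguous.
#' @return a [PloidyCall].
#' @export
inferPloidy <- function(afs, kMax = 6L, minSites = 200L, lambda = 1e-4,
                        regionLabel = "global", nBins = 100L, smoothBw = 3L,
                        minProminenceFrac = 0.05, edgeExclude = 0.03,
                        scoreTol = 1e-6) {
  if (length(afs) < minSites)
    stop("only ", length(afs), " usable allele frequencies for '",
         regionLabel, "' (need >= ", minSites, ")")
  spec <- buildSpectrum(afs, nBins = nBins, regionLabel = regionLabel)
  peaks <- detectPeaks(spec, smoothBw = smoothBw,
                       minProminenceFrac = minProminenceFrac,
                       edgeExclude = edgeExclude)
  if (nrow(peaks) == 0L)
    stop("no allele-frequency peaks detected for '", regionLabel, "'")
  ks <- 2:kMax
  score <- vapply(ks, function(k) {
    modes <- (1:(k - 1L)) / k
    mean(vapply(peaks$location,
                function(p) min((p - modes)^2), numeric(1))) + lambda * k
  }, numeric(1))
  best <- min(score)
  inTol <- ks[score <= best + scoreTol]
  k <- min(inTol)
  ambiguous <- length(inTol) > 1L
  if (ambiguous)
    warning("ploidy models k = ", paste(inTol, collapse = ", "),
            " score within tolerance for '", regionLabel,
            "'; reporting k = ", k)
  modes <- (1:(k - 1L)) / k
  peaks$mode <- vapply(peaks$location,
                       function(p) modes[which.min(abs(p - modes))], numeric(1))
  top <- which.max(peaks$height)
  i <- as.integer(round(peaks$mode[top] * k))
  new("PloidyCall", regionLabel = regionLabel, ploidy = as.integer(k),
      peaks = peaks, nRefLike = i, nDivergent = as.integer(k - i),
      fitScore = score[match(k, ks)], ambiguous = ambiguous)
}

#' Per-segment ploidy calls
#'
#' Runs [inferPloidy()] once over the genomic background (all `"real"`
#' segments at the baseline copy number) and once per non-baseline real
#' segment with enough SNVs.  Segment calls are cross-checked against the
#' depth-based copy number: a mismatch is flagged in the report, never
#' silently altered — depth and allele balance are independent witnesses of
#' the same copy state.
#'
#' @param variants a `GRanges` of kept variant records.
#' @param segments segment `GRanges` from [segmentCopyNumber()].
#' @param baselinePloidy defaults to the value stored by
#'   [segmentCopyNumber()] in `metadata(segments)`.
#' @param minSites minimum usable frequencies per call.
#' @param ... further arguments passed to [inferPloidy()] / [refAF()]
#'   (`minSupport`, `invariantCutoff`, `includeIndels`, `kMax`, ...).
#' @return a list with `calls` (named list of [PloidyCall]; `"global"` plus
#'   one per called segment) and `report` (a `data.frame` with one row per
#'   region: coordinates, depth copy number, site count, inferred ploidy,
#'   haplophase composition, consistency flag, or the skip reason).
#' @export
segmentPloidy <- function(variants, segments, baselinePloidy = NULL,
                          minSites = 200L, ...) {
  if (is.null(baselinePloidy))
    baselinePloidy <- metadata(segments)$baselinePloidy
  if (is.null(baselinePloidy))
    stop("baselinePloidy not given and not stored in segments metadata")
  dots <- list(...)
  afArgs <- dots[names(dots) %in% c("minSupport", "invariantCutoff",
                                    "includeIndels")]
  ipArgs <- dots[names(dots) %in% c("kMax", "lambda", "nBins", "smoothBw",
                                    "minProminenceFrac", "edgeExclude",
                                    "scoreTol")]
  real <- segments[segments$status == "real"]
  baseRegion <- real[real$copyNumber == baselinePloidy]
  calls <- list()
  rows <- list()
  callRegion <- function(region, label, copyNumber) {
    hit <- variants[IRanges::overlapsAny(variants, region)]
    afs <- do.call(refAF, c(list(hit), afArgs))
    n <- length(afs)
    if (n < minSites) {
      warning("region '", label, "' has ", n,
              " usable SNVs (< ", minSites, "); call skipped")
      return(data.frame(regionLabel = label, copyNumber = copyNumber,
                        nSites = n, ploidy = NA_integer_,
                        nRefLike = NA_integer_, nDivergent = NA_integer_,
                        consistent = NA, note = "insufficient sites"))
    }
    call <- do.call(inferPloidy,
                    c(list(afs, minSites = minSites, regionLabel = label),
                      ipArgs))
    calls[[label]] <<- call
    data.frame(regionLabel = label, copyNumber = copyNumber,
               nSites = n, ploidy = ploidy(call), nRefLike = nRefLike(call),
               nDivergent = nDivergent(call),
               consistent = ploidy(call) == copyNumber, note = "")
  }
  rows[["global"]] <- callRegion(baseRegion, "global",
                                 as.integer(baselinePloidy))
  nonBase <- real[real$copyNumber != baselinePloidy]
  for (i in seq_along(nonBase)) {
    seg <- nonBase[i]
    label <- sprintf("%s:%d-%d", as.character(seqnames(seg)), start(seg),
                     end(seg))
    rows[[label]] <- callRegion(seg, label, seg$copyNumber)
  }
  list(calls = calls, report = do.call(rbind, c(rows, make.row.names = FALSE)))
}
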