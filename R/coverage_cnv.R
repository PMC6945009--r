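#' Tile the genome into fixed-width windows
#'
#' @param ref a [ReferenceIndex].
#' @param window window width in bp; the last window of each chromosome may
#'   be shorter.
#' @return a `GRanges` of windows in genome order.
#' @keywords internal
genomeWindows <- function(ref, window = 100000L) {
  unlist(GenomicRanges::tileGenome(ref@seqinfo, tilewidth = window,
                                   cut.last.tile.in.chrom = FALSE))
}

#' Windowed mean depth and N-gap overlap
#'
#' Bins a depth track into fixed-width windows, computing the mean depth
#' over *all* positions of each window (positions absent from the track
#' count as depth 0) and the fraction of the window covered by reference
#' N-gaps.  Accepts per-position or pre-binned tracks (see [readDepth()]).
#'
#' @param depth a depth `data.table` from [readDepth()] (or with the same
#'   columns).
#' @param ref a [ReferenceIndex]; every chromosome in `depth` must be known
#'   to it.
#' @param window window width in bp (default 100 kb).
#' @return a `GRanges` of windows with metadata columns `meanDepth` and
#'   `nFraction`.
#' @export
windowDepth <- function(depth, ref, window = 100000L) {
  window <- as.integer(window)
  chroms <- unique(as.character(depth$chrom))
  unknown <- setdiff(chroms, as.character(chromNames(ref)))
  if (length(unknown))
    stop("depth track references unknown chromosome(s): ",
         paste(unknown, collapse = ", "))
  win <- genomeWindows(ref, window)
  binned <- isTRUE(attr(depth, "binned"))
  sums <- numeric(length(win))
  key <- paste0(as.character(seqnames(win)), ":", start(win))
  idx <- stats::setNames(seq_along(win), key)
  if (!binned) {
    lens <- chromLengths(ref)[depth$chrom]
    if (any(depth$pos < 1L) || any(depth$pos > lens))
      stop("depth position outside chromosome bounds")
    dt <- data.table::data.table(chrom = depth$chrom,
                                 wstart = ((depth$pos - 1L) %/% window) * window + 1L,
                                 depth = as.numeric(depth$depth))
    agg <- dt[, list(s = sum(depth)), by = c("chrom", "wstart")]
    sums[idx[paste0(agg$chrom, ":", agg$wstart)]] <- agg$s
  } else {
    bins <- GRanges(depth$chrom, IRanges(depth$start + 1L, depth$end))
    hits <- GenomicRanges::findOverlaps(bins, win)
    ov <- IRanges::pintersect(bins[S4Vectors::queryHits(hits)],
                              win[S4Vectors::subjectHits(hits)])
    contrib <- width(ov) * depth$depth[S4Vectors::queryHits(hits)]
    agg <- tapply(contrib, S4Vectors::subjectHits(hits), sum)
    sums[as.integer(names(agg))] <- agg
  }
  meanDepth <- sums / width(win)
  gaps <- IRanges::reduce(nGaps(ref))
  nFrac <- numeric(length(win))
  if (length(gaps)) {
    hits <- GenomicRanges::findOverlaps(win, gaps)
    ov <- IRanges::pintersect(win[S4Vectors::queryHits(hits)],
                              gaps[S4Vectors::subjectHits(hits)])
    agg <- tapply(width(ov), S4Vectors::queryHits(hits), sum)
    nFrac[as.integer(names(agg))] <- agg / width(win)[as.integer(names(agg))]
  }
  mcols(win) <- DataFrame(meanDepth = meanDepth, nFraction = nFrac)
  metadata(win)$window <- window
  win
}

#' Normalize windowed depth to copy ratios
#'
#' The genome-wide baseline is the median `meanDepth` over windows with at
#' most 10% N-gap overlap (gap-dominated windows would bias it downwards);
#' each window's `copyRatio` is its mean depth divided by this baseline, so
#' a region present in c copies on a k-ploid background sits near c/k.
#'
#' @param windows output of [windowDepth()].
#' @param maxBaselineNFraction windows with `nFraction` above this value are
#'   excluded from the baseline median.
#' @return `windows` with an added `copyRatio` column; the baseline is
#'   stored in `metadata(windows)$baselineDepth`.
#' @export
normalizeWindows <- function(windows, maxBaselineNFraction = 0.1) {
  usable <- windows$nFraction <= maxBaselineNFraction
  if (!any(usable))
    stop("all windows are gap-dominated; cannot establish a depth baseline")
  baseline <- stats::median(windows$meanDepth[usable])
  if (baseline <= 0)
    stop("baseline depth is zero; depth track appears empty")
  windows$copyRatio <- windows$meanDepth / baseline
  metadata(windows)$baselineDepth <- baseline
  windows
}

#' Flag N-gap depth artifacts
#'
#' Windows with near-zero copy ratio that are mostly covered by reference
#' N-gaps are pseudo low-coverage regions — apparent deletions caused by
#' unmappable N-stretches in the assembly, not by missing sample sequence.
#' They are flagged `artifact = TRUE` and excluded from deletion calls.
#'
#' @param windows output of [normalizeWindows()].
#' @param lowRatio copy-ratio ceiling for the artifact call.
#' @param nMin minimum N-gap fraction for the artifact call.
#' @return `windows` with an added logical `artifact` column.
#' @export
maskArtifacts <- function(windows, lowRatio = 0.15, nMin = 0.5) {
  if (is.null(windows$copyRatio))
    stop("copyRatio missing; run normalizeWindows() first")
  windows$artifact <- windows$copyRatio <= lowRatio & windows$nFraction >= nMin
  windows
}

# nearest state c/ploidy with midpoint thresholds; an exact midpoint
# resolves to the lower state (ceiling(x - 0.5) is the nearest integer with
# halves rounding down), conservative against false duplications
.nearestState <- function(ratio, ploidy, cMax) {
  s <- as.integer(ceiling(ratio * ploidy - 0.5))
  pmin(pmax(s, 0L), as.integer(cMax))
}

#' Segment windows into copy-number states
#'
#' Assigns each non-artifact window the copy number c (0..`cMax`) whose
#' expected ratio c/`baselinePloidy` is nearest its observed `copyRatio`
#' (exact midpoints resolve to the lower c, conservative against false
#' duplications).  Artifact windows inherit the state of their flanking
#' windows.  Runs shorter than `minSeg` windows are reassigned to the longer
#' flanking run, suppressing depth-noise blips; adjacent windows of equal
#' final state are merged into segments.  Maximal runs of artifact windows
#' are reported as their own sub-segments with `status = "n_artifact"` (and
#' the inherited copy number), so no N-gap stretch can surface as a real
#' deletion.
#'
#' @param windows output of [maskArtifacts()].
#' @param baselinePloidy genome-wide ploidy the ratios are quantized
#'   against (>= 1).
#' @param cMax largest copy number considered.
#' @param minSeg minimum run length in windows.
#' @return a `GRanges` of segments tiling each chromosome, with metadata
#'   columns `copyNumber`, `meanRatio` and `status` (`"real"` or
#'   `"n_artifact"`).
#' @export
segmentCopyNumber <- function(windows, baselinePloidy = 3L, cMax = 6L,
                              minSeg = 5L) {
  if (baselinePloidy < 1L) stop("baselinePloidy must be >= 1")
  if (is.null(windows$artifact))
    stop("artifact flags missing; run maskArtifacts() first")
  segs <- lapply(split(windows, seqnames(windows), drop = TRUE), function(w) {
    w <- w[order(start(w))]
    n <- length(w)
    state <- rep(NA_integer_, n)
    real <- !w$artifact
    state[real] <- .nearestState(w$copyRatio[real], baselinePloidy, cMax)
    if (all(is.na(state)))
      stop("chromosome ", as.character(seqnames(w))[1L],
           " has only artifact windows")
    # artifact windows inherit flanking state (carry forward, then backward)
    for (i in seq_len(n)) if (is.na(state[i]) && i > 1L) state[i] <- state[i - 1L]
    for (i in rev(seq_len(n))) if (is.na(state[i]) && i < n) state[i] <- state[i + 1L]
    # dissolve interior runs shorter than minSeg into the longer flank;
    # runs touching a chromosome boundary are kept (no second flank to
    # vote them down, and dissolving them would erase true terminal states)
    repeat {
      r <- rle(state)
      short <- which(r$lengths < minSeg)
      short <- short[short > 1L & short < length(r$lengths)]
      if (!length(short)) break
      j <- short[which.min(r$lengths[short])]
      leftLen <- r$lengths[j - 1L]
      rightLen <- r$lengths[j + 1L]
      newVal <- if (leftLen >= rightLen) r$values[j - 1L] else r$values[j + 1L]
      pos <- sum(r$lengths[seq_len(j - 1L)])
      state[(pos + 1L):(pos + r$lengths[j])] <- newVal
    }
    # split final state runs at artifact boundaries for status reporting
    grp <- cumsum(c(TRUE, diff(state) != 0L | diff(w$artifact) != 0L))
    out <- lapply(split(seq_len(n), grp), function(ii) {
      data.frame(chrom = as.character(seqnames(w))[1L],
                 start = start(w)[ii[1L]], end = end(w)[ii[length(ii)]],
                 copyNumber = state[ii[1L]],
                 meanRatio = mean(w$copyRatio[ii]),
                 status = if (w$artifact[ii[1L]]) "n_artifact" else "real")
    })
    do.call(rbind, out)
  })
  df <- do.call(rbind, segs)
  gr <- GRanges(df$chrom, IRanges(df$start, df$end),
                seqinfo = seqinfo(windows))
  mcols(gr) <- DataFrame(copyNumber = df$copyNumber,
                         meanRatio = df$meanRatio, status = df$status)
  gr <- sort(gr)
  metadata(gr)$baselinePloidy <- as.integer(baselinePloidy)
  gr
}
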