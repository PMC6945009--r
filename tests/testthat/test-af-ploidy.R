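# binomial read sampling around the expected allele-frequency modes of a
# region with nRef reference-like and nDiv divergent haplophases
simulateAFs <- function(nDivSites, nRefSites, nRef, nDiv, depth = 60,
                        mapRate = 1) {
  p1 <- nRef / (nRef + nDiv * mapRate)        # divergent-het sites
  p2 <- (nDiv * mapRate) / (nRef + nDiv * mapRate)  # ref-like-shared sites
  dp <- rpois(nDivSites + nRefSites, depth)
  p <- c(rep(p1, nDivSites), rep(p2, nRefSites))
  adRef <- rbinom(length(dp), dp, p)
  (adRef / pmax(dp, 1))[dp > 0]
}

test_that("reference-allele frequency excludes reference-only deviations", {
  v <- makeVariants(pos = c(10L, 20L, 30L),
                    adRef = c(20L, 0L, 15L), adAlt = c(10L, 30L, 15L))
  af <- refAF(v)
  expect_equal(af, c(20 / 30, 0.5), tolerance = 1e-9)   # 0/30 excluded
  # zero informative reads excluded even with dp > 0
  v0 <- makeVariants(adRef = 0L, adAlt = 0L, dp = 10L)
  expect_length(refAF(v0, minSupport = 0), 0L)
  # indels excluded by default, included on request
  vi <- makeVariants(ref = "ACC", alt = "A", adRef = 10L, adAlt = 10L)
  expect_length(refAF(vi), 0L)
  expect_equal(refAF(vi, includeIndels = TRUE), 0.5)
})

test_that("spectrum bins conserve counts and place 1.0 in the last bin", {
  sp <- buildSpectrum(c(0.5, 0.5, 0.5), nBins = 10)
  expect_equal(spectrumCounts(sp)[6], 3L)   # bin [0.5, 0.6)
  expect_equal(sum(spectrumCounts(sp)), 3L)

  sp1 <- buildSpectrum(c(1.0, 0.999, 0.0), nBins = 10)
  expect_equal(spectrumCounts(sp1)[10], 2L)
  expect_equal(sum(spectrumCounts(sp1)), 3L)

  expect_error(buildSpectrum(numeric(0)), "no usable SNVs")
  expect_error(buildSpectrum(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("uniform draws fill bins within binomial sampling bounds", {
  set.seed(19)
  sp <- buildSpectrum(runif(10000))
  expected <- 10000 / 100
  sdBin <- sqrt(10000 * 0.01 * 0.99)
  expect_true(all(abs(spectrumCounts(sp) - expected) <= 5 * sdBin))
  expect_equal(sum(spectrumCounts(sp)), 10000L)
})

test_that("peak detection localizes a two-Gaussian mixture at 1/3 and 2/3", {
  set.seed(19)
  af <- pmin(pmax(c(rnorm(20000 / 3, 1 / 3, 0.04),
                    rnorm(2 * 20000 / 3, 2 / 3, 0.04)), 0), 1)
  pk <- detectPeaks(buildSpectrum(af))
  expect_equal(nrow(pk), 2L)
  expect_lt(abs(pk$location[1] - 1 / 3), 0.02)
  expect_lt(abs(pk$location[2] - 2 / 3), 0.02)
  expect_gt(pk$height[2], pk$height[1])
})

test_that("peak detection handles spikes, flat spectra and edge exclusion", {
  counts <- rep(0, 100); counts[40] <- 50
  spike <- new("AFSpectrum", binEdges = seq(0, 1, 0.01),
               counts = as.integer(counts), regionLabel = "x")
  pk <- detectPeaks(spike, smoothBw = 1)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$location, 0.395)

  flat <- new("AFSpectrum", binEdges = seq(0, 1, 0.01),
              counts = rep(10L, 100), regionLabel = "x")
  expect_equal(nrow(detectPeaks(flat)), 0L)

  # a spike at the first bin is excluded as an edge artifact
  counts2 <- rep(0, 100); counts2[1] <- 50
  edge <- new("AFSpectrum", binEdges = seq(0, 1, 0.01),
              counts = as.integer(counts2), regionLabel = "x")
  expect_equal(nrow(detectPeaks(edge, smoothBw = 1)), 0L)
})

test_that("expected mode sets are mirror-symmetric under x -> 1 - x", {
  for (k in 2:6) {
    modes <- (1:(k - 1)) / k
    expect_equal(sort(1 - modes), modes)
  }
})

test_that("frequencies all at 0.5 resolve to diploid via the complexity penalty", {
  call <- inferPloidy(rep(0.5, 500))
  expect_equal(ploidy(call), 2L)
  expect_equal(nRefLike(call) + nDivergent(call), ploidy(call))
})

test_that("triploid and tetraploid allele-frequency patterns are recovered", {
  set.seed(4)
  # 2 reference-like + 1 divergent: peaks near 1/3 and 2/3, 2/3 dominant
  af3 <- simulateAFs(5000, 500, nRef = 2, nDiv = 1)
  call3 <- inferPloidy(af3)
  expect_equal(ploidy(call3), 3L)
  expect_equal(nRefLike(call3), 2L)
  expect_equal(nDivergent(call3), 1L)
  # 3 reference-like + 1 divergent: peaks near 1/4 and 3/4
  af4 <- simulateAFs(3000, 300, nRef = 3, nDiv = 1)
  call4 <- inferPloidy(af4)
  expect_equal(ploidy(call4), 4L)
  expect_equal(nRefLike(call4), 3L)
  expect_error(inferPloidy(af3[1:50]), "usable allele frequencies")
})

test_that("per-segment calls match depth copy numbers on simulated data", {
  sim <- simulateGenome(smallSimConfig(seed = 12))
  kept <- suppressWarnings(filterVariants(sim$variants))$kept
  win <- maskArtifacts(normalizeWindows(windowDepth(sim$depth, sim$refIndex,
                                                    window = 20000L)))
  segs <- segmentCopyNumber(win, 3)
  sp <- segmentPloidy(kept, segs)
  rep <- sp$report
  expect_equal(rep$ploidy[rep$regionLabel == "global"], 3L)
  segRow <- rep[rep$copyNumber == 4L, ]
  expect_equal(nrow(segRow), 1L)
  expect_equal(segRow$ploidy, 4L)
  expect_equal(segRow$nRefLike, 3L)
  expect_true(all(rep$consistent, na.rm = TRUE))
  # spectrum conservation: counts sum to usable SNVs of the region
  afs <- refAF(kept)
  expect_equal(sum(spectrumCounts(buildSpectrum(afs))), length(afs))
})

test_that("segments without enough variants are skipped, not called", {
  v <- makeVariants(pos = seq(10L, 1000L, by = 10L))
  segs <- GRanges(c("chr01", "chr01"), IRanges(c(1L, 2001L), c(2000L, 3000L)))
  mcols(segs) <- DataFrame(copyNumber = c(3L, 4L), meanRatio = c(1, 4 / 3),
                           status = "real")
  S4Vectors::metadata(segs)$baselinePloidy <- 3L
  expect_warning(sp <- segmentPloidy(v, segs, minSites = 20L), "skipped")
  rep <- sp$report
  expect_equal(rep$note[rep$copyNumber == 4L], "insufficient sites")
  expect_true(is.na(rep$ploidy[rep$copyNumber == 4L]))
})
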