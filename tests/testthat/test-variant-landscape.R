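# a 3-codon-per-exon toy gene on a hand-written chromosome:
# + strand CDS 11..22 codes ATG TAC GGG TGA
toyGene <- function(strand = "+") {
  pre <- "GGGGGGGGGG"
  orf <- "ATGTACGGGTGA"
  post <- "GGGGGGGGGG"
  if (strand == "+") {
    seqs <- Biostrings::DNAStringSet(paste0(pre, orf, post))
  } else {
    seqs <- Biostrings::DNAStringSet(paste0(
      pre, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(orf))), post))
  }
  names(seqs) <- "chrT"
  cds <- GRanges("chrT", IRanges(11L, 22L), strand = strand, phase = 0L)
  genes <- GenomicRanges::GRangesList(gx = cds)
  list(seqs = seqs, genes = genes)
}

test_that("density track counts each variant once in its anchor window", {
  fa <- writeFasta(list(chrD = strrep("A", 200000)))
  ri <- readReference(fa)
  v <- makeVariants(chrom = "chrD", pos = c(10L, 50000L, 99999L, 100000L),
                    alt = "T")
  d <- densityTrack(v, ri, window = 100000L)
  expect_equal(d$snvCount, c(4L, 0L))   # pos 100000 (1-based) is window 1
  expect_equal(sum(d$snvCount) + sum(d$indelCount), length(v))

  vBad <- makeVariants(chrom = "chrD", pos = 300000L)
  expect_error(densityTrack(vBad, ri), "beyond chromosome end")
  # SNVs and InDels are counted on separate tracks
  vm <- makeVariants(chrom = "chrD", pos = c(10L, 20L), ref = c("A", "ACC"),
                     alt = c("T", "A"))
  dm <- densityTrack(vm, ri, window = 100000L)
  expect_equal(dm$snvCount[1], 1L)
  expect_equal(dm$indelCount[1], 1L)
})

test_that("mod-3 fractions count frame-preserving InDels per class", {
  tg <- toyGene()
  cdsLens <- c(3L, 6L, 3L, 1L)
  nonLens <- 1:6
  v <- makeVariants(
    chrom = "chrT",
    pos = c(rep(12L, 4), rep(25L, 6)),   # 12 inside CDS, 25 outside
    ref = c(vapply(c(cdsLens, nonLens), function(l)
      paste(rep("A", l + 1L), collapse = ""), character(1))),
    alt = "A")
  res <- indelMod3Bias(v, tg$genes)
  expect_equal(res$pCds, 0.75)
  expect_equal(res$pNoncds, 1 / 3)
  expect_equal(res$nCds, 4L)
  expect_equal(res$method, "fisher")
  # empty class: no CDS indels
  res0 <- indelMod3Bias(v[5:10], tg$genes)
  expect_true(is.na(res0$pCds))
  expect_null(res0$test)
})

test_that("generator enrichment produces a positive CDS bias, null does not", {
  set.seed(77)
  pos <- replicate(20, {
    lc <- sampleIndelLengths(60, 12, 3, 0.35)
    ln <- sampleIndelLengths(2000, 12, 1, 0.35)
    mean(lc %% 3 == 0) - mean(ln %% 3 == 0)
  })
  expect_gte(mean(pos > 0), 0.95)
  # identical distributions: difference within 3 sd of sampling noise
  set.seed(78)
  lc <- sampleIndelLengths(2000, 12, 1, 0.35)
  ln <- sampleIndelLengths(2000, 12, 1, 0.35)
  p <- mean(c(lc, ln) %% 3 == 0)
  sdDiff <- sqrt(p * (1 - p) * (1 / 2000 + 1 / 2000))
  expect_lt(abs(mean(lc %% 3 == 0) - mean(ln %% 3 == 0)), 3 * sdDiff)
})

test_that("effect classes follow codon logic on the plus strand", {
  tg <- toyGene("+")
  # 2 bp insertion inside CDS -> frameshift
  v1 <- makeVariants(chrom = "chrT", pos = 12L, ref = "T", alt = "TAA")
  expect_equal(classifyEffects(v1, tg$genes, tg$seqs)$effect, "frameshift")
  # 3 bp deletion inside CDS -> not a frameshift
  v2 <- makeVariants(chrom = "chrT", pos = 12L, ref = "TGTA", alt = "T")
  expect_equal(classifyEffects(v2, tg$genes, tg$seqs)$effect, "other")
  # TAC -> TAA mid-CDS: stop gained (codon 2 position 3 is chromosome pos 16)
  v3 <- makeVariants(chrom = "chrT", pos = 16L, ref = "C", alt = "A")
  expect_equal(classifyEffects(v3, tg$genes, tg$seqs)$effect, "stop_gained")
  # TGA -> CGA at the annotated stop: stop lost (pos 20)
  v4 <- makeVariants(chrom = "chrT", pos = 20L, ref = "T", alt = "C")
  expect_equal(classifyEffects(v4, tg$genes, tg$seqs)$effect, "stop_lost")
  # synonymous-ish SNV -> other; outside CDS -> other with no gene
  v5 <- makeVariants(chrom = "chrT", pos = 18L, ref = "G", alt = "A")
  expect_equal(classifyEffects(v5, tg$genes, tg$seqs)$effect, "other")
  v6 <- makeVariants(chrom = "chrT", pos = 2L, ref = "G", alt = "A")
  res6 <- classifyEffects(v6, tg$genes, tg$seqs)
  expect_equal(res6$effect, "other")
  expect_true(is.na(res6$geneId))
})

test_that("effect classes are identical on the reverse-complement mirror", {
  plus <- toyGene("+"); minus <- toyGene("-")
  L <- 32L  # chromosome length; position x mirrors to L - x + 1
  cases <- list(c(16L, "C", "A"), c(20L, "T", "C"), c(18L, "G", "A"),
                c(13L, "G", "A"))
  for (cs in cases) {
    pos <- as.integer(cs[1])
    vP <- makeVariants(chrom = "chrT", pos = pos, ref = cs[2], alt = cs[3])
    effP <- classifyEffects(vP, plus$genes, plus$seqs)$effect
    comp <- function(b) chartr("ACGT", "TGCA", b)
    vM <- makeVariants(chrom = "chrT", pos = L - pos + 1L,
                       ref = comp(cs[2]), alt = comp(cs[3]))
    effM <- classifyEffects(vM, minus$genes, minus$seqs)$effect
    expect_equal(effM, effP)
  }
})

test_that("classification agrees with a translate-and-diff oracle on random variants", {
  sim <- simulateGenome(smallSimConfig(seed = 9))
  set.seed(9)
  nChecked <- 0L
  mism <- list()
  for (gid in sample(names(sim$genes), 20)) {
    cds <- sim$genes[[gid]]
    chromName <- as.character(seqnames(cds))[1]
    chromSeq <- sim$reference[[chromName]]
    for (rep in 1:15) {
      iv <- cds[sample.int(length(cds), 1)]
      kind <- sample(c("snv", "ins", "del"), 1, prob = c(0.6, 0.2, 0.2))
      if (kind == "snv") {
        pos <- sample(start(iv):end(iv), 1)
        ref <- as.character(Biostrings::subseq(chromSeq, pos, pos))
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      } else if (kind == "ins") {
        pos <- sample(start(iv):(end(iv) - 1L), 1)
        ref <- as.character(Biostrings::subseq(chromSeq, pos, pos))
        alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"),
                                        sample(1:6, 1), replace = TRUE),
                                 collapse = ""))
      } else {
        len <- sample(1:6, 1)
        if (end(iv) - start(iv) < len + 1L) next
        pos <- sample(start(iv):(end(iv) - len - 1L), 1)
        ref <- as.character(Biostrings::subseq(chromSeq, pos, pos + len))
        alt <- substr(ref, 1, 1)
      }
      v <- makeVariants(chrom = chromName, pos = pos, ref = ref, alt = alt)
      got <- classifyEffects(v, sim$genes[gid], sim$reference)$effect
      want <- oracleEffect(pos, ref, alt, cds = sim$genes[[gid]],
                           chromSeq = chromSeq)
      nChecked <- nChecked + 1L
      if (!identical(got, want))
        mism[[length(mism) + 1L]] <- c(gid, pos, ref, alt, got, want)
    }
  }
  expect_gte(nChecked, 250L)
  expect_equal(mism, list())
})
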