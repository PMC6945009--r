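test_that("N-gap indexing finds maximal N-runs above the length threshold", {
  fa <- writeFasta(list(chrA = "ACGTNNNNNNNNNNACGT"))
  ri <- readReference(fa, minGap = 10)
  expect_equal(unname(chromLengths(ri)), 18L)
  expect_equal(start(nGaps(ri)), 5L)   # 0-based [4, 14)
  expect_equal(end(nGaps(ri)), 14L)

  fa2 <- writeFasta(list(chrA = "ACGTACGTACGT"))
  expect_length(nGaps(readReference(fa2, minGap = 2)), 0L)

  fa3 <- writeFasta(list(c1 = strrep("A", 1000), c2 = strrep("C", 2000)))
  ri3 <- readReference(fa3)
  expect_equal(length(chromNames(ri3)), 2L)
  expect_equal(sum(chromLengths(ri3)), 3000L)
})

test_that("reference reading rejects duplicate names and empty files", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chrA", "ACGT", ">chrA", "AAAA"), fa)
  expect_error(readReference(fa), "duplicate")
  empty <- tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_error(readReference(empty))
})

test_that("N-gap detection matches a brute-force scan on random sequences", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(500:10000, 1)
    s <- sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
                prob = c(0.2, 0.2, 0.2, 0.2, 0.2))
    str <- paste(s, collapse = "")
    minGap <- sample(1:5, 1)
    ri <- readReference(writeFasta(list(chrX = str)), minGap = minGap)
    m <- gregexpr("N+", str)[[1L]]
    keep <- attr(m, "match.length") >= minGap & m[1L] != -1
    expect_equal(start(nGaps(ri)), as.integer(m[keep]))
    expect_equal(width(nGaps(ri)), attr(m, "match.length")[keep])
  }
})

test_that("VCF records are split per alt allele with matching allele depths", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr01,length=1000>",
    '##INFO=<ID=QD,Number=1,Type=Float,Description="x">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="x">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="x">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="x">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="x">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="x">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr01\t10\t.\tA\tT,G\t50\t.\tQD=20;FS=1;MQ=55\tGT:AD:DP\t0/1:20,10,5:40",
    "chr01\t20\t.\tA\tAT\t50\t.\tQD=20;FS=1;MQ=55\tGT:AD:DP\t0/1:20,10:30",
    "chr01\t30\t.\tC\tG\t50\t.\tQD=20;MQ=55\tGT:AD:DP\t0/1:20,10:30"), vcf)
  v <- readVcfRecords(vcf)
  expect_length(v, 4L)           # multi-allelic split into two records
  expect_equal(v$adRef[1:2], c(20L, 20L))
  expect_equal(v$adAlt[1:2], c(10L, 5L))
  expect_equal(v$dp[1], 40L)
  expect_equal(v$vtype, c("SNV", "SNV", "InDel", "SNV"))
  expect_equal(v$indelLen[3], 1L)
  # missing FS is flagged, not defaulted
  expect_true(v$annoMissing[4])
  expect_false(any(v$annoMissing[1:3]))
})

test_that("malformed VCF input raises an informative error", {
  bad <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr01\tnotanumber\t.\tA\tT\t.\t.\t."), bad)
  expect_error(readVcfRecords(bad), "line 3")
  expect_error(readVcfRecords(tempfile()), "not found")
})

test_that("VCF writer round-trips through the reader", {
  gr <- makeVariants(pos = c(10L, 50L), ref = c("A", "ACC"),
                     alt = c("T", "A"), qd = c(30, 25), fs = c(1.5, 3),
                     mq = c(55, 50), adRef = c(20L, 8L), adAlt = c(10L, 30L))
  f <- tempfile(fileext = ".vcf")
  writeVcfRecords(gr, f)
  back <- readVcfRecords(f)
  expect_equal(start(back), start(gr))
  expect_equal(back$ref, gr$ref)
  expect_equal(back$alt, gr$alt)
  expect_equal(back$adRef, gr$adRef)
  expect_equal(back$adAlt, gr$adAlt)
  expect_equal(back$dp, gr$dp)
  expect_equal(back$qd, gr$qd, tolerance = 0.01)
  expect_equal(back$vtype, gr$vtype)
})

test_that("BED output is 0-based half-open and round-trips", {
  gr <- GRanges("chr02", IRanges(10000001, 16200000))
  f <- tempfile(fileext = ".bed")
  writeBed(gr, f)
  expect_equal(readLines(f), "chr02\t10000000\t16200000")

  writeBed(GRanges(), f)
  expect_length(readLines(f), 0L)

  set.seed(3)
  gr3 <- GRanges(sample(c("c1", "c2"), 3, replace = TRUE),
                 IRanges(start = sample.int(1e6, 3), width = sample.int(1e4, 3)))
  writeBed(gr3, f)
  back <- readBed(f)
  expect_equal(as.character(seqnames(back)), as.character(seqnames(gr3)))
  expect_equal(ranges(back), ranges(gr3))
})

test_that("TSV writer/reader are inverse and depth layouts are detected", {
  df <- data.frame(chrom = c("c1", "c1"), pos = c(1L, 2L), depth = c(5L, 7L))
  f <- tempfile(fileext = ".tsv")
  writeTsv(df, f)
  back <- readTsv(f)
  expect_equal(as.data.frame(back), df)

  writeTsv(df, f)
  d3 <- readDepth(f)
  expect_false(attr(d3, "binned"))
  expect_equal(names(d3), c("chrom", "pos", "depth"))

  writeTsv(data.frame(chrom = "c1", start = 0L, end = 100L, depth = 12.5), f)
  d4 <- readDepth(f)
  expect_true(attr(d4, "binned"))
  expect_error(readDepth(tempfile()), "not found")
})

test_that("gene models group CDS intervals per gene with strand and phase", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
    "c1\tsrc\tgene\t100\t400\t.\t+\t.\tID=g1",
    "c1\tsrc\tCDS\t100\t199\t.\t+\t0\tParent=g1",
    "c1\tsrc\tCDS\t300\t400\t.\t+\t2\tParent=g1",
    "c1\tsrc\tgene\t500\t600\t.\t-\t.\tID=g2",
    "c1\tsrc\tCDS\t500\t600\t.\t-\t0\tParent=g2"), gff)
  g <- readGeneModels(gff)
  expect_setequal(names(g), c("g1", "g2"))
  expect_length(g[["g1"]], 2L)
  expect_equal(g[["g1"]]$phase, c(0L, 2L))
  expect_equal(as.character(strand(g[["g2"]])), "-")
})
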