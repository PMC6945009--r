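suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
  library(Biostrings)
})

# write a FASTA from named sequences, return the path
writeFasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n),
                                                      seqs[[n]]))), path)
  path
}

# variant records in the package's internal layout, from plain vectors;
# defaults give a clean passing SNV
makeVariants <- function(chrom = "chr01", pos = 100L, ref = "A", alt = "T",
                         qd = 30, fs = 1, mq = 55, adRef = 20L, adAlt = 10L,
                         dp = adRef + adAlt, gt = NULL) {
  n <- max(lengths(list(chrom, pos, ref, alt, qd, fs, mq, adRef, adAlt)))
  r <- function(x) rep_len(x, n)
  ref <- r(ref); alt <- r(alt)
  vtype <- ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
                  ifelse(nchar(ref) != nchar(alt), "InDel", "MNV"))
  gr <- GRanges(r(chrom), IRanges(r(pos), width = nchar(ref)))
  mcols(gr) <- DataFrame(ref = ref, alt = alt, vtype = vtype,
                         indelLen = abs(nchar(alt) - nchar(ref)),
                         qd = r(qd), fs = r(fs), mq = r(mq),
                         adRef = r(adRef), adAlt = r(adAlt), dp = r(dp),
                         annoMissing = is.na(r(qd)) | is.na(r(fs)) |
                           is.na(r(mq)))
  if (!is.null(gt)) gr$gt <- r(gt)
  gr
}

# windows GRanges with given copy ratios / flags, for segmentation tests
makeWindows <- function(ratios, chrom = "chrA", window = 1000L,
                        nFraction = 0, artifact = FALSE,
                        meanDepth = ratios * 60) {
  n <- length(ratios)
  si <- Seqinfo(chrom, n * window)
  gr <- GRanges(chrom, IRanges((seq_len(n) - 1L) * window + 1L,
                               seq_len(n) * window), seqinfo = si)
  mcols(gr) <- DataFrame(meanDepth = meanDepth, nFraction = rep_len(nFraction, n),
                         copyRatio = ratios,
                         artifact = rep_len(artifact, n))
  metadata(gr)$window <- window
  gr
}

# scaled-down simulation for fast unit tests: 3 x 600 kb, 200 kb duplication,
# one 40 kb N-gap; analyse with 20 kb windows
smallSimConfig <- function(seed = 1, ...) {
  simConfig(seed = seed,
            chromosomes = data.frame(name = c("chr01", "chr02", "chr03"),
                                     length = rep(600000L, 3)),
            duplication = list(chrom = "chr02", start = 200001L,
                               end = 400000L, source = "ref_like"),
            nGaps = GRanges("chr01", IRanges(100001L, 140000L)),
            genes = list(count = 40L, meanCdsLength = 900L),
            ...)
}

# brute-force hard-filter oracle: direct evaluation of the stated predicates
bruteFilterKeep <- function(gr, minSupport = 5) {
  m <- mcols(gr)
  support <- m$adRef + m$adAlt
  ifelse(is.na(m$qd) | is.na(m$fs) | (m$vtype == "SNV" & is.na(m$mq)),
         FALSE,
         ifelse(m$vtype == "SNV",
                !(m$qd < 2.0) & !(m$fs > 60.0) & !(m$mq < 40) &
                  support >= minSupport,
                !(m$qd < 2.0) & !(m$fs > 200.0) & m$indelLen <= 100 &
                  support >= minSupport))
}

# random variant records spanning both types and all failure modes
randomVariantSet <- function(n, seed = 1) {
  set.seed(seed)
  isSnv <- runif(n) < 0.7
  len <- ifelse(isSnv, 0L, sample(c(1:120), n, replace = TRUE))
  ref <- ifelse(isSnv, "A", vapply(len, function(l)
    paste(c("A", rep("C", l)), collapse = ""), character(1)))
  adRef <- sample(0:40, n, replace = TRUE)
  adAlt <- sample(0:40, n, replace = TRUE)
  makeVariants(chrom = "chr01", pos = sample.int(1e6, n), ref = ref,
               alt = "T",
               qd = round(runif(n, 0, 5), 2),
               fs = round(runif(n, 0, 250), 1),
               mq = round(runif(n, 20, 60), 1),
               adRef = adRef, adAlt = adAlt, dp = adRef + adAlt)
}

# translate-and-diff oracle for effect classification: apply the edit to the
# chromosome sequence, shift CDS intervals downstream of the edit, re-extract
# and translate the CDS, and classify from the protein difference
oracleEffect <- function(pos, ref, alt, cds, chromSeq) {
  seqChars <- strsplit(as.character(chromSeq), "")[[1L]]
  stopifnot(paste(seqChars[pos:(pos + nchar(ref) - 1L)], collapse = "") == ref)
  mutChars <- c(seqChars[seq_len(pos - 1L)], strsplit(alt, "")[[1L]],
                seqChars[seq.int(pos + nchar(ref), length(seqChars))])
  delta <- nchar(alt) - nchar(ref)
  st <- start(cds); en <- end(cds)
  # anchor-based VCF edits: bases after position pos + nchar(ref) - 1 shift
  editEnd <- pos + nchar(ref) - 1L
  st2 <- ifelse(st > editEnd, st + delta, st)
  en2 <- ifelse(en >= editEnd & en >= pos, en + delta, en)
  extract <- function(chars, s, e) {
    o <- order(s)
    paste(unlist(Map(function(a, b) chars[a:b], s[o], e[o])), collapse = "")
  }
  refCds <- extract(seqChars, st, en)
  mutCds <- extract(mutChars, st2, en2)
  minus <- as.character(strand(cds))[1L] == "-"
  if (minus) {
    rc <- function(x) as.character(reverseComplement(DNAString(x)))
    refCds <- rc(refCds); mutCds <- rc(mutCds)
  }
  if (nchar(mutCds) %% 3L != nchar(refCds) %% 3L) return("frameshift")
  tr <- function(x) strsplit(as.character(suppressWarnings(
    translate(DNAString(substr(x, 1, 3 * (nchar(x) %/% 3)))))), "")[[1L]]
  pr <- tr(refCds); pm <- tr(mutCds)
  nAA <- length(pr)
  if (length(pm) == nAA) {
    changed <- which(pr != pm)
    for (i in changed) {
      if (i < nAA && pm[i] == "*" && pr[i] != "*") return("stop_gained")
      if (i == nAA && pr[i] == "*" && pm[i] != "*") return("stop_lost")
    }
  }
  "other"
}
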