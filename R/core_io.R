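#' Build a ReferenceIndex from a FASTA file
#'
#' Reads a reference assembly, records chromosome names and lengths, and
#' indexes maximal runs of ambiguous bases (N) of at least `minGap` bp.
#' These N-gaps are later used to mask pseudo low-coverage regions: windows
#' that look like deletions only because reads cannot map onto N-stretches.
#'
#' @param fastaPath path to a FASTA file over the alphabet ACGTN
#'   (case-insensitive).
#' @param minGap minimum N-run length (bp) indexed as a gap.  Shorter runs
#'   are ignored.
#' @param centromeres optional `GRanges` (or path to a BED file) of
#'   centromere positions.
#' @return a [ReferenceIndex].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chrA", "ACGTNNNNNNNNNNACGT"), fa)
#' ri <- readReference(fa, minGap = 10)
#' nGaps(ri)  # one 10 bp gap at 5..14
#' @export
readReference <- function(fastaPath, minGap = 100, centromeres = NULL) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  if (length(seqs) == 0L)
    stop("empty FASTA file: ", fastaPath)
  nms <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nms))
    stop("duplicate sequence name in FASTA: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(seqs) <- nms
  si <- Seqinfo(seqnames = nms, seqlengths = width(seqs))
  gapList <- lapply(seq_along(seqs), function(i) {
    r <- IRanges::reduce(as(Biostrings::matchPattern("N", seqs[[i]],
                                                     fixed = TRUE), "IRanges"))
    r[width(r) >= minGap]
  })
  nGap <- GRanges(rep(nms, lengths(gapList)),
                  unlist(IRanges::IRangesList(gapList)), seqinfo = si)
  cen <- GRanges(seqinfo = si)
  if (!is.null(centromeres)) {
    if (is.character(centromeres)) centromeres <- readBed(centromeres)
    cen <- GRanges(seqnames(centromeres), ranges(centromeres), seqinfo = si)
  }
  new("ReferenceIndex", seqinfo = si, nGaps = nGap, centromeres = cen)
}

#' Read variant records from a VCF file
#'
#' Parses a VCF 4.x with GATK-style INFO annotations (QD, FS, MQ) and a
#' single sample carrying FORMAT AD and DP.  Multi-allelic records are split
#' into one record per alternate allele with the matching allele depth.
#' Records missing any of QD/FS/MQ are flagged (`annoMissing`) rather than
#' silently defaulted; downstream filtering removes them with an explicit
#' reason.
#'
#' @param vcfPath path to a VCF (plain or bgzipped).
#' @return a `GRanges`, one range per (record, alt allele), with metadata
#'   columns `ref`, `alt`, `vtype` (`"SNV"`, `"InDel"` or `"MNV"`),
#'   `indelLen`, `qd`, `fs`, `mq`, `adRef`, `adAlt`, `dp`, `annoMissing`.
#'   Range start is the 1-based VCF POS; width is `nchar(ref)`.
#' @export
readVcfRecords <- function(vcfPath) {
  if (!file.exists(vcfPath)) stop("VCF not found: ", vcfPath)
  if (!grepl("\\.gz$", vcfPath)) .validateVcfLines(vcfPath)
  v <- tryCatch(VariantAnnotation::readVcf(vcfPath),
                error = function(e) stop("malformed VCF '", vcfPath, "': ",
                                         conditionMessage(e), call. = FALSE))
  if (ncol(v) > 1L) {
    warning("VCF has ", ncol(v), " samples; using the first")
    v <- v[, 1L]
  }
  ve <- VariantAnnotation::expand(v)
  rr <- SummarizedExperiment::rowRanges(ve)
  n <- length(rr)
  ref <- as.character(VariantAnnotation::ref(ve))
  alt <- as.character(VariantAnnotation::alt(ve))
  vtype <- ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
                  ifelse(nchar(ref) != nchar(alt), "InDel", "MNV"))
  getInfo <- function(key) {
    if (key %in% colnames(VariantAnnotation::info(ve)))
      as.numeric(VariantAnnotation::info(ve)[[key]])
    else rep(NA_real_, n)
  }
  qd <- getInfo("QD"); fs <- getInfo("FS"); mq <- getInfo("MQ")
  gen <- VariantAnnotation::geno(ve)
  if (!all(c("AD", "DP") %in% names(gen)))
    stop("VCF must carry FORMAT fields AD and DP")
  ad <- gen$AD
  adRef <- as.integer(ad[, 1L, 1L]); adAlt <- as.integer(ad[, 1L, 2L])
  dp <- as.integer(gen$DP[, 1L])
  gr <- GRanges(seqnames(rr), ranges(rr))
  mcols(gr) <- DataFrame(ref = ref, alt = alt, vtype = vtype,
                         indelLen = abs(nchar(alt) - nchar(ref)),
                         qd = qd, fs = fs, mq = mq,
                         adRef = adRef, adAlt = adAlt, dp = dp,
                         annoMissing = is.na(qd) | is.na(fs) | is.na(mq))
  gr
}

# coordinate/allele sanity check so malformed records fail with the line
# number instead of being silently coerced downstream
.validateVcfLines <- function(vcfPath) {
  lines <- readLines(vcfPath)
  body <- which(!startsWith(lines, "#"))
  if (!length(body)) return(invisible(TRUE))
  parts <- strsplit(lines[body], "\t", fixed = TRUE)
  short <- lengths(parts) < 8L
  if (any(short))
    stop("malformed VCF record (fewer than 8 fields) at line ",
         body[which(short)[1L]], " of ", vcfPath)
  pos <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  badPos <- !is.finite(pos) | pos < 1 | pos != floor(pos)
  if (any(badPos))
    stop("malformed coordinate at line ", body[which(badPos)[1L]],
         " of ", vcfPath)
  ref <- vapply(parts, `[[`, character(1), 4L)
  alt <- vapply(parts, `[[`, character(1), 5L)
  badAll <- !grepl("^[ACGTNacgtn]+$", ref) |
    !grepl("^(\\.|\\*|[ACGTNacgtn]+)(,(\\*|[ACGTNacgtn]+))*$", alt)
  if (any(badAll))
    stop("malformed allele at line ", body[which(badAll)[1L]],
         " of ", vcfPath)
  invisible(TRUE)
}

#' Write variant records as a VCF 4.2 file
#'
#' Inverse of [readVcfRecords()] for the record layout this package uses:
#' single sample, INFO QD/FS/MQ, FORMAT GT:AD:DP.  Used by the simulator and
#' to emit the filtered call set.
#'
#' @param variants a `GRanges` as returned by [readVcfRecords()].  An
#'   optional metadata column `gt` supplies genotypes (default `"0/1"`).
#' @param path output path.
#' @param sampleName sample column name.
#' @param refIndex optional [ReferenceIndex] used to write contig header
#'   lines.
#' @return `path`, invisibly.
#' @export
writeVcfRecords <- function(variants, path, sampleName = "SAMPLE",
                            refIndex = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=ploidyscan")
  if (!is.null(refIndex))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          chromNames(refIndex),
                          unname(chromLengths(refIndex))))
  hdr <- c(hdr,
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand bias (phred)">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sampleName, sep = "\t"))
  m <- mcols(variants)
  fmtNum <- function(x) ifelse(is.na(x), NA, formatC(x, format = "f",
                                                     digits = 2))
  keys <- cbind(QD = fmtNum(m$qd), FS = fmtNum(m$fs), MQ = fmtNum(m$mq))
  info <- apply(keys, 1L, function(r) {
    r <- r[!is.na(r)]
    if (!length(r)) "." else paste(names(r), r, sep = "=", collapse = ";")
  })
  gt <- if (!is.null(m$gt)) m$gt else rep("0/1", length(variants))
  body <- paste(as.character(seqnames(variants)), start(variants), ".",
                m$ref, m$alt, ".", ".", info, "GT:AD:DP",
                paste0(gt, ":", m$adRef, ",", m$adAlt, ":", m$dp),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a depth track
#'
#' Accepts a samtools-depth-like 3-column TSV (chrom, 1-based position,
#' depth) or a pre-binned 4-column TSV (chrom, 0-based bin start, bin end,
#' mean depth).  A header row is detected automatically.
#'
#' @param path TSV path.
#' @return a `data.table`: per-position layout has columns `chrom`, `pos`,
#'   `depth`; binned layout has `chrom`, `start`, `end`, `depth` with
#'   attribute `binned = TRUE`.
#' @export
readDepth <- function(path) {
  if (!file.exists(path)) stop("depth file not found: ", path)
  dt <- data.table::fread(path)
  if (ncol(dt) == 3L) {
    data.table::setnames(dt, c("chrom", "pos", "depth"))
    data.table::setattr(dt, "binned", FALSE)
  } else if (ncol(dt) == 4L) {
    data.table::setnames(dt, c("chrom", "start", "end", "depth"))
    data.table::setattr(dt, "binned", TRUE)
  } else stop("depth TSV must have 3 (per-position) or 4 (binned) columns")
  dt
}

#' Write/read intervals as BED
#'
#' BED output is 0-based half-open; internal `GRanges` are 1-based closed,
#' so the conversion happens here and only here.  Metadata columns are
#' appended after the three coordinate columns (BED+ style) and restored on
#' reading when `extraCols` is given.
#'
#' @param gr a `GRanges`; metadata columns become extra BED columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @examples
#' gr <- GenomicRanges::GRanges("chr02", IRanges::IRanges(10000001, 16200000))
#' f <- tempfile(fileext = ".bed")
#' writeBed(gr, f)
#' readLines(f)  # "chr02\t10000000\t16200000"
#' @export
writeBed <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   as.data.frame(mcols(gr)), check.names = FALSE)
  ok <- tryCatch({
    data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write BED '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' @rdname writeBed
#' @param extraCols character vector naming metadata columns stored beyond
#'   the third BED column.
#' @export
readBed <- function(path, extraCols = character()) {
  if (!file.exists(path)) stop("BED not found: ", path)
  dt <- data.table::fread(path, header = FALSE)
  if (nrow(dt) == 0L) return(GRanges())
  gr <- GRanges(dt[[1L]], IRanges(dt[[2L]] + 1L, dt[[3L]]))
  if (length(extraCols)) {
    ex <- dt[, -(1:3), drop = FALSE]
    data.table::setnames(ex, extraCols[seq_len(ncol(ex))])
    mcols(gr) <- DataFrame(as.data.frame(ex))
  }
  gr
}

#' Write/read a TSV table with header
#'
#' @param x a data.frame-like table.
#' @param path file path.
#' @return `path` invisibly for the writer; a `data.table` for the reader.
#' @export
writeTsv <- function(x, path) {
  tryCatch(data.table::fwrite(as.data.frame(x), path, sep = "\t"),
           error = function(e) stop("cannot write TSV '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
  if (!file.exists(path)) stop("TSV not found: ", path)
  data.table::fread(path)
}

#' Read gene models (CDS structure) from GFF3
#'
#' Extracts CDS features and groups them by their parent gene/transcript,
#' keeping strand and phase.  One model per parent; CDS intervals are stored
#' in ascending genomic order.
#'
#' @param gffPath path to a GFF3 file with CDS features carrying `Parent`
#'   (or `ID`) attributes.
#' @return a named `GRangesList`, one element of CDS ranges per gene, each
#'   with a `phase` metadata column.
#' @export
readGeneModels <- function(gffPath) {
  g <- rtracklayer::import(gffPath)
  cds <- g[tolower(as.character(g$type)) == "cds"]
  if (length(cds) == 0L) stop("no CDS features in ", gffPath)
  par <- if (!is.null(cds$Parent) && any(lengths(cds$Parent) > 0L))
    vapply(cds$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
           character(1))
  else cds$ID
  if (any(is.na(par))) stop("CDS feature without Parent/ID in ", gffPath)
  mcols(cds) <- DataFrame(phase = if (!is.null(cds$phase)) cds$phase
                          else rep(0L, length(cds)))
  grl <- S4Vectors::split(cds, par)
  grl <- S4Vectors::endoapply(grl, function(x) x[order(start(x))])
  grl
}
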