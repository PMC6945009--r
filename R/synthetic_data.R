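#' Simulation configuration for a polyploid resequencing sample
#'
#' Describes the generative model behind the package's synthetic data: a
#' k-ploid sample in which `nRefLike` haplophases are nearly identical to
#' the reference and the remaining haplophases are divergent (carrying
#' variants at a much higher per-bp rate); one optional segmental
#' duplication adds an extra copy of one haplophase class; read depth is
#' drawn per position proportional to local copy number, with the divergent
#' haplophases' contribution thinned by a mapping-rate penalty; allele
#' depths at variant sites are binomial in the local haplophase dosage.
#' Reads themselves are never generated — the pipeline starts at VCF +
#' depth, so depth and allele depths are sampled directly.
#'
#' @slot seed RNG seed.
#' @slot chromosomes `data.frame` with columns `name`, `length` (bp).
#' @slot baselinePloidy genome-wide copy number k.
#' @slot nRefLike reference-like haplophases (< `baselinePloidy`).
#' @slot divergentSnvRate,refLikeSnvRate,homAltSnvRate per-bp SNV rates for
#'   sites heterozygous in the divergent class, sites where all
#'   reference-like copies share an alternate allele, and sites where every
#'   haplophase carries the alternate (the reference deviates from an
#'   invariant sample position).
#' @slot duplication `list(chrom, start, end, source)` (1-based closed;
#'   `source` is `"ref_like"` or `"divergent"`), or an empty list for none.
#' @slot depthPerCopy mean reads per haplotype copy.
#' @slot depthModel `"poisson"` or `"negative_binomial"`.
#' @slot nbDispersion negative-binomial size parameter.
#' @slot divergentMapRate mapping-rate multiplier in (0, 1] applied to
#'   divergent copies for both depth and allele-depth sampling.
#' @slot nGaps `GRanges` of N-stretches written into the reference.
#' @slot genes `list(count, meanCdsLength)` for the synthetic gene models.
#' @slot indelRate per-bp InDel rate.
#' @slot indelMaxLen maximum InDel length.
#' @slot indelGeomP geometric length parameter (P(len) ~ dgeom(len - 1)).
#' @slot cdsMod3Enrichment multiplier on the probability of frame-preserving
#'   (mod-3) lengths for InDels inside CDS.
#' @slot failFrac fraction of VCF records drawn with failing QD/FS/MQ
#'   annotations to exercise the hard filter.
#'
#' @seealso [simConfig()], [simulateGenome()]
#' @export
setClass("SimConfig",
  slots = c(seed = "numeric", chromosomes = "data.frame",
            baselinePloidy = "integer", nRefLike = "integer",
            divergentSnvRate = "numeric", refLikeSnvRate = "numeric",
            homAltSnvRate = "numeric", duplication = "list",
            depthPerCopy = "numeric", depthModel = "character",
            nbDispersion = "numeric", divergentMapRate = "numeric",
            nGaps = "GRanges", genes = "list", indelRate = "numeric",
            indelMaxLen = "integer", indelGeomP = "numeric",
            cdsMod3Enrichment = "numeric", failFrac = "numeric"))

setValidity("SimConfig", function(object) {
  ch <- object@chromosomes
  if (!all(c("name", "length") %in% names(ch)))
    return("chromosomes needs columns 'name' and 'length'")
  if (anyDuplicated(ch$name)) return("duplicate chromosome names")
  if (any(ch$length < 1)) return("zero-length chromosome")
  if (object@nRefLike >= object@baselinePloidy)
    return("nRefLike must be < baselinePloidy")
  if (object@nRefLike < 1L) return("nRefLike must be >= 1")
  rates <- c(object@divergentSnvRate, object@refLikeSnvRate,
             object@homAltSnvRate, object@indelRate)
  if (any(rates < 0 | rates > 0.1))
    return("variant rates must lie in [0, 0.1]")
  if (object@divergentMapRate <= 0 || object@divergentMapRate > 1)
    return("divergentMapRate must lie in (0, 1]")
  if (!object@depthModel %in% c("poisson", "negative_binomial"))
    return("depthModel must be 'poisson' or 'negative_binomial'")
  d <- object@duplication
  if (length(d)) {
    if (!all(c("chrom", "start", "end", "source") %in% names(d)))
      return("duplication needs chrom, start, end, source")
    if (!d$chrom %in% ch$name) return("duplication on unknown chromosome")
    len <- ch$length[match(d$chrom, ch$name)]
    if (d$start < 1 || d$end > len || d$start > d$end)
      return("duplication interval outside its chromosome")
    if (!d$source %in% c("ref_like", "divergent"))
      return("duplication source must be 'ref_like' or 'divergent'")
  }
  TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d chromosome(s), %.1f Mbp, ploidy %d (%d+%d), seed %d\n",
              nrow(object@chromosomes),
              sum(object@chromosomes$length) / 1e6, object@baselinePloidy,
              object@nRefLike, object@baselinePloidy - object@nRefLike,
              as.integer(object@seed)))
  if (length(object@duplication))
    cat(sprintf("  duplication %s:%d-%d (+1 %s copy)\n",
                object@duplication$chrom, object@duplication$start,
                object@duplication$end, object@duplication$source))
})

#' Construct a SimConfig
#'
#' The defaults describe the package's reference scenario: a 6 Mbp triploid
#' genome (three 2 Mbp chromosomes) with two reference-like and one
#' divergent haplophase, ~60x depth (20x per copy), a 600 kb duplication on
#' chromosome 2 contributing an extra reference-like copy, two N-gap
#' stretches producing pseudo low-coverage windows, and CDS-aware InDel
#' length biases.  See the package vignette for the rationale behind each
#' value.
#'
#' @param seed,chromosomes,baselinePloidy,nRefLike see [SimConfig-class].
#' @param divergentSnvRate,refLikeSnvRate,homAltSnvRate per-bp SNV rates.
#' @param duplication `list(chrom, start, end, source)` or `NULL`.
#' @param depthPerCopy,depthModel,nbDispersion,divergentMapRate depth model.
#' @param nGaps `GRanges` of N-stretches (or `NULL`).
#' @param genes `list(count, meanCdsLength)`.
#' @param indelRate,indelMaxLen,indelGeomP,cdsMod3Enrichment InDel model.
#' @param failFrac fraction of records with failing filter annotations.
#' @return a [SimConfig].
#' @export
simConfig <- function(seed = 1,
                      chromosomes = data.frame(
                        name = c("chr01", "chr02", "chr03"),
                        length = rep(2000000L, 3)),
                      baselinePloidy = 3L, nRefLike = 2L,
                      divergentSnvRate = 0.005, refLikeSnvRate = 0.0005,
                      homAltSnvRate = 0.001,
                      duplication = list(chrom = "chr02", start = 800001L,
                                         end = 1400000L, source = "ref_like"),
                      depthPerCopy = 20, depthModel = "poisson",
                      nbDispersion = 20, divergentMapRate = 0.95,
                      nGaps = GRanges(c("chr01", "chr03"),
                                      IRanges(c(400001L, 1500001L),
                                              c(600000L, 1600000L))),
                      genes = list(count = 90L, meanCdsLength = 900L),
                      indelRate = 0.0005, indelMaxLen = 12L,
                      indelGeomP = 0.35, cdsMod3Enrichment = 3,
                      failFrac = 0.05) {
  new("SimConfig", seed = seed, chromosomes = chromosomes,
      baselinePloidy = as.integer(baselinePloidy),
      nRefLike = as.integer(nRefLike),
      divergentSnvRate = divergentSnvRate, refLikeSnvRate = refLikeSnvRate,
      homAltSnvRate = homAltSnvRate,
      duplication = if (is.null(duplication)) list() else duplication,
      depthPerCopy = depthPerCopy, depthModel = depthModel,
      nbDispersion = nbDispersion, divergentMapRate = divergentMapRate,
      nGaps = if (is.null(nGaps)) GRanges() else nGaps, genes = genes,
      indelRate = indelRate, indelMaxLen = as.integer(indelMaxLen),
      indelGeomP = indelGeomP, cdsMod3Enrichment = cdsMod3Enrichment,
      failFrac = failFrac)
}

#' Load a SimConfig from YAML
#'
#' Reads a YAML file with snake_case keys mirroring the [simConfig()]
#' arguments (`chromosomes` as a list of `{name, length}` entries,
#' `duplication` and `n_gaps` as interval mappings or absent).  Two presets
#' ship with the package under `inst/extdata/`: `triploid_default.yaml`
#' (the reference triploid-plus-duplication scenario) and
#' `null_diploid.yaml` (a diploid negative control with no duplication, no
#' mapping-rate penalty and no mod-3 enrichment).
#'
#' @param path YAML path.
#' @param seed optional seed overriding the file's value.
#' @return a [SimConfig].
#' @export
loadSimConfig <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(seed)) args$seed <- seed
  if (!is.null(y$chromosomes))
    args$chromosomes <- data.frame(
      name = vapply(y$chromosomes, `[[`, character(1), "name"),
      length = vapply(y$chromosomes, function(c) as.integer(c$length),
                      integer(1)))
  map <- c(baseline_ploidy = "baselinePloidy", n_ref_like = "nRefLike",
           divergent_snv_rate = "divergentSnvRate",
           ref_like_snv_rate = "refLikeSnvRate",
           hom_alt_snv_rate = "homAltSnvRate",
           depth_per_copy = "depthPerCopy", depth_model = "depthModel",
           nb_dispersion = "nbDispersion",
           divergent_map_rate = "divergentMapRate",
           indel_rate = "indelRate", indel_max_len = "indelMaxLen",
           indel_geom_p = "indelGeomP",
           cds_mod3_enrichment = "cdsMod3Enrichment", fail_frac = "failFrac")
  for (k in names(map)) if (!is.null(y[[k]])) args[[map[[k]]]] <- y[[k]]
  args$duplication <- if (is.null(y$duplication)) list() else
    list(chrom = y$duplication$chrom,
         start = as.integer(y$duplication$start),
         end = as.integer(y$duplication$end),
         source = y$duplication$source)
  args$nGaps <- if (is.null(y$n_gaps)) GRanges() else
    GRanges(vapply(y$n_gaps, `[[`, character(1), "chrom"),
            IRanges(vapply(y$n_gaps, function(g) as.integer(g$start),
                           integer(1)),
                    vapply(y$n_gaps, function(g) as.integer(g$end),
                           integer(1))))
  if (!is.null(y$genes))
    args$genes <- list(count = as.integer(y$genes$count),
                       meanCdsLength = as.integer(y$genes$mean_cds_length))
  do.call(simConfig, args)
}

.BASES <- c("A", "C", "G", "T")
.ALLCODONS <- as.vector(outer(outer(.BASES, .BASES, paste0), .BASES, paste0))
.SENSECODONS <- setdiff(.ALLCODONS, c("TAA", "TAG", "TGA"))

#' Sample InDel lengths with optional frame-preservation enrichment
#'
#' Lengths follow a truncated geometric distribution (short InDels dominate,
#' as in real call sets); inside coding sequence the probability of lengths
#' divisible by 3 is multiplied by `mod3Enrichment` and renormalized,
#' emulating selection against frameshifts.
#'
#' @param n number of lengths to draw.
#' @param maxLen truncation point (bp).
#' @param mod3Enrichment multiplier on mod-3 length probabilities (1 = no
#'   bias).
#' @param geomP geometric parameter.
#' @return integer vector of lengths in 1..`maxLen`.
#' @export
sampleIndelLengths <- function(n, maxLen = 12L, mod3Enrichment = 1,
                               geomP = 0.35) {
  lens <- seq_len(maxLen)
  w <- stats::dgeom(lens - 1L, geomP)
  w[lens %% 3L == 0L] <- w[lens %% 3L == 0L] * mod3Enrichment
  sample(lens, n, replace = TRUE, prob = w / sum(w))
}

# copy composition (ref-like, divergent) for baseline vs duplicated region
.copyComposition <- function(cfg) {
  nRef <- cfg@nRefLike
  nDiv <- cfg@baselinePloidy - cfg@nRefLike
  dupRef <- nRef + (length(cfg@duplication) &&
                      cfg@duplication$source == "ref_like")
  dupDiv <- nDiv + (length(cfg@duplication) &&
                      cfg@duplication$source == "divergent")
  list(base = c(ref = nRef, div = nDiv),
       dup = c(ref = as.integer(dupRef), div = as.integer(dupDiv)))
}

.placeGenes <- function(cfg, gapByChrom) {
  count <- cfg@genes$count
  meanLen <- cfg@genes$meanCdsLength
  ch <- cfg@chromosomes
  placed <- list()
  occupied <- lapply(seq_len(nrow(ch)), function(i) IRanges())
  names(occupied) <- ch$name
  for (g in seq_len(count)) {
    nCodons <- max(33L, as.integer(round(stats::rnorm(1, meanLen / 3,
                                                      meanLen / 9))))
    L <- 3L * nCodons
    nExons <- sample(1:2, 1L)
    widths <- if (nExons == 1L) L else {
      w1 <- sample(3:(L - 3L), 1L); c(w1, L - w1)
    }
    intron <- if (nExons == 2L) sample(100:500, 1L) else 0L
    span <- L + intron
    strand <- sample(c("+", "-"), 1L)
    ci <- sample(nrow(ch), 1L)
    ok <- FALSE
    for (try in 1:50) {
      st <- sample.int(ch$length[ci] - span - 1L, 1L)
      rng <- IRanges(st, st + span - 1L)
      busy <- IRanges::overlapsAny(rng + 200L, occupied[[ch$name[ci]]]) ||
        IRanges::overlapsAny(rng, gapByChrom[[ch$name[ci]]])
      if (!busy) { ok <- TRUE; break }
    }
    if (!ok) next
    occupied[[ch$name[ci]]] <- c(occupied[[ch$name[ci]]], rng)
    exonStarts <- st
    if (nExons == 2L) exonStarts <- c(st, st + widths[1L] + intron)
    exonEnds <- exonStarts + widths - 1L
    # phase: 0 for the transcription-first exon, then cumulative
    txOrder <- if (strand == "-") rev(seq_len(nExons)) else seq_len(nExons)
    phase <- integer(nExons)
    acc <- 0L
    for (j in txOrder) {
      phase[j] <- (3L - acc %% 3L) %% 3L
      acc <- acc + widths[j]
    }
    codons <- c("ATG", sample(.SENSECODONS, nCodons - 2L, replace = TRUE),
                sample(c("TAA", "TAG", "TGA"), 1L))
    sense <- paste(codons, collapse = "")
    placed[[length(placed) + 1L]] <-
      list(id = sprintf("gene%04d", g), chrom = ch$name[ci], strand = strand,
           starts = exonStarts, ends = exonEnds, phase = phase, sense = sense)
  }
  placed
}

#' Simulate a polyploid resequencing dataset with known truth
#'
#' Realizes the generative model of [SimConfig-class]: draws a random
#' reference with N-gap stretches and embedded gene models (proper ORFs on
#' either strand), places SNVs and InDels on the haplophase classes, draws
#' per-position depth proportional to local copy number (divergent copies
#' thinned by the mapping-rate penalty), samples allele depths binomially
#' from the local haplophase dosage, and attaches QD/FS/MQ annotations
#' (mostly passing, a configurable fraction failing).  The same
#' configuration and seed always produce identical output.
#'
#' @param cfg a [SimConfig].
#' @return a list with components `reference` (`DNAStringSet`), `refIndex`
#'   ([ReferenceIndex]), `depth` (`data.table` chrom/pos/depth, zero-depth
#'   positions omitted), `variants` (`GRanges` in [readVcfRecords()]
#'   layout, plus `gt`), `genes` (`GRangesList` of CDS models), and `truth`
#'   (list: `ploidyMap` `GRanges` with copy composition per interval,
#'   `variants` `data.table` of per-site haplophase assignments, `config`).
#' @seealso [writeSimulation()] to materialize the dataset as
#'   FASTA/TSV/VCF/GFF3/BED/JSON files.
#' @export
simulateGenome <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  dup <- cfg@duplication
  if (length(dup) && length(cfg@nGaps)) {
    dupGr <- GRanges(dup$chrom, IRanges(dup$start, dup$end))
    if (any(suppressWarnings(IRanges::overlapsAny(dupGr, cfg@nGaps))))
      stop("duplication overlaps an N-gap; copy-number truth undefined")
  }
  set.seed(as.integer(cfg@seed))
  ch <- cfg@chromosomes
  si <- Seqinfo(seqnames = ch$name, seqlengths = as.integer(ch$length))
  gapByChrom <- lapply(stats::setNames(ch$name, ch$name), function(cn) {
    g <- cfg@nGaps[seqnames(cfg@nGaps) == cn]
    IRanges::reduce(ranges(g))
  })

  # 1. reference sequence with N-gaps
  chars <- lapply(seq_len(nrow(ch)), function(i) {
    v <- sample(.BASES, ch$length[i], replace = TRUE)
    g <- gapByChrom[[ch$name[i]]]
    if (length(g))
      v[unlist(Map(seq.int, start(g), end(g)))] <- "N"
    v
  })
  names(chars) <- ch$name

  # 2. gene models with embedded ORFs
  geneDefs <- .placeGenes(cfg, gapByChrom)
  for (gd in geneDefs) {
    genomic <- if (gd$strand == "-")
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(gd$sense)))
    else gd$sense
    off <- 0L
    for (j in seq_along(gd$starts)) {
      w <- gd$ends[j] - gd$starts[j] + 1L
      chars[[gd$chrom]][gd$starts[j]:gd$ends[j]] <-
        strsplit(substr(genomic, off + 1L, off + w), "")[[1L]]
      off <- off + w
    }
  }
  genes <- if (length(geneDefs)) {
    grl <- lapply(geneDefs, function(gd)
      GRanges(gd$chrom, IRanges(gd$starts, gd$ends), strand = gd$strand,
              phase = gd$phase, seqinfo = si))
    stats::setNames(GenomicRanges::GRangesList(grl),
                    vapply(geneDefs, `[[`, character(1), "id"))
  } else GenomicRanges::GRangesList()

  comp <- .copyComposition(cfg)
  m <- cfg@divergentMapRate

  # 3. SNV sites per haplophase class
  snvRates <- c(divergent_het = cfg@divergentSnvRate,
                ref_like_shared = cfg@refLikeSnvRate,
                hom_alt = cfg@homAltSnvRate)
  siteList <- list()
  usedByChrom <- list()
  for (i in seq_len(nrow(ch))) {
    cn <- ch$name[i]
    eligible <- which(chars[[cn]] != "N")
    nPer <- stats::rpois(length(snvRates), length(eligible) * snvRates)
    tot <- sum(nPer)
    pos <- sample(eligible, min(tot, length(eligible)))
    cls <- rep(names(snvRates), nPer)[seq_along(pos)]
    usedByChrom[[cn]] <- pos
    if (!length(pos)) next
    refB <- chars[[cn]][pos]
    shift <- sample(1:3, length(pos), replace = TRUE)
    altB <- .BASES[(match(refB, .BASES) - 1L + shift) %% 4L + 1L]
    siteList[[cn]] <- data.table::data.table(
      chrom = cn, pos = pos, ref = refB, alt = altB, vtype = "SNV",
      indelLen = 0L, class = cls)
  }

  # 4. InDels, mod-3 enriched inside CDS
  cdsAll <- if (length(genes)) unlist(genes, use.names = FALSE) else GRanges()
  pDiv <- cfg@divergentSnvRate /
    (cfg@divergentSnvRate + cfg@refLikeSnvRate)
  indelList <- list()
  for (i in seq_len(nrow(ch))) {
    cn <- ch$name[i]
    lenC <- ch$length[i]
    clear <- rep(TRUE, lenC)
    clear[chars[[cn]] == "N"] <- FALSE
    g <- gapByChrom[[cn]]
    # keep maxLen + 1 bp of clearance before gaps and the chromosome end
    for (k in seq_along(g))
      clear[max(1L, start(g)[k] - cfg@indelMaxLen - 1L):end(g)[k]] <- FALSE
    clear[(lenC - cfg@indelMaxLen):lenC] <- FALSE
    clear[usedByChrom[[cn]]] <- FALSE
    eligible <- which(clear)
    nInd <- stats::rpois(1L, sum(chars[[cn]] != "N") * cfg@indelRate)
    if (!nInd) next
    pos <- sample(eligible, min(nInd, length(eligible)))
    inCds <- if (length(cdsAll))
      IRanges::overlapsAny(GRanges(cn, IRanges(pos, pos)), cdsAll)
    else rep(FALSE, length(pos))
    lens <- integer(length(pos))
    if (any(inCds))
      lens[inCds] <- sampleIndelLengths(sum(inCds), cfg@indelMaxLen,
                                        cfg@cdsMod3Enrichment, cfg@indelGeomP)
    if (any(!inCds))
      lens[!inCds] <- sampleIndelLengths(sum(!inCds), cfg@indelMaxLen, 1,
                                         cfg@indelGeomP)
    isIns <- sample(c(TRUE, FALSE), length(pos), replace = TRUE)
    refA <- character(length(pos)); altA <- character(length(pos))
    for (j in seq_along(pos)) {
      anchor <- chars[[cn]][pos[j]]
      if (isIns[j]) {
        refA[j] <- anchor
        altA[j] <- paste0(anchor, paste(sample(.BASES, lens[j],
                                               replace = TRUE),
                                        collapse = ""))
      } else {
        refA[j] <- paste(chars[[cn]][pos[j]:(pos[j] + lens[j])],
                         collapse = "")
        altA[j] <- anchor
      }
    }
    cls <- ifelse(stats::runif(length(pos)) < pDiv, "divergent_het",
                  "ref_like_shared")
    indelList[[cn]] <- data.table::data.table(
      chrom = cn, pos = pos, ref = refA, alt = altA, vtype = "InDel",
      indelLen = lens, class = cls)
  }

  sites <- data.table::rbindlist(c(siteList, indelList))
  sites <- sites[order(match(sites$chrom, ch$name), sites$pos), ]

  # 5. per-position depth proportional to local copy number
  depthList <- lapply(seq_len(nrow(ch)), function(i) {
    cn <- ch$name[i]
    dose <- rep(comp$base["ref"] + m * comp$base["div"], ch$length[i])
    if (length(dup) && cn == dup$chrom)
      dose[dup$start:dup$end] <- comp$dup["ref"] + m * comp$dup["div"]
    dose[chars[[cn]] == "N"] <- 0
    rate <- cfg@depthPerCopy * dose
    d <- if (cfg@depthModel == "poisson") stats::rpois(ch$length[i], rate)
    else stats::rnbinom(ch$length[i], mu = rate, size = cfg@nbDispersion)
    d[rate == 0] <- 0L
    d
  })
  names(depthList) <- ch$name

  # 6. allele depths from local haplophase dosage
  n <- nrow(sites)
  dp <- integer(n); fAlt <- numeric(n)
  posIdx <- split(seq_len(n), sites$chrom)
  for (cn in names(posIdx)) {
    ii <- posIdx[[cn]]
    if (!length(ii)) next
    dp[ii] <- depthList[[cn]][sites$pos[ii]]
    dupHere <- if (length(dup) && cn == dup$chrom)
      sites$pos[ii] >= dup$start & sites$pos[ii] <= dup$end
    else rep(FALSE, length(ii))
    nR <- ifelse(dupHere, comp$dup["ref"], comp$base["ref"])
    nD <- ifelse(dupHere, comp$dup["div"], comp$base["div"])
    cl <- sites$class[ii]
    fAlt[ii] <- ifelse(cl == "divergent_het", (nD * m) / (nR + nD * m),
                ifelse(cl == "ref_like_shared", nR / (nR + nD * m), 1))
  }
  adAlt <- stats::rbinom(n, dp, fAlt)
  adRef <- dp - adAlt

  # 7. filter annotations: mostly passing, failFrac failing
  qd <- stats::runif(n, 15, 35)
  fsv <- stats::runif(n, 0, 10)
  mqv <- stats::runif(n, 45, 60)
  fail <- stats::runif(n) < cfg@failFrac
  isSnv <- sites$vtype == "SNV"
  mode <- integer(n)
  mode[fail & isSnv] <- sample(1:3, sum(fail & isSnv), replace = TRUE)
  mode[fail & !isSnv] <- sample(1:2, sum(fail & !isSnv), replace = TRUE)
  qd[mode == 1L] <- stats::runif(sum(mode == 1L), 0.1, 1.9)
  fsv[mode == 2L & isSnv] <- stats::runif(sum(mode == 2L & isSnv), 61, 120)
  fsv[mode == 2L & !isSnv] <- stats::runif(sum(mode == 2L & !isSnv), 201, 300)
  mqv[mode == 3L] <- stats::runif(sum(mode == 3L), 10, 39)

  variants <- GRanges(as.character(sites$chrom),
                      IRanges(sites$pos, width = nchar(sites$ref)),
                      seqinfo = si)
  mcols(variants) <- DataFrame(
    ref = sites$ref, alt = sites$alt, vtype = sites$vtype,
    indelLen = sites$indelLen, qd = qd, fs = fsv, mq = mqv,
    adRef = adRef, adAlt = adAlt, dp = dp,
    annoMissing = FALSE,
    gt = ifelse(sites$class == "hom_alt", "1/1", "0/1"))

  depth <- data.table::rbindlist(lapply(ch$name, function(cn) {
    d <- depthList[[cn]]
    keep <- d > 0L
    data.table::data.table(chrom = cn, pos = which(keep), depth = d[keep])
  }))
  data.table::setattr(depth, "binned", FALSE)

  # truth
  ploidyMap <- local({
    rows <- list()
    for (i in seq_len(nrow(ch))) {
      cn <- ch$name[i]; len <- ch$length[i]
      if (length(dup) && cn == dup$chrom) {
        iv <- rbind(c(1L, dup$start - 1L, 0L), c(dup$start, dup$end, 1L),
                    c(dup$end + 1L, len, 0L))
        iv <- iv[iv[, 1L] <= iv[, 2L], , drop = FALSE]
      } else iv <- cbind(1L, len, 0L)
      isDup <- iv[, 3L] == 1L
      rows[[i]] <- data.frame(
        chrom = cn, start = iv[, 1L], end = iv[, 2L],
        copyNumber = ifelse(isDup, sum(comp$dup), sum(comp$base)),
        nRefLike = ifelse(isDup, comp$dup["ref"], comp$base["ref"]),
        nDivergent = ifelse(isDup, comp$dup["div"], comp$base["div"]))
    }
    df <- do.call(rbind, rows)
    gr <- GRanges(df$chrom, IRanges(df$start, df$end), seqinfo = si)
    mcols(gr) <- DataFrame(df[, c("copyNumber", "nRefLike", "nDivergent")])
    gr
  })
  inDupV <- if (length(dup))
    IRanges::overlapsAny(variants, GRanges(dup$chrom,
                                           IRanges(dup$start, dup$end)))
  else rep(FALSE, n)
  locRef <- ifelse(inDupV, comp$dup["ref"], comp$base["ref"])
  locDiv <- ifelse(inDupV, comp$dup["div"], comp$base["div"])
  altCopies <- ifelse(sites$class == "hom_alt", locRef + locDiv,
               ifelse(sites$class == "divergent_het", locDiv, locRef))
  truthVariants <- data.table::data.table(
    chrom = as.character(sites$chrom), pos = sites$pos, vtype = sites$vtype,
    indelLen = sites$indelLen, class = sites$class,
    altCopies = as.integer(altCopies),
    totCopies = as.integer(locRef + locDiv))

  reference <- Biostrings::DNAStringSet(
    vapply(chars, paste, character(1), collapse = ""))
  refIndex <- new("ReferenceIndex", seqinfo = si,
                  nGaps = GRanges(seqnames(cfg@nGaps), ranges(cfg@nGaps),
                                  seqinfo = si),
                  centromeres = GRanges(seqinfo = si))
  list(reference = reference, refIndex = refIndex, depth = depth,
       variants = variants, genes = genes,
       truth = list(ploidyMap = ploidyMap, variants = truthVariants,
                    config = cfg))
}

#' Write a simulated dataset to disk
#'
#' Materializes a [simulateGenome()] result as the standard files the
#' pipeline consumes: `reference.fasta`, `depth.tsv` (chrom, pos, depth),
#' `variants.vcf` (VCF 4.2), `genes.gff3`, `truth.bed` (ploidy map with
#' copy-composition columns), `truth_variants.tsv` and `truth.json`.
#'
#' @param sim result of [simulateGenome()].
#' @param outdir output directory (created if missing).
#' @return named character vector of the written paths, invisibly.
#' @export
writeSimulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  Biostrings::writeXStringSet(sim$reference, p("reference.fasta"))
  data.table::fwrite(sim$depth, p("depth.tsv"), sep = "\t")
  writeVcfRecords(sim$variants, p("variants.vcf"), refIndex = sim$refIndex)
  .writeGff3(sim$genes, p("genes.gff3"))
  writeBed(sim$truth$ploidyMap, p("truth.bed"))
  data.table::fwrite(sim$truth$variants, p("truth_variants.tsv"), sep = "\t")
  cfg <- sim$truth$config
  cls <- table(sim$truth$variants$class)
  jsonlite::write_json(list(
    seed = as.integer(cfg@seed),
    baseline_ploidy = cfg@baselinePloidy, n_ref_like = cfg@nRefLike,
    divergent_map_rate = cfg@divergentMapRate,
    depth_per_copy = cfg@depthPerCopy,
    duplication = cfg@duplication,
    n_variants = nrow(sim$truth$variants),
    variant_classes = as.list(cls),
    n_genes = length(sim$genes)),
    p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = p("reference.fasta"), depth = p("depth.tsv"),
              vcf = p("variants.vcf"), gff = p("genes.gff3"),
              truth_bed = p("truth.bed"),
              truth_variants = p("truth_variants.tsv"),
              truth_json = p("truth.json")))
}

# deterministic GFF3 writer (gene + CDS rows); read back via readGeneModels()
.writeGff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (gid in names(genes)) {
    cds <- genes[[gid]]
    cn <- as.character(seqnames(cds))[1L]
    strand <- as.character(strand(cds))[1L]
    lines <- c(lines,
      sprintf("%s\tploidyscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              cn, min(start(cds)), max(end(cds)), strand, gid),
      sprintf("%s\tploidyscan\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
              cn, start(cds), end(cds), strand, cds$phase, gid))
  }
  writeLines(lines, path)
  invisible(path)
}
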