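#' Run the full analysis pipeline
#'
#' Composes the stages end to end: hard-filter the VCF, window and
#' normalize the depth track with N-gap artifact masking, segment copy
#' number, infer global and per-segment ploidy from reference-allele
#' frequencies, and characterize the variant landscape (density track,
#' InDel mod-3 bias, effect classes).  Stage outputs are written to
#' `outdir`; a stage whose outputs already exist is skipped unless
#' `force = TRUE`, so a run can be resumed.  Every run records the package
#' version, a hash of the configuration and the seed in the report.
#'
#' @param config a list (or path to a YAML file) with entries `vcf`,
#'   `depth`, `ref` (FASTA), `gff`, optional `centromeres` (BED), `outdir`,
#'   and optional parameters `window` (default 100000), `ploidy` (default
#'   3), `min_gap` (default 100), `seed` (default 1), plus optional
#'   sub-lists `filter` (arguments to [filterConfig()]) and `ploidy_model`
#'   (arguments passed to [segmentPloidy()]).
#' @param force rerun stages whose outputs already exist.
#' @return the report, invisibly: a list with `filter` counts, `segments`,
#'   `ploidy` report, `density` summary, `mod3` estimates and `effects`
#'   counts.  Also written to `outdir/report.json`.
#' @export
runAll <- function(config, force = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (key in c("vcf", "depth", "ref", "gff", "outdir"))
    if (is.null(config[[key]]))
      stop("config entry '", key, "' is required")
  for (key in c("vcf", "depth", "ref", "gff"))
    if (!file.exists(config[[key]]))
      stop("input path does not exist: ", config[[key]], " ('", key, "')")
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  window <- if (is.null(config$window)) 100000L else as.integer(config$window)
  basePloidy <- if (is.null(config$ploidy)) 3L else as.integer(config$ploidy)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  set.seed(seed)
  cfgHash <- .configHash(config)
  out <- function(f) file.path(outdir, f)
  stage <- function(name, outputs, fun) {
    if (!force && all(file.exists(outputs))) {
      message("stage '", name, "': outputs present, skipping (use force = TRUE to rerun)")
      return(NULL)
    }
    tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  ref <- readReference(config$ref,
                       minGap = if (is.null(config$min_gap)) 100
                                else config$min_gap,
                       centromeres = config$centromeres)
  fcfg <- do.call(filterConfig, if (is.null(config$filter)) list()
                                else config$filter)

  # filter
  stage("filter", out(c("kept.vcf", "filter_report.tsv")), function() {
    raw <- readVcfRecords(config$vcf)
    fl <- filterVariants(raw, fcfg)
    writeVcfRecords(fl$kept, out("kept.vcf"), refIndex = ref)
    writeTsv(fl$report, out("filter_report.tsv"))
  })
  kept <- readVcfRecords(out("kept.vcf"))
  filterReport <- readTsv(out("filter_report.tsv"))

  # cnv
  stage("cnv", out(c("segments.bed", "windows.tsv")), function() {
    depth <- readDepth(config$depth)
    win <- windowDepth(depth, ref, window)
    win <- maskArtifacts(normalizeWindows(win))
    segs <- segmentCopyNumber(win, basePloidy)
    writeBed(segs, out("segments.bed"))
    wdf <- data.frame(chrom = as.character(seqnames(win)),
                      start = start(win) - 1L, end = end(win),
                      as.data.frame(mcols(win)))
    if (length(centromeres(ref)))
      wdf$centromere <- IRanges::overlapsAny(win, centromeres(ref))
    writeTsv(wdf, out("windows.tsv"))
  })
  segments <- readBed(out("segments.bed"),
                      c("copyNumber", "meanRatio", "status"))
  metadata(segments)$baselinePloidy <- basePloidy

  # ploidy
  stage("ploidy", out(c("ploidy_report.tsv", "spectrum.tsv")), function() {
    pm <- if (is.null(config$ploidy_model)) list() else config$ploidy_model
    sp <- do.call(segmentPloidy, c(list(kept, segments,
                                        baselinePloidy = basePloidy), pm))
    writeTsv(sp$report, out("ploidy_report.tsv"))
    specRows <- lapply(names(sp$calls), function(lab) {
      region <- if (lab == "global")
        segments[segments$status == "real" &
                   segments$copyNumber == basePloidy]
      else {
        pieces <- strsplit(lab, "[:-]")[[1L]]
        GRanges(pieces[1L], IRanges(as.numeric(pieces[2L]),
                                    as.numeric(pieces[3L])))
      }
      afs <- refAF(kept[IRanges::overlapsAny(kept, region)])
      spec <- buildSpectrum(afs, regionLabel = lab)
      nb <- length(spectrumCounts(spec))
      data.frame(bin_start = spectrumBinEdges(spec)[-(nb + 1L)],
                 bin_end = spectrumBinEdges(spec)[-1L],
                 count = spectrumCounts(spec), region_label = lab)
    })
    writeTsv(do.call(rbind, specRows), out("spectrum.tsv"))
  })
  ploidyReport <- readTsv(out("ploidy_report.tsv"))

  # landscape
  stage("landscape", out(c("landscape.tsv", "effects.tsv", "mod3.json")),
        function() {
    genes <- readGeneModels(config$gff)
    dens <- densityTrack(kept, ref, window)
    writeTsv(data.frame(chrom = as.character(seqnames(dens)),
                        start = start(dens) - 1L, end = end(dens),
                        snv_count = dens$snvCount,
                        indel_count = dens$indelCount),
             out("landscape.tsv"))
    mod3 <- indelMod3Bias(kept, genes)
    jsonlite::write_json(list(p_cds = mod3$pCds, p_noncds = mod3$pNoncds,
                              diff = mod3$diff, n_cds = mod3$nCds,
                              n_noncds = mod3$nNoncds, method = mod3$method,
                              p_value = if (is.null(mod3$test)) NULL
                                        else mod3$test$p.value),
                         out("mod3.json"), auto_unbox = TRUE, digits = NA,
                         null = "null")
    refSeqs <- Biostrings::readDNAStringSet(config$ref)
    names(refSeqs) <- sub("\\s.*$", "", names(refSeqs))
    eff <- classifyEffects(kept, genes, refSeqs)
    writeTsv(data.frame(chrom = as.character(seqnames(kept)),
                        pos = start(kept), effect = eff$effect,
                        gene_id = eff$geneId),
             out("effects.tsv"))
  })
  landscape <- readTsv(out("landscape.tsv"))
  effects <- readTsv(out("effects.tsv"))
  mod3 <- jsonlite::read_json(out("mod3.json"))

  report <- list(
    tool = "ploidyscan",
    version = as.character(utils::packageVersion("ploidyscan")),
    config_hash = cfgHash, seed = seed,
    filter = stats::setNames(as.list(filterReport$count),
                             filterReport$reason),
    segments = data.frame(chrom = as.character(seqnames(segments)),
                          start = start(segments) - 1L, end = end(segments),
                          copy_number = segments$copyNumber,
                          mean_ratio = segments$meanRatio,
                          status = segments$status),
    ploidy = ploidyReport,
    density = list(snv_total = sum(landscape$snv_count),
                   indel_total = sum(landscape$indel_count),
                   windows = nrow(landscape)),
    mod3 = mod3,
    effects = as.list(table(effects$effect)))
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(report)
}

# stable hash of the configuration (timestamp-free)
.configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config[order(names(config))],
                              auto_unbox = TRUE), f)
  unname(tools::md5sum(f))
}
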