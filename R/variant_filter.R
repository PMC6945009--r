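#' Construct a FilterConfig
#'
#' Defaults follow the GATK germline hard-filter recommendations used for
#' short-read resequencing call sets: SNVs are removed on QD < 2.0,
#' FS > 60.0 or MQ < 40; InDels on QD < 2.0 or FS > 200.0; InDels longer
#' than 100 bp and variants supported by fewer than five reads are removed
#' in either class.
#'
#' @param snvQdMin,snvFsMax,snvMqMin SNV thresholds.
#' @param indelQdMin,indelFsMax InDel thresholds.
#' @param indelMaxLen maximum InDel length (bp).
#' @param minSupport minimum read support.
#' @param supportField `"AD"` counts `adRef + adAlt` as support (the GATK
#'   notion of informative reads); `"DP"` uses total site depth.
#' @return a [FilterConfig].
#' @export
filterConfig <- function(snvQdMin = 2.0, snvFsMax = 60.0, snvMqMin = 40.0,
                         indelQdMin = 2.0, indelFsMax = 200.0,
                         indelMaxLen = 100, minSupport = 5,
                         supportField = c("AD", "DP")) {
  new("FilterConfig", snvQdMin = snvQdMin, snvFsMax = snvFsMax,
      snvMqMin = snvMqMin, indelQdMin = indelQdMin, indelFsMax = indelFsMax,
      indelMaxLen = indelMaxLen, minSupport = minSupport,
      supportField = match.arg(supportField))
}

.removalReasons <- c("missing-annotation", "QD", "FS", "MQ", "length",
                     "support")

#' Hard-filter variant records
#'
#' Applies the hard-filter rules of a [FilterConfig] to a set of variant
#' records.  An SNV is kept iff QD >= `snvQdMin` AND FS <= `snvFsMax` AND
#' MQ >= `snvMqMin` AND support >= `minSupport`; an InDel is kept iff
#' QD >= `indelQdMin` AND FS <= `indelFsMax` AND length <= `indelMaxLen`
#' AND support >= `minSupport`.  Removal conditions are strict inequalities
#' (a record sitting exactly on a threshold is kept).  Records with missing
#' QD/FS/MQ annotations are removed with reason `"missing-annotation"` and
#' a warning, never kept.  Each removed record is attributed to the first
#' failing rule in the fixed order QD, FS, MQ, length, support, so the
#' report is deterministic.
#'
#' @param variants a `GRanges` from [readVcfRecords()].
#' @param cfg a [FilterConfig].
#' @return a list with elements `kept` (the surviving `GRanges`, input
#'   order preserved) and `report` (a `data.frame` of removal counts per
#'   reason plus a `kept` row).  `sum(report$count)` equals the input count.
#' @export
filterVariants <- function(variants, cfg = filterConfig()) {
  stopifnot(is(cfg, "FilterConfig"))
  m <- mcols(variants)
  n <- length(variants)
  support <- if (cfg@supportField == "AD") m$adRef + m$adAlt else m$dp
  isSnv <- m$vtype == "SNV"
  reason <- rep(NA_character_, n)

  missing <- m$annoMissing | is.na(m$qd) | is.na(m$fs) |
    (isSnv & is.na(m$mq))
  reason[missing] <- "missing-annotation"
  ok <- is.na(reason)

  qdMin <- ifelse(isSnv, cfg@snvQdMin, cfg@indelQdMin)
  fsMax <- ifelse(isSnv, cfg@snvFsMax, cfg@indelFsMax)
  failQD <- ok & m$qd < qdMin
  reason[failQD] <- "QD"; ok <- is.na(reason)
  failFS <- ok & m$fs > fsMax
  reason[failFS] <- "FS"; ok <- is.na(reason)
  failMQ <- ok & isSnv & m$mq < cfg@snvMqMin
  reason[failMQ] <- "MQ"; ok <- is.na(reason)
  failLen <- ok & !isSnv & m$indelLen > cfg@indelMaxLen
  reason[failLen] <- "length"; ok <- is.na(reason)
  failSup <- ok & support < cfg@minSupport
  reason[failSup] <- "support"; ok <- is.na(reason)

  if (any(missing))
    warning(sum(missing), " record(s) removed for missing QD/FS/MQ annotations")
  counts <- vapply(.removalReasons, function(r) sum(reason == r, na.rm = TRUE),
                   integer(1))
  report <- data.frame(reason = c(.removalReasons, "kept"),
                       count = c(unname(counts), sum(ok)),
                       row.names = NULL)
  list(kept = variants[ok], report = report)
}
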