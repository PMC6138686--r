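#' Segment CNVs into loci (small overlapping regions)
#'
#' A locus is a maximal genomic segment covered by a constant, non-empty set
#' of patient CNVs. Per chromosome, every CNV start and end becomes a
#' breakpoint; the elementary intervals between consecutive breakpoints each
#' carry the set of CNVs covering them; uncovered intervals are discarded and
#' adjacent intervals with identical CNV sets are merged. The resulting loci
#' partition the covered genome: their union equals the union of the input
#' CNVs base for base, and each CNV is exactly tiled by the loci it supports.
#'
#' All records must share one variant class; deletion and duplication
#' subnetworks are segmented independently.
#'
#' @param cnvs data.frame of CNV records (columns `cnv_id`, `patient_id`,
#'   `chrom`, `start`, `end`, `variant_class`), 0-based half-open.
#' @return data.frame with one row per locus: `locus_id` (`chrom:start-end`),
#'   `chrom`, `start`, `end`, `n_cnvs`, `n_patients`, plus list-columns
#'   `cnv_ids` and `patient_ids`; sorted by (chrom, start).
#' @export
segment_sors <- function(cnvs) {
  empty <- data.frame(locus_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_cnvs = integer(), n_patients = integer(),
                      stringsAsFactors = FALSE)
  empty$cnv_ids <- list()
  empty$patient_ids <- list()
  if (is.null(cnvs) || !nrow(cnvs)) return(empty)
  if (length(unique(cnvs$variant_class)) > 1L) {
    stop("segment_sors expects CNVs of a single variant class; got: ",
         paste(unique(cnvs$variant_class), collapse = ", "))
  }

  per_chrom <- lapply(split(cnvs, cnvs$chrom), segment_one_chrom)
  out <- do.call(rbind, per_chrom[order(names(per_chrom))])
  rownames(out) <- NULL
  out
}

segment_one_chrom <- function(cc) {
  bp <- sort(unique(c(cc$start, cc$end)))
  seg_start <- bp[-length(bp)]
  seg_end <- bp[-1L]

  # CNV set covering each elementary segment
  covering <- lapply(seq_along(seg_start), function(i) {
    hit <- cc$start <= seg_start[i] & cc$end >= seg_end[i]
    sort(cc$cnv_id[hit])
  })
  keep <- lengths(covering) > 0L
  seg_start <- seg_start[keep]; seg_end <- seg_end[keep]
  covering <- covering[keep]
  if (!length(seg_start)) return(NULL)

  # merge runs of adjacent segments with identical CNV sets
  key <- vapply(covering, paste, "", collapse = ",")
  new_run <- c(TRUE, key[-1L] != key[-length(key)] |
                     seg_start[-1L] != seg_end[-length(key)])
  run <- cumsum(new_run)
  start <- tapply(seg_start, run, min)
  end <- tapply(seg_end, run, max)
  cnv_ids <- covering[new_run]

  chrom <- cc$chrom[1L]
  patient_ids <- lapply(cnv_ids, function(ids)
    sort(unique(cc$patient_id[match(ids, cc$cnv_id)])))
  out <- data.frame(
    locus_id = sprintf("%s:%.0f-%.0f", chrom, start, end),
    chrom = chrom, start = as.numeric(start), end = as.numeric(end),
    n_cnvs = lengths(cnv_ids), n_patients = lengths(patient_ids),
    stringsAsFactors = FALSE)
  out$cnv_ids <- cnv_ids
  out$patient_ids <- patient_ids
  out[order(out$start), , drop = FALSE]
}

#' Map a query interval onto reference loci
#'
#' Returns every locus sharing at least one base with the query on the same
#' chromosome, with the overlap in bp and the percentage of the *locus*
#' covered by the query (`locus_overlap_pct`). 100 means the query CNV
#' contains the entire locus; a small value flags a marginal overlap whose
#' phenotype associations should be read with caution.
#'
#' @param loci data.frame from [segment_sors()].
#' @param chrom,start,end query interval, 0-based half-open.
#' @return the overlapping locus rows with extra columns `overlap_bp` and
#'   `locus_overlap_pct`, sorted by position; zero rows when nothing overlaps.
#' @export
map_query <- function(loci, chrom, start, end) {
  if (end <= start) stop("query interval must satisfy start < end")
  chrom <- sub("^chr", "", chrom, ignore.case = TRUE)
  hit <- loci$chrom == chrom & loci$start < end & loci$end > start
  out <- loci[hit, , drop = FALSE]
  if (nrow(out)) {
    out$overlap_bp <- pmin(out$end, end) - pmax(out$start, start)
    out$locus_overlap_pct <- 100 * out$overlap_bp / (out$end - out$start)
    out <- out[order(out$start), , drop = FALSE]
  } else {
    out$overlap_bp <- numeric()
    out$locus_overlap_pct <- numeric()
  }
  rownames(out) <- NULL
  out
}

#' Query region not covered by any locus
#'
#' The part of a query CNV that falls outside every matched locus, as maximal
#' intervals. A sizeable unmatched region in a clinical case is itself a
#' finding: it may harbor the cause of phenotypes the network cannot see.
#'
#' @param hits data.frame from [map_query()] for this query.
#' @param chrom,start,end the query interval.
#' @return data.frame with columns `chrom`, `start`, `end` (possibly empty).
#' @export
unmatched_region <- function(hits, chrom, start, end) {
  chrom <- sub("^chr", "", chrom, ignore.case = TRUE)
  if (!nrow(hits)) {
    return(data.frame(chrom = chrom, start = start, end = end,
                      stringsAsFactors = FALSE))
  }
  s <- pmax(hits$start, start); e <- pmin(hits$end, end)
  o <- order(s)
  s <- s[o]; e <- e[o]
  gaps_start <- c(start, e)
  gaps_end <- c(s, end)
  keep <- gaps_start < gaps_end
  data.frame(chrom = rep(chrom, sum(keep)),
             start = gaps_start[keep], end = gaps_end[keep],
             stringsAsFactors = FALSE)
}

#' Export loci as a BED-style table
#'
#' Writes the loci in 0-based half-open BED coordinates with the locus id as
#' name plus CNV and patient counts as extra columns (BED4+2).
#'
#' @param loci data.frame from [segment_sors()].
#' @param file output path.
#' @export
write_loci_bed <- function(loci, file) {
  out <- data.frame(chrom = loci$chrom,
                    start = format(loci$start, scientific = FALSE, trim = TRUE),
                    end = format(loci$end, scientific = FALSE, trim = TRUE),
                    name = loci$locus_id,
                    n_cnvs = loci$n_cnvs,
                    n_patients = loci$n_patients)
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
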