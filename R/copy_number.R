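#' Copy-number loss-calling thresholds
#'
#' A gene is considered lost in a sample when an overlapping segment has
#' logR below `loss_logR` (-0.4 by default); losses below `homo_logR` are
#' classed as biallelic (homozygous).  In a pure diploid tumor a single-copy
#' loss expects logR about -1, hence the default split at -1.0.
#'
#' @param loss_logR logR below which a gene counts as lost (default -0.4).
#' @param homo_logR logR below which a loss counts as homozygous (default
#'   -1.0); must be below `loss_logR`.
#' @return an object of class `cn_thresholds`.
#' @export
cn_thresholds <- function(loss_logR = -0.4, homo_logR = -1.0) {
  if (!is.finite(loss_logR) || !is.finite(homo_logR))
    stop_input("thresholds must be finite")
  if (homo_logR >= loss_logR)
    stop_input("homo_logR must be below loss_logR")
  structure(list(loss_logR = loss_logR, homo_logR = homo_logR),
            class = "cn_thresholds")
}

#' Does a segment overlap a gene interval?
#'
#' Both intervals are 1-based inclusive; overlap means sharing at least one
#' base on the same chromosome.  Symmetric in its two interval arguments.
#'
#' @param segment list/row with `chrom`, `start`, `end`.
#' @param gene list/row with `chrom`, `start`, `end`.
#' @return logical.
#' @export
#' @examples
#' segment_overlaps_gene(list(chrom = "chr9", start = 100, end = 200),
#'                       list(chrom = "chr9", start = 200, end = 300))
segment_overlaps_gene <- function(segment, gene) {
  segment$chrom == gene$chrom &&
    segment$start <= gene$end && segment$end >= gene$start
}

#' Call copy-number loss status of one gene in one sample
#'
#' Among segments overlapping the gene, the minimum logR is taken (so a
#' focal deletion nested in a broad neutral segment is not averaged away)
#' and compared with the thresholds: below `homo_logR` is a homozygous
#' loss, between `homo_logR` and `loss_logR` a heterozygous loss, otherwise
#' no loss.  LOH is reported if any overlapping segment carries the flag.
#'
#' @param segments data.frame of segments from ONE sample (`sample_id`,
#'   `chrom`, `start`, `end`, `logR`, `loh`).
#' @param gene one gene interval (list/row: `gene`, `chrom`, `start`, `end`).
#' @param thresholds [cn_thresholds()].
#' @return one-row data.frame: `sample_id`, `gene`, `status`,
#'   `min_overlapping_logR` (NA when the locus is uncovered), `loh`.
#' @export
call_gene_loss <- function(segments, gene, thresholds = cn_thresholds()) {
  if (nrow(segments) > 0 && length(unique(segments$sample_id)) > 1)
    stop_input("call_gene_loss expects segments from a single sample")
  ov <- segments$chrom == gene$chrom &
    segments$start <= gene$end & segments$end >= gene$start
  sample_id <- if (nrow(segments)) segments$sample_id[1] else NA_character_
  if (!any(ov)) {
    message(sprintf("locus %s uncovered by any segment in sample %s",
                    gene$gene, sample_id))
    return(data.frame(sample_id = sample_id, gene = gene$gene,
                      status = "no_loss", min_overlapping_logR = NA_real_,
                      loh = FALSE, stringsAsFactors = FALSE))
  }
  m <- min(segments$logR[ov])
  status <- if (m < thresholds$homo_logR) "homo_loss"
  else if (m < thresholds$loss_logR) "het_loss"
  else "no_loss"
  data.frame(sample_id = sample_id, gene = gene$gene, status = status,
             min_overlapping_logR = m, loh = any(segments$loh[ov]),
             stringsAsFactors = FALSE)
}

#' Gene-level loss profile across a cohort
#'
#' Vectorizes [call_gene_loss()] over every sample in the segment table and
#' every gene, using GenomicRanges for the interval overlap.  Output rows
#' are ordered deterministically by sample, then gene symbol.
#'
#' @param segments segment data.frame (possibly many samples).
#' @param genes data.frame of gene intervals (`gene`, `chrom`, `start`,
#'   `end`).
#' @param thresholds [cn_thresholds()].
#' @return data.frame with one row per sample x gene: `sample_id`, `gene`,
#'   `status`, `min_overlapping_logR`, `loh`.
#' @export
genome_loss_profile <- function(segments, genes, thresholds = cn_thresholds()) {
  if (nrow(genes) == 0 || nrow(segments) == 0)
    return(data.frame(sample_id = character(0), gene = character(0),
                      status = character(0), min_overlapping_logR = numeric(0),
                      loh = logical(0), stringsAsFactors = FALSE))
  seg_gr <- GenomicRanges::GRanges(segments$chrom,
                                   IRanges::IRanges(segments$start, segments$end))
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(gene_gr, seg_gr)
  gi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)

  samples <- sort(unique(segments$sample_id))
  gsyms <- sort(genes$gene)
  out <- expand.grid(gene = gsyms, sample_id = samples,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("sample_id", "gene")]
  out$status <- "no_loss"
  out$min_overlapping_logR <- NA_real_
  out$loh <- FALSE

  if (length(gi)) {
    key <- paste(segments$sample_id[si], genes$gene[gi], sep = "\r")
    mins <- tapply(segments$logR[si], key, min)
    lohs <- tapply(segments$loh[si], key, any)
    okey <- paste(out$sample_id, out$gene, sep = "\r")
    idx <- match(okey, names(mins))
    cov <- !is.na(idx)
    out$min_overlapping_logR[cov] <- unname(mins[idx[cov]])
    out$loh[cov] <- unname(lohs[idx[cov]])
    m <- out$min_overlapping_logR
    out$status[cov & m < thresholds$loss_logR] <- "het_loss"
    out$status[cov & m < thresholds$homo_logR] <- "homo_loss"
  }
  uncovered <- is.na(out$min_overlapping_logR)
  if (any(uncovered))
    message(sprintf("%d sample x gene pairs uncovered by any segment", sum(uncovered)))
  rownames(out) <- NULL
  out
}
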